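# ConText-style contextual-property detection: negation, experiencer and
# temporality are assigned to a keyword mention by scanning its sentence for
# trigger phrases and testing whether the keyword span falls inside each
# trigger's scope. Scopes run from a forward trigger to the end of the
# sentence (cut at a termination term of the same property), or from the
# sentence start (or nearest preceding termination term) back to a backward
# trigger. Pseudo-negation phrases block negation triggers inside their span.

CONTEXT_PROPERTIES <- c("negation", "pseudo_negation", "experiencer",
                        "historical", "hypothetical")

#' Load a ConText trigger table
#'
#' Reads the tab-separated trigger dialect: columns `phrase`, `property`
#' (negation/pseudo_negation/experiencer/historical/hypothetical), `direction`
#' (forward/backward/both) and `action` (set/terminate); `#` comment lines
#' ignored. The shipped base table is initialised from the published
#' ConText/NegEx term lists; a British-English overlay ships separately and is
#' off by default.
#'
#' @param path path to a trigger TSV; `NULL` loads the shipped base table.
#' @param overlay also merge the shipped British-English overlay (only
#'   meaningful with the default `path`).
#' @return data.frame of triggers with compiled token patterns attached.
#' @export
load_triggers <- function(path = NULL, overlay = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "context_triggers.tsv", package = "smisym",
                        mustWork = TRUE)
  }
  read_one <- function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("empty trigger table: ", p, call. = FALSE)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(trimws(header), c("phrase", "property", "direction", "action"))) {
      stop("trigger table header must be: phrase, property, direction, action",
           call. = FALSE)
    }
    fields <- strsplit(lines[-1], "\t", fixed = TRUE)
    data.frame(phrase = vapply(fields, `[`, "", 1),
               property = vapply(fields, `[`, "", 2),
               direction = vapply(fields, `[`, "", 3),
               action = vapply(fields, `[`, "", 4),
               stringsAsFactors = FALSE)
  }
  df <- read_one(path)
  if (overlay) {
    op <- system.file("extdata", "context_triggers_uk_overlay.tsv",
                      package = "smisym", mustWork = TRUE)
    df <- rbind(df, read_one(op))
  }
  bad <- !df$property %in% CONTEXT_PROPERTIES
  if (any(bad)) stop("unknown trigger property: ",
                     paste(unique(df$property[bad]), collapse = ", "),
                     call. = FALSE)
  stopifnot(all(df$direction %in% c("forward", "backward", "both")),
            all(df$action %in% c("set", "terminate")))
  attr(df, "compiled") <- lapply(df$phrase, function(p) {
    toks <- parse_phrase(p)
    list(tokens = sub("\\*$", "", toks), prefix = grepl("\\*$", toks),
         string = phrase_to_string(toks))
  })
  class(df) <- c("context_triggers", "data.frame")
  df
}

default_triggers_cache <- new.env(parent = emptyenv())

default_triggers <- function() {
  if (is.null(default_triggers_cache$base)) {
    default_triggers_cache$base <- load_triggers()
  }
  default_triggers_cache$base
}

# All matches of every trigger phrase against a token sequence.
match_triggers <- function(toks_low, triggers) {
  comp <- attr(triggers, "compiled")
  out <- NULL
  for (i in seq_len(nrow(triggers))) {
    mm <- match_phrase(toks_low, comp[[i]])
    for (r in seq_len(nrow(mm))) {
      out <- rbind(out, data.frame(
        idx = i, phrase = triggers$phrase[i], property = triggers$property[i],
        direction = triggers$direction[i], action = triggers$action[i],
        first = mm[r, "first"], last = mm[r, "last"],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(idx = integer(), phrase = character(),
                      property = character(), direction = character(),
                      action = character(), first = integer(),
                      last = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Assign contextual properties to a candidate instance
#'
#' Scans the instance's sentence for trigger phrases and returns the ConText
#' flags for its keyword span: `negated`, `experiencer` (patient/other) and
#' `temporality` (recent/historical/hypothetical), together with the trigger
#' matches that justify every non-default flag.
#'
#' @param instance a `candidate_instance` from [build_instances].
#' @param triggers a trigger table from [load_triggers]; the shipped base
#'   table by default.
#' @return object of class `context_flags`.
#' @export
apply_context <- function(instance, triggers = default_triggers()) {
  stopifnot(inherits(instance, "candidate_instance"))
  toks_low <- tolower(instance$sentence$tokens$text)
  n <- length(toks_low)
  kw <- c(instance$keyword$first, instance$keyword$last)
  tm <- match_triggers(toks_low, triggers)

  # pseudo-negation spans block negation triggers contained in them
  pseudo <- tm[tm$property == "pseudo_negation" & tm$action == "set", , drop = FALSE]
  blocked <- function(row) {
    if (row$property != "negation") return(FALSE)
    any(pseudo$first <= row$first & pseudo$last >= row$last)
  }

  term_spans <- function(prop) {
    tm[tm$action == "terminate" & tm$property == prop, , drop = FALSE]
  }

  applies <- function(row) {
    if (row$action != "set") return(NULL)
    trm <- term_spans(row$property)
    scopes <- list()
    if (row$direction %in% c("forward", "both")) {
      lo <- row$last + 1L
      hi <- n
      cuts <- trm$first[trm$first > row$last]
      if (length(cuts)) hi <- min(cuts) - 1L
      if (lo <= hi) scopes[[length(scopes) + 1L]] <- c(lo, hi)
    }
    if (row$direction %in% c("backward", "both")) {
      lo <- 1L
      hi <- row$first - 1L
      cuts <- trm$last[trm$last < row$first]
      if (length(cuts)) lo <- max(cuts) + 1L
      if (lo <= hi) scopes[[length(scopes) + 1L]] <- c(lo, hi)
    }
    for (sc in scopes) {
      if (kw[1] >= sc[1] && kw[2] <= sc[2]) return(sc)
    }
    NULL
  }

  fired <- data.frame(phrase = character(), property = character(),
                      first = integer(), last = integer(),
                      scope_first = integer(), scope_last = integer(),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(tm))) {
    row <- tm[r, ]
    if (row$action != "set" || row$property == "pseudo_negation") next
    if (blocked(row)) next
    sc <- applies(row)
    if (!is.null(sc)) {
      fired <- rbind(fired, data.frame(
        phrase = row$phrase, property = row$property,
        first = row$first, last = row$last,
        scope_first = sc[1], scope_last = sc[2], stringsAsFactors = FALSE))
    }
  }

  negated <- any(fired$property == "negation")
  experiencer <- if (any(fired$property == "experiencer")) "other" else "patient"
  temporality <- if (any(fired$property == "hypothetical")) "hypothetical"
                 else if (any(fired$property == "historical")) "historical"
                 else "recent"
  structure(list(negated = negated, experiencer = experiencer,
                 temporality = temporality, triggers = fired),
            class = "context_flags")
}

#' @export
print.context_flags <- function(x, ...) {
  cat("<context_flags> negated=", x$negated, " experiencer=", x$experiencer,
      " temporality=", x$temporality, "\n", sep = "")
  if (nrow(x$triggers)) {
    cat("  triggers: ",
        paste(x$triggers$phrase, " (", x$triggers$property, ")",
              sep = "", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Fill context flags on a list of instances
#'
#' @param instances list of `candidate_instance`.
#' @param triggers trigger table; shipped base table by default.
#' @return the instances, each with `$context` set.
#' @export
add_context <- function(instances, triggers = default_triggers()) {
  lapply(instances, function(x) {
    x$context <- apply_context(x, triggers)
    x
  })
}

#' Rule-only label from context flags
#'
#' The rules-alone arm of the evaluation: an instance is positive iff it is
#' not negated, the experiencer is the patient and the temporality is not
#' hypothetical; otherwise negative.
#'
#' @param flags a `context_flags` object.
#' @return `"positive"` or `"negative"`.
#' @export
context_only_label <- function(flags) {
  stopifnot(inherits(flags, "context_flags"))
  if (!flags$negated && flags$experiencer == "patient" &&
      flags$temporality != "hypothetical") "positive" else "negative"
}
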