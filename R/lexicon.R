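# ---- phrase patterns --------------------------------------------------------

#' Parse a phrase pattern into token patterns
#'
#' A phrase pattern is a space-separated sequence of token patterns. A token
#' pattern ending in `*` matches any token sharing that prefix; otherwise the
#' token must match exactly. Matching is case-insensitive (patterns are stored
#' lower-cased).
#'
#' @param phrase character scalar, e.g. `"flight of idea*"`.
#' @return character vector of token patterns (lower-cased).
#' @export
parse_phrase <- function(phrase) {
  phrase <- tolower(trimws(phrase))
  toks <- strsplit(phrase, "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    stop("empty phrase pattern", call. = FALSE)
  }
  bad <- grepl("\\*", sub("\\*$", "", toks))
  if (any(bad)) {
    stop("'*' may appear only at the end of a token pattern: ",
         paste(toks[bad], collapse = ", "), call. = FALSE)
  }
  if (any(toks == "*")) {
    stop("a token pattern must have at least one literal character before '*'",
         call. = FALSE)
  }
  toks
}

parse_phrase_list <- function(field) {
  field <- trimws(field)
  if (is.na(field) || !nzchar(field)) return(list())
  lapply(strsplit(field, "\\|")[[1]], parse_phrase)
}

phrase_to_string <- function(toks) paste(toks, collapse = " ")

# ---- SymptomConcept ---------------------------------------------------------

CONCEPT_STATUSES <- c("ml_model", "keyword_only", "hand_annotate", "excluded")
SYMPTOM_DOMAINS <- c("positive", "negative", "disorganisation", "manic", "catatonic")
MODIFIER_MODES <- c("none", "optional", "mandatory")

#' Construct a symptom concept
#'
#' One row of the symptom lexicon: a named clinical construct with its keyword
#' phrase patterns, optional modifier patterns and modifier mode, SNOMED-CT
#' identifiers, symptom domain and modelling status.
#'
#' @param name concept label, unique within a lexicon.
#' @param keyword_patterns list of token-pattern vectors (see [parse_phrase]).
#' @param modifier_patterns list of token-pattern vectors; may be empty.
#' @param modifier_mode one of `"none"`, `"optional"`, `"mandatory"`. Must be
#'   `"none"` exactly when `modifier_patterns` is empty.
#' @param snomed_ids character vector of SNOMED-CT SCTIDs (possibly empty).
#' @param domain one of the five symptom domains, or `NA` for excluded
#'   concepts.
#' @param status one of `"ml_model"`, `"keyword_only"`, `"hand_annotate"`,
#'   `"excluded"`.
#' @return an object of class `symptom_concept`.
#' @export
symptom_concept <- function(name, keyword_patterns, modifier_patterns = list(),
                            modifier_mode = "none", snomed_ids = character(),
                            domain = NA_character_, status = "ml_model") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(keyword_patterns) || length(keyword_patterns) == 0L) {
    stop("concept '", name, "': needs at least one keyword pattern", call. = FALSE)
  }
  modifier_mode <- match.arg(modifier_mode, MODIFIER_MODES)
  status <- match.arg(status, CONCEPT_STATUSES)
  if ((modifier_mode == "none") != (length(modifier_patterns) == 0L)) {
    stop("concept '", name, "': modifier_mode must be 'none' iff there are no ",
         "modifier patterns", call. = FALSE)
  }
  if (!is.na(domain)) domain <- match.arg(domain, SYMPTOM_DOMAINS)
  if (status != "excluded" && is.na(domain)) {
    stop("concept '", name, "': non-excluded concepts must have a domain",
         call. = FALSE)
  }
  structure(
    list(name = name,
         keyword_patterns = keyword_patterns,
         modifier_patterns = modifier_patterns,
         modifier_mode = modifier_mode,
         snomed_ids = snomed_ids,
         domain = domain,
         status = status),
    class = "symptom_concept")
}

#' @export
print.symptom_concept <- function(x, ...) {
  cat("<symptom_concept> ", x$name, " [", x$status, "]\n", sep = "")
  cat("  keywords: ", paste(vapply(x$keyword_patterns, phrase_to_string, ""),
                            collapse = " | "), "\n", sep = "")
  if (length(x$modifier_patterns)) {
    cat("  modifiers (", x$modifier_mode, "): ",
        paste(vapply(x$modifier_patterns, phrase_to_string, ""),
              collapse = " | "), "\n", sep = "")
  }
  cat("  domain: ", ifelse(is.na(x$domain), "(none)", x$domain), "\n", sep = "")
  invisible(x)
}

# ---- Lexicon ----------------------------------------------------------------

#' Construct a validated lexicon
#'
#' @param concepts list of [symptom_concept] objects.
#' @param version identifier string for this lexicon edition.
#' @return object of class `smi_lexicon`.
#' @export
smi_lexicon <- function(concepts, version = "custom") {
  stopifnot(is.list(concepts), length(concepts) > 0L)
  ok <- vapply(concepts, inherits, TRUE, what = "symptom_concept")
  if (!all(ok)) stop("all elements must be symptom_concept objects", call. = FALSE)
  nms <- vapply(concepts, `[[`, "", "name")
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop("duplicate concept name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(concepts) <- nms
  structure(list(concepts = concepts, version = version), class = "smi_lexicon")
}

#' @export
print.smi_lexicon <- function(x, ...) {
  st <- table(factor(vapply(x$concepts, `[[`, "", "status"),
                     levels = CONCEPT_STATUSES))
  cat("<smi_lexicon> ", x$version, ": ", length(x$concepts), " concepts (",
      paste(names(st), st, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Concept names in a lexicon
#' @param lexicon an `smi_lexicon`.
#' @param status optional status filter.
#' @return character vector of concept labels.
#' @export
concept_names <- function(lexicon, status = NULL) {
  stopifnot(inherits(lexicon, "smi_lexicon"))
  nms <- names(lexicon$concepts)
  if (!is.null(status)) {
    keep <- vapply(lexicon$concepts, `[[`, "", "status") %in% status
    nms <- nms[keep]
  }
  nms
}

#' Load a symptom lexicon from TSV
#'
#' Reads the tab-separated lexicon dialect: columns `concept`, `keywords`
#' (|-separated phrases), `modifiers` (|-separated, may be empty),
#' `modifier_mode` (none/optional/mandatory), `snomed_ids` (comma-separated),
#' `domain`, `status`; UTF-8; `#` comment lines ignored. All patterns are
#' lower-cased on load.
#'
#' @param path path to the TSV file.
#' @param version version label; defaults to the file name without extension.
#' @return a validated [smi_lexicon].
#' @export
load_lexicon <- function(path, version = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty lexicon file: ", path, call. = FALSE)
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("concept", "keywords", "modifiers", "modifier_mode",
                "snomed_ids", "domain", "status")
  if (!identical(trimws(header), expected)) {
    stop("lexicon header must be: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  body <- keep[-1]
  if (length(body) == 0L) stop("lexicon file has no concept rows: ", path,
                               call. = FALSE)
  concepts <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    length(fields) <- 7L                      # pad trailing empties
    fields[is.na(fields)] <- ""
    if (!nzchar(trimws(fields[1])) || !nzchar(trimws(fields[2]))) {
      stop("malformed lexicon row at line ", ln, ": concept and keywords are ",
           "required", call. = FALSE)
    }
    concepts[[i]] <- tryCatch(
      symptom_concept(
        name = trimws(fields[1]),
        keyword_patterns = parse_phrase_list(fields[2]),
        modifier_patterns = parse_phrase_list(fields[3]),
        modifier_mode = ifelse(nzchar(trimws(fields[4])), trimws(fields[4]), "none"),
        snomed_ids = {
          ids <- trimws(strsplit(fields[5], ",")[[1]])
          ids[nzchar(ids)]
        },
        domain = ifelse(nzchar(trimws(fields[6])), trimws(fields[6]), NA_character_),
        status = ifelse(nzchar(trimws(fields[7])), trimws(fields[7]), "ml_model")),
      error = function(e) {
        stop("lexicon parse error at line ", ln, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  if (is.null(version)) version <- sub("\\.[^.]*$", "", basename(path))
  smi_lexicon(concepts, version = version)
}

#' Write a lexicon back to TSV
#'
#' Inverse of [load_lexicon]; `load_lexicon(write_lexicon(x, f))` reproduces
#' `x` (round-trip property).
#'
#' @param lexicon an [smi_lexicon].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "smi_lexicon"))
  fmt_patterns <- function(pats) {
    paste(vapply(pats, phrase_to_string, ""), collapse = "|")
  }
  rows <- vapply(lexicon$concepts, function(cc) {
    paste(cc$name, fmt_patterns(cc$keyword_patterns),
          fmt_patterns(cc$modifier_patterns), cc$modifier_mode,
          paste(cc$snomed_ids, collapse = ","),
          ifelse(is.na(cc$domain), "", cc$domain), cc$status, sep = "\t")
  }, "")
  writeLines(c(paste(c("concept", "keywords", "modifiers", "modifier_mode",
                       "snomed_ids", "domain", "status"), collapse = "\t"),
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Load one of the shipped lexicon editions
#'
#' Two editions ship with the package: `"curated"` (default; keyword stems
#' adjusted where the worked examples use a broader wildcard, e.g.
#' `hallucinat*`) and `"table1_verbatim"` (exact transcription of the printed
#' keyword table, e.g. `hallucinate*`).
#'
#' @param edition `"curated"` or `"table1_verbatim"`.
#' @return a validated [smi_lexicon] with 50 concepts.
#' @export
default_lexicon <- function(edition = c("curated", "table1_verbatim")) {
  edition <- match.arg(edition)
  path <- system.file("extdata", paste0("lexicon_", edition, ".tsv"),
                      package = "smisym", mustWork = TRUE)
  load_lexicon(path, version = edition)
}

#' Compile a concept's phrase patterns into matchers
#'
#' Each phrase pattern becomes a matcher over token sequences: matching is
#' case-insensitive, a trailing `*` on a token pattern means prefix match,
#' otherwise the token must match exactly.
#'
#' @param concept a [symptom_concept].
#' @return list with `keywords` and `modifiers`, each a list of compiled
#'   patterns (`tokens`, `prefix` flags, `string`).
#' @export
compile_patterns <- function(concept) {
  stopifnot(inherits(concept, "symptom_concept"))
  compile_one <- function(toks) {
    prefix <- grepl("\\*$", toks)
    list(tokens = sub("\\*$", "", toks), prefix = prefix,
         string = phrase_to_string(toks))
  }
  list(keywords = lapply(concept$keyword_patterns, compile_one),
       modifiers = lapply(concept$modifier_patterns, compile_one))
}

#' Match one compiled phrase pattern against a token sequence
#'
#' @param tokens_lower character vector of lower-cased tokens.
#' @param pattern one compiled pattern from [compile_patterns].
#' @return integer matrix with columns `first`, `last` (1-based token indices),
#'   one row per match; zero rows when there is no match.
#' @export
match_phrase <- function(tokens_lower, pattern) {
  np <- length(pattern$tokens)
  nt <- length(tokens_lower)
  out <- NULL
  if (nt >= np) {
    for (s in seq_len(nt - np + 1L)) {
      ok <- TRUE
      for (j in seq_len(np)) {
        tok <- tokens_lower[s + j - 1L]
        pat <- pattern$tokens[j]
        if (pattern$prefix[j]) {
          if (!startsWith(tok, pat)) { ok <- FALSE; break }
        } else if (tok != pat) { ok <- FALSE; break }
      }
      if (ok) out <- rbind(out, c(s, s + np - 1L))
    }
  }
  if (is.null(out)) out <- matrix(integer(), ncol = 2L)
  colnames(out) <- c("first", "last")
  out
}

#' Domain of a concept
#'
#' Looks up the symptom-domain grouping (positive, negative, disorganisation,
#' manic, catatonic) of a named concept.
#'
#' @param lexicon an [smi_lexicon].
#' @param name concept label.
#' @return domain label (character scalar).
#' @export
domain_of <- function(lexicon, name) {
  stopifnot(inherits(lexicon, "smi_lexicon"))
  cc <- lexicon$concepts[[name]]
  if (is.null(cc)) stop("unknown concept: '", name, "'", call. = FALSE)
  if (is.na(cc$domain)) {
    stop("concept '", name, "' has no domain assignment (status: ",
         cc$status, ")", call. = FALSE)
  }
  cc$domain
}
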