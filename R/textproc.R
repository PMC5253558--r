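# Sentence segmentation, tokenization and candidate-instance construction.
#
# The unit of classification is the sentence: a candidate instance is a
# sentence containing a symptom keyword (plus, for mandatory-modifier
# concepts, at least one modifier within the eight-word window). All
# character offsets are 0-based half-open into the original document, so
# `substr(text, start + 1, end)` reconstructs any span exactly.

# ---- tokenization -----------------------------------------------------------

#' Tokenize text with character offsets
#'
#' Splits on whitespace, then strips leading/trailing punctuation characters
#' into separate single-character tokens; hyphenated words and internal
#' apostrophes are kept whole.
#'
#' @param text character scalar.
#' @param base integer, character offset of `text[1]` within the document
#'   (0-based).
#' @return data.frame with columns `text`, `start`, `end` (0-based half-open),
#'   `index` (1-based position), `is_word` (contains a letter or digit) and
#'   `pos` (coarse part-of-speech tag).
#' @export
tokenize <- function(text, base = 0L) {
  out_text <- character()
  out_start <- integer()
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      chunk <- substr(text, m[k], m[k] + lens[k] - 1L)
      off <- m[k] - 1L            # 0-based offset of chunk within text
      chars <- strsplit(chunk, "")[[1]]
      is_an <- grepl("[[:alnum:]]", chars)
      if (!any(is_an)) {          # punctuation-only chunk: one token per char
        out_text <- c(out_text, chars)
        out_start <- c(out_start, off + seq_along(chars) - 1L)
        next
      }
      lead <- which(is_an)[1] - 1L
      trail <- length(chars) - max(which(is_an))
      core_from <- lead + 1L
      core_to <- length(chars) - trail
      if (lead > 0L) {
        out_text <- c(out_text, chars[seq_len(lead)])
        out_start <- c(out_start, off + seq_len(lead) - 1L)
      }
      out_text <- c(out_text, paste(chars[core_from:core_to], collapse = ""))
      out_start <- c(out_start, off + core_from - 1L)
      if (trail > 0L) {
        idx <- (core_to + 1L):length(chars)
        out_text <- c(out_text, chars[idx])
        out_start <- c(out_start, off + idx - 1L)
      }
    }
  }
  n <- length(out_text)
  df <- data.frame(text = out_text,
                   start = base + out_start,
                   end = base + out_start + nchar(out_text),
                   index = seq_len(n),
                   stringsAsFactors = FALSE)
  df$is_word <- grepl("[[:alnum:]]", df$text)
  df$pos <- pos_tag(df$text)
  df
}

# Closed-class word lists for the coarse tagger. Tags feed classifier
# features only; they never gate keyword or trigger matching.
.POS_DET <- c("the", "a", "an", "this", "that", "these", "those", "some",
              "any", "no", "each", "every", "his", "her", "their", "its", "my",
              "our", "your")
.POS_PRON <- c("he", "she", "it", "they", "i", "we", "you", "him", "them",
               "himself", "herself", "who", "which", "there")
.POS_ADP <- c("of", "in", "on", "at", "by", "for", "with", "to", "from",
              "about", "into", "over", "during", "without", "within", "after",
              "before", "between", "towards", "against")
.POS_CONJ <- c("and", "or", "but", "nor", "so", "yet", "because", "although",
               "while", "if", "when", "however", "though")
.POS_AUX <- c("is", "are", "was", "were", "be", "been", "being", "am", "has",
              "have", "had", "do", "does", "did", "will", "would", "can",
              "could", "may", "might", "shall", "should", "must")

#' Coarse part-of-speech tags
#'
#' A small closed-class + suffix heuristic tagger over the tagset
#' PUNCT/NUM/DET/PRON/ADP/CONJ/AUX/ADV/VERB/ADJ/NOUN. Deterministic and
#' context-free; intended only as a feature source for the sentence
#' classifier.
#'
#' @param tokens character vector of token strings.
#' @return character vector of tags, same length.
#' @export
pos_tag <- function(tokens) {
  low <- tolower(tokens)
  tag <- rep("NOUN", length(tokens))
  tag[!grepl("[[:alnum:]]", tokens)] <- "PUNCT"
  num <- grepl("^[0-9][0-9.,/-]*$", tokens)
  tag[num] <- "NUM"
  open <- tag == "NOUN"
  tag[open & low %in% .POS_DET] <- "DET"
  open <- tag == "NOUN"
  tag[open & low %in% .POS_PRON] <- "PRON"
  open <- tag == "NOUN"
  tag[open & low %in% .POS_ADP] <- "ADP"
  open <- tag == "NOUN"
  tag[open & low %in% .POS_CONJ] <- "CONJ"
  open <- tag == "NOUN"
  tag[open & low %in% .POS_AUX] <- "AUX"
  open <- tag == "NOUN"
  tag[open & grepl("ly$", low) & nchar(low) > 3] <- "ADV"
  open <- tag == "NOUN"
  tag[open & grepl("(ing|ed)$", low) & nchar(low) > 4] <- "VERB"
  open <- tag == "NOUN"
  tag[open & grepl("(ous|ive|able|ible|al|ful)$", low) & nchar(low) > 4] <- "ADJ"
  tag
}

# ---- sentence segmentation --------------------------------------------------

#' Segment a document into sentences
#'
#' Boundaries are placed after runs of sentence-final punctuation (`.`, `!`,
#' `?`, optionally followed by closing quotes/brackets) and at hard line
#' breaks. Offsets are 0-based half-open into the original text, so every
#' sentence slices back to its exact source substring. Text with no terminal
#' punctuation yields a single sentence.
#'
#' @param text document string.
#' @param doc_id document identifier attached to each sentence.
#' @return list of `smi_sentence` objects (possibly empty for blank text),
#'   each with `doc_id`, `start`, `end`, `text` and a token table from
#'   [tokenize].
#' @export
segment_sentences <- function(text, doc_id = "doc") {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(list())
  n <- nchar(text)
  breaks <- integer()                      # 0-based offsets AFTER which to cut
  m <- gregexpr("[.!?]+[\"')\\]]*", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    ends <- m + attr(m, "match.length") - 1L   # 1-based last char of run
    nxt <- substr(text, ends + 1L, ends + 1L)
    ok <- ends == n | grepl("^\\s$", nxt)
    breaks <- c(breaks, ends[ok])
  }
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (nl[1] != -1L) breaks <- c(breaks, nl)
  breaks <- sort(unique(c(breaks, n)))
  out <- list()
  from <- 1L
  for (b in breaks) {
    if (b < from) next
    raw <- substr(text, from, b)
    # trim whitespace, keeping offsets exact
    lead <- regmatches(raw, regexpr("^\\s*", raw))
    trail <- regmatches(raw, regexpr("\\s*$", raw))
    s0 <- from + nchar(lead) - 1L           # 0-based start
    e0 <- b - nchar(trail)                  # 0-based end (half-open)
    if (e0 > s0) {
      stext <- substr(text, s0 + 1L, e0)
      toks <- tokenize(stext, base = s0)
      out[[length(out) + 1L]] <- structure(
        list(doc_id = doc_id, start = s0, end = e0, text = stext,
             tokens = toks),
        class = "smi_sentence")
    }
    from <- b + 1L
  }
  out
}

#' @export
print.smi_sentence <- function(x, ...) {
  cat("<smi_sentence> [", x$doc_id, " ", x$start, ":", x$end, "] ",
      substr(x$text, 1, 60), if (nchar(x$text) > 60) "...", "\n", sep = "")
  invisible(x)
}

# ---- keyword and modifier matching ------------------------------------------

compiled_lexicon <- function(lexicon) {
  if (!is.null(attr(lexicon, "compiled"))) return(attr(lexicon, "compiled"))
  lapply(lexicon$concepts, compile_patterns)
}

#' Pre-compile a lexicon's patterns
#'
#' Optional; [match_keywords] and [build_instances] compile on the fly, but a
#' pre-compiled lexicon avoids recompiling for every document.
#'
#' @param lexicon an [smi_lexicon].
#' @return the lexicon with compiled matchers attached.
#' @export
compile_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "smi_lexicon"))
  attr(lexicon, "compiled") <- lapply(lexicon$concepts, compile_patterns)
  lexicon
}

#' Find keyword matches in a sentence
#'
#' Returns every match of every (by default non-excluded) concept's keyword
#' patterns against the sentence's tokens. Within one concept, overlapping
#' matches are resolved leftmost-longest (one match per locus); matches from
#' distinct concepts are never deduplicated against each other, so shared
#' keywords yield one match per concept.
#'
#' @param sentence an `smi_sentence`.
#' @param lexicon an [smi_lexicon] (pre-compiled or not).
#' @param include_excluded also match concepts with status `"excluded"`.
#' @return data.frame with columns `concept`, `first`, `last` (token indices),
#'   `matched_text`.
#' @export
match_keywords <- function(sentence, lexicon, include_excluded = FALSE) {
  stopifnot(inherits(sentence, "smi_sentence"), inherits(lexicon, "smi_lexicon"))
  comp <- compiled_lexicon(lexicon)
  toks_low <- tolower(sentence$tokens$text)
  res_concept <- character(); res_first <- integer(); res_last <- integer()
  for (nm in names(lexicon$concepts)) {
    cc <- lexicon$concepts[[nm]]
    if (!include_excluded && cc$status == "excluded") next
    hits <- NULL
    for (pat in comp[[nm]]$keywords) {
      mm <- match_phrase(toks_low, pat)
      if (nrow(mm)) hits <- rbind(hits, mm)
    }
    if (is.null(hits) || nrow(hits) == 0L) next
    # leftmost-longest, non-overlapping within this concept
    ord <- order(hits[, "first"], -(hits[, "last"] - hits[, "first"]))
    hits <- hits[ord, , drop = FALSE]
    taken_up_to <- 0L
    for (r in seq_len(nrow(hits))) {
      if (hits[r, "first"] > taken_up_to) {
        res_concept <- c(res_concept, nm)
        res_first <- c(res_first, hits[r, "first"])
        res_last <- c(res_last, hits[r, "last"])
        taken_up_to <- hits[r, "last"]
      }
    }
  }
  data.frame(concept = res_concept, first = res_first, last = res_last,
             matched_text = vapply(seq_along(res_first), function(i) {
               paste(sentence$tokens$text[res_first[i]:res_last[i]],
                     collapse = " ")
             }, ""),
             stringsAsFactors = FALSE)
}

# Count word tokens (tokens containing a letter or digit) strictly between
# two token spans; punctuation-only tokens do not count towards the window.
intervening_words <- function(tokens, span_a, span_b) {
  if (span_a[1] > span_b[2]) { tmp <- span_a; span_a <- span_b; span_b <- tmp }
  if (span_b[1] <= span_a[2]) return(0L)    # overlapping/adjacent spans
  between <- seq_len(nrow(tokens)) > span_a[2] & seq_len(nrow(tokens)) < span_b[1]
  sum(tokens$is_word[between])
}

#' Attach modifier matches within the eight-word window
#'
#' A modifier attaches to a keyword match iff it matches within the same
#' sentence and the number of intervening word tokens between the nearest
#' edges of the two spans is at most eight (either direction).
#' Punctuation-only tokens do not count towards the window.
#'
#' @param match one row of [match_keywords] output (list or 1-row data.frame
#'   with `first`, `last`).
#' @param sentence the `smi_sentence` the match belongs to.
#' @param concept the [symptom_concept] whose modifiers to search for.
#' @return data.frame with columns `pattern`, `first`, `last`, `distance`;
#'   zero rows when the concept has no modifier patterns or none qualify.
#' @export
attach_modifiers <- function(match, sentence, concept) {
  stopifnot(inherits(sentence, "smi_sentence"), inherits(concept, "symptom_concept"))
  empty <- data.frame(pattern = character(), first = integer(),
                      last = integer(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (length(concept$modifier_patterns) == 0L) return(empty)
  comp <- compile_patterns(concept)
  toks_low <- tolower(sentence$tokens$text)
  kw_span <- c(match$first, match$last)
  out <- empty
  for (pat in comp$modifiers) {
    mm <- match_phrase(toks_low, pat)
    for (r in seq_len(nrow(mm))) {
      mod_span <- c(mm[r, "first"], mm[r, "last"])
      # a modifier match inside the keyword span is not a modifier of it
      if (mod_span[1] >= kw_span[1] && mod_span[2] <= kw_span[2]) next
      d <- intervening_words(sentence$tokens, kw_span, mod_span)
      if (d <= 8L) {
        out <- rbind(out, data.frame(pattern = pat$string,
                                     first = mod_span[1], last = mod_span[2],
                                     distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# ---- candidate instances ----------------------------------------------------

new_candidate_instance <- function(doc_id, sentence, concept_name, match,
                                   modifiers) {
  structure(
    list(doc_id = doc_id,
         sentence = sentence,
         concept = concept_name,
         keyword = list(first = match$first, last = match$last,
                        matched_text = match$matched_text,
                        start = sentence$tokens$start[match$first],
                        end = sentence$tokens$end[match$last]),
         modifiers = modifiers,
         context = NULL),
    class = "candidate_instance")
}

#' @export
print.candidate_instance <- function(x, ...) {
  cat("<candidate_instance> ", x$concept, " @ ", x$doc_id, " [",
      x$sentence$start, ":", x$sentence$end, "] '", x$keyword$matched_text,
      "'", sep = "")
  if (nrow(x$modifiers)) {
    cat(" + mods(", paste(x$modifiers$pattern, collapse = ","), ")", sep = "")
  }
  if (!is.null(x$context)) {
    cat(" [", if (x$context$negated) "neg" else "aff", "/",
        x$context$experiencer, "/", x$context$temporality, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build candidate instances for a document
#'
#' Segments the document, matches keywords and attaches modifiers, and emits
#' one candidate instance per (sentence, concept, keyword locus) where the
#' instance definition is met: mandatory-modifier concepts require at least
#' one attached modifier, optional/none concepts require only the keyword.
#' Instances for different concepts may share a sentence.
#'
#' @param text document text.
#' @param doc_id document identifier.
#' @param lexicon an [smi_lexicon] (pre-compiling with [compile_lexicon] is
#'   recommended for corpora).
#' @param include_excluded also build instances for excluded concepts.
#' @return list of `candidate_instance` objects (possibly empty).
#' @export
build_instances <- function(text, doc_id, lexicon, include_excluded = FALSE) {
  sentences <- segment_sentences(text, doc_id = doc_id)
  out <- list()
  for (sent in sentences) {
    km <- match_keywords(sent, lexicon, include_excluded = include_excluded)
    for (r in seq_len(nrow(km))) {
      cc <- lexicon$concepts[[km$concept[r]]]
      mods <- attach_modifiers(km[r, ], sent, cc)
      if (cc$modifier_mode == "mandatory" && nrow(mods) == 0L) next
      out[[length(out) + 1L]] <- new_candidate_instance(
        doc_id, sent, cc$name, km[r, ], mods)
    }
  }
  out
}

#' Flatten candidate instances to a data.frame
#'
#' One row per instance, carrying spans (token indices and 0-based half-open
#' character offsets), modifier count and context flags (NA until
#' [apply_context] has been run).
#'
#' @param instances list of `candidate_instance`.
#' @return data.frame keyed by (`doc_id`, `sent_start`, `sent_end`, `concept`,
#'   `kw_start`).
#' @export
instances_to_df <- function(instances) {
  if (length(instances) == 0L) {
    return(data.frame(doc_id = character(), concept = character(),
                      sent_start = integer(), sent_end = integer(),
                      kw_first = integer(), kw_last = integer(),
                      kw_start = integer(), kw_end = integer(),
                      matched_text = character(), n_modifiers = integer(),
                      negated = logical(), experiencer = character(),
                      temporality = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(instances, function(x) {
    ctx <- x$context
    data.frame(doc_id = x$doc_id, concept = x$concept,
               sent_start = x$sentence$start, sent_end = x$sentence$end,
               kw_first = x$keyword$first, kw_last = x$keyword$last,
               kw_start = x$keyword$start, kw_end = x$keyword$end,
               matched_text = x$keyword$matched_text,
               n_modifiers = nrow(x$modifiers),
               negated = if (is.null(ctx)) NA else ctx$negated,
               experiencer = if (is.null(ctx)) NA_character_ else ctx$experiencer,
               temporality = if (is.null(ctx)) NA_character_ else ctx$temporality,
               stringsAsFactors = FALSE)
  }))
}

# ---- corpus IO --------------------------------------------------------------

#' Read a line-delimited JSON corpus
#'
#' Each line is a JSON record with fields `doc_id`, `patient_id`, `doc_type`,
#' `date`, `icd10_codes` (array) and `text`.
#'
#' @param path file path.
#' @return data.frame with one row per document; `icd10_codes` is a list
#'   column.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    doc_id = vapply(recs, `[[`, "", "doc_id"),
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    doc_type = vapply(recs, `[[`, "", "doc_type"),
    date = vapply(recs, `[[`, "", "date"),
    icd10_codes = I(lapply(recs, function(r) as.character(r$icd10_codes))),
    text = vapply(recs, `[[`, "", "text"),
    stringsAsFactors = FALSE)
}

#' Write a corpus as line-delimited JSON
#'
#' @param corpus data.frame as returned by [read_corpus].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(doc_id = corpus$doc_id[i], patient_id = corpus$patient_id[i],
                doc_type = corpus$doc_type[i], date = corpus$date[i],
                icd10_codes = as.character(corpus$icd10_codes[[i]]),
                text = corpus$text[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write candidate instances as line-delimited JSON for audit
#'
#' @param instances list of `candidate_instance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  df <- instances_to_df(instances)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  }
  invisible(path)
}
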