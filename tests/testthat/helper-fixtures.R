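# Shared fixtures: tiny in-code lexicons, a random-sentence generator and a
# brute-force instance oracle that enumerates all contiguous token
# subsequences against all patterns (kept deliberately naive and independent
# of the production matcher).

tiny_lexicon <- function() {
  smi_lexicon(list(
    symptom_concept("Hallucinations", list(c("hallucinat*")),
                    list(c("audit*"), c("visual*")), "optional",
                    domain = "positive"),
    symptom_concept("Pressured speech", list(c("speech*")),
                    list(c("pressure*")), "mandatory", domain = "manic"),
    symptom_concept("Thought block", list(c("though*", "block")),
                    domain = "disorganisation"),
    symptom_concept("Waxy flexibility", list(c("waxy")),
                    domain = "catatonic")),
    version = "tiny")
}

one_sentence <- function(text, doc_id = "doc") {
  s <- segment_sentences(text, doc_id)
  stopifnot(length(s) == 1L)
  s[[1]]
}

first_instance <- function(text, lexicon = default_lexicon(),
                           concept = NULL, doc_id = "doc") {
  inst <- build_instances(text, doc_id, lexicon)
  if (!is.null(concept)) {
    inst <- Filter(function(x) x$concept == concept, inst)
  }
  stopifnot(length(inst) >= 1L)
  inst[[1]]
}

instance_with_context <- function(text, lexicon = default_lexicon(),
                                  concept = NULL,
                                  triggers = load_triggers()) {
  x <- first_instance(text, lexicon, concept)
  x$context <- apply_context(x, triggers)
  x
}

# labelled training set over the full feature pipeline (affirmed vs negated
# by default: linearly separable via the trigger n-grams)
classifier_fixture <- function(n_patients = 60, seed = 11,
                               mix = c(affirmed = 0.5, negated = 0.5,
                                       hypothetical = 0, other_experiencer = 0,
                                       irrelevant_homograph = 0)) {
  cfg <- generator_config(n_patients = n_patients, docs_min = 2, docs_max = 2,
                          concepts = "Paranoia", mention_rate = 1.0,
                          context_mix = mix, seed = seed)
  make_training_set(generate_corpus(cfg), "Paranoia")
}

# vocabulary pool for random sentences: lexicon stems and realized forms,
# modifiers, plain filler words and punctuation
oracle_token_pool <- function(lexicon) {
  stems <- unlist(lapply(lexicon$concepts, function(cc) {
    sub("\\*$", "", unlist(c(cc$keyword_patterns, cc$modifier_patterns)))
  }))
  realized <- paste0(stems, "s")
  fillers <- c("the", "patient", "was", "and", "with", "of", "on", "ward",
               "seen", "today", "marked", "some", "very", "poor", "good",
               "review", "team", "plan", "mental", "state")
  unique(c(stems, realized, fillers, ",", ";", "-"))
}

random_sentence_tokens <- function(pool, max_len = 30L) {
  n <- sample(3:max_len, 1L)
  sample(pool, n, replace = TRUE)
}

# naive phrase check: does pattern match tokens[first..] exactly?
oracle_phrase_at <- function(tokens_lower, pattern_tokens, first) {
  stems <- sub("\\*$", "", pattern_tokens)
  prefix <- grepl("\\*$", pattern_tokens)
  last <- first + length(stems) - 1L
  if (last > length(tokens_lower)) return(FALSE)
  for (j in seq_along(stems)) {
    tok <- tokens_lower[first + j - 1L]
    if (prefix[j]) {
      if (substr(tok, 1, nchar(stems[j])) != stems[j]) return(FALSE)
    } else if (tok != stems[j]) return(FALSE)
  }
  TRUE
}

# brute-force instance finder over one sentence's tokens: enumerate every
# (concept, pattern, start); leftmost-longest dedup per concept; apply the
# mandatory-modifier rule with a naive window count
oracle_instances <- function(tokens, lexicon, include_excluded = FALSE) {
  tokens_lower <- tolower(tokens$text)
  is_word <- grepl("[[:alnum:]]", tokens$text)
  out <- list()
  for (nm in names(lexicon$concepts)) {
    cc <- lexicon$concepts[[nm]]
    if (!include_excluded && cc$status == "excluded") next
    cand <- list()
    for (pat in cc$keyword_patterns) {
      for (s in seq_along(tokens_lower)) {
        if (oracle_phrase_at(tokens_lower, pat, s)) {
          cand[[length(cand) + 1L]] <- c(s, s + length(pat) - 1L)
        }
      }
    }
    if (!length(cand)) next
    m <- do.call(rbind, cand)
    m <- m[order(m[, 1], -(m[, 2] - m[, 1])), , drop = FALSE]
    kept <- list(); upto <- 0L
    for (r in seq_len(nrow(m))) {
      if (m[r, 1] > upto) { kept[[length(kept) + 1L]] <- m[r, ]; upto <- m[r, 2] }
    }
    for (kw in kept) {
      n_mods <- 0L
      for (pat in cc$modifier_patterns) {
        for (s in seq_along(tokens_lower)) {
          if (!oracle_phrase_at(tokens_lower, pat, s)) next
          e <- s + length(pat) - 1L
          if (s >= kw[1] && e <= kw[2]) next
          lo <- min(kw[2], e); hi <- max(kw[1], s)
          gap <- if (hi - lo <= 1L) 0L
                 else sum(is_word[(lo + 1L):(hi - 1L)])
          if (gap <= 8L) n_mods <- n_mods + 1L
        }
      }
      if (cc$modifier_mode == "mandatory" && n_mods == 0L) next
      out[[length(out) + 1L]] <- data.frame(concept = nm, first = kw[1],
                                            last = kw[2],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(concept = character(), first = integer(),
                      last = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$concept, df$first), , drop = FALSE]
}

# production-side view of the same sentence for comparing with the oracle
pipeline_instances_keyed <- function(text, lexicon) {
  inst <- build_instances(text, "oracle-doc", lexicon)
  if (!length(inst)) {
    return(data.frame(concept = character(), first = integer(),
                      last = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(concept = vapply(inst, `[[`, "", "concept"),
                   first = vapply(inst, function(x) x$keyword$first, 0L),
                   last = vapply(inst, function(x) x$keyword$last, 0L),
                   stringsAsFactors = FALSE)
  df[order(df$concept, df$first), , drop = FALSE]
}
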