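# Seeded generator of synthetic discharge-summary corpora with planted,
# gold-labelled symptom mentions. Templates are deliberately stylised
# (mental-state-examination phrasing): the generator exists to exercise the
# pipeline's mechanics end to end, not to emulate linguistic generality.
# All randomness flows from one seed, split into independent streams per
# purpose (patient assembly vs per-document planting) so adding a template
# class does not shift other draws.

.TEMPLATES <- list(
  affirmed = c(
    "On examination there was marked %s.",
    "The patient presented with %s.",
    "Mental state examination revealed %s.",
    "Staff observed %s throughout the day.",
    "He described %s during the interview."),
  negated = c(
    "There was no %s.",
    "She denied %s.",
    "No evidence of %s was observed.",
    "He did not display %s.",
    "The assessment was negative for %s."),
  hypothetical = c(
    "Today I examined the patient for %s.",
    "We will monitor for %s at the next review.",
    "Staff will check for %s on the ward.",
    "If %s emerges the team will update the care plan."),
  other_experiencer = c(
    "His mother has experienced %s for many years.",
    "Her brother was described as showing %s.",
    "The family reported %s in the father."),
  irrelevant_homograph = c(
    "The %s management leaflet was filed in the notes.",
    "A copy of the %s policy document was given to the team.",
    "The %s workshop meeting was rescheduled by the office."))

CONTEXT_CLASSES <- names(.TEMPLATES)

.FILLERS <- c(
  "The ward round took place in the morning.",
  "Medication was administered as prescribed.",
  "The patient attended the group session.",
  "Bloods were taken and results are awaited.",
  "The care plan was updated by the nursing team.",
  "Leave was granted for the weekend.",
  "Dietary intake was adequate.",
  "The patient engaged well with occupational therapy.",
  "A community follow-up appointment was arranged.")

# Surface forms for keyword/modifier stems, used only to make generated text
# readable; any stem absent from the map is emitted verbatim (it still
# matches its own prefix pattern).
.SURFACE <- c(
  aggress = "aggression", agitat = "agitation", anhedon = "anhedonia",
  apath = "apathy", arous = "arousal", blunt = "blunted",
  catalep = "catalepsy", catatoni = "catatonia", circumstan = "circumstantial",
  coheren = "coherence", delusion = "delusions", depriv = "deprived",
  derail = "derailment", difficult = "difficult", disturb = "disturbed",
  disorder = "disordered", elat = "elation", elevat = "elevated",
  erratic = "erratic", euphor = "euphoria", flat = "flat",
  grandios = "grandiosity", hallucinat = "hallucinations",
  hallucinate = "hallucinated", hostil = "hostility", idea = "ideas",
  immobil = "immobility", impair = "impaired", impoverish = "impoverished",
  inadequat = "inadequate", insom = "insomnia", interrupt = "interrupted",
  irritabl = "irritable", less = "less", mannerism = "mannerisms",
  audit = "auditory", motivat = "motivation", nightmare = "nightmares",
  olfact = "olfactory", paranoi = "paranoia", persecu = "persecutory",
  persever = "perseveration", poor = "poor", postur = "posturing",
  poverty = "poverty", pressure = "pressured", prevent = "prevented",
  problem = "problematic", reduced = "reduced", restrict = "restricted",
  rigid = "rigidity", social = "social", stereotyp = "stereotyped",
  stop = "stopped", stupor = "stupor", symptom = "symptoms",
  tactil = "tactile", tangent = "tangential", though = "thought",
  unable = "unable", visual = "visual", withdraw = "withdrawal",
  worse = "worse")

realize_pattern <- function(toks) {
  stems <- sub("\\*$", "", toks)
  paste(ifelse(stems %in% names(.SURFACE), .SURFACE[stems], stems),
        collapse = " ")
}

# seed-stream splitting: deterministic sub-seeds below 2^31
sub_seed <- function(seed, purpose, i = 0L) {
  ((as.numeric(seed) %% 97561) * 20011 + purpose * 4099 + i * 7) %% 2147483629 + 1
}

#' Synthetic-corpus generator configuration
#'
#' Defaults define the generator's reference conditions: 60 patients with 1-3
#' discharge summaries each, five concepts spanning the optional, mandatory
#' and no-modifier modes, 0.8 expected mentions per concept per document, a
#' context mix of 50% affirmed / 20% negated / 10% hypothetical / 10%
#' other-experiencer / 10% irrelevant-homograph plants, and a diagnosis mix
#' of 30% F20 / 5% F25 / 15% F31 / 10% Multiple / 40% non-SMI.
#'
#' @param n_patients number of patients.
#' @param docs_min,docs_max documents per patient (uniform integer range).
#' @param concepts concept labels to plant; must exist in the lexicon.
#' @param mention_rate expected planted mentions per concept per document
#'   (Poisson).
#' @param context_mix named proportions over the five context classes
#'   (must sum to 1).
#' @param diagnosis_mix named proportions over diagnosis groups
#'   (must sum to 1).
#' @param seed integer master seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 60L, docs_min = 1L, docs_max = 3L,
                             concepts = c("Hallucinations", "Paranoia",
                                          "Pressured speech", "Disturbed sleep",
                                          "Poor rapport"),
                             mention_rate = 0.8,
                             context_mix = c(affirmed = 0.5, negated = 0.2,
                                             hypothetical = 0.1,
                                             other_experiencer = 0.1,
                                             irrelevant_homograph = 0.1),
                             diagnosis_mix = c(F20 = 0.30, F25 = 0.05,
                                               F31 = 0.15, Multiple = 0.10,
                                               NonSMI = 0.40),
                             seed = 1L) {
  stopifnot(n_patients >= 1L, docs_min >= 1L, docs_max >= docs_min,
            mention_rate >= 0, length(concepts) >= 1L)
  if (!setequal(names(context_mix), CONTEXT_CLASSES)) {
    stop("context_mix must be named over: ",
         paste(CONTEXT_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (any(context_mix < 0) || abs(sum(context_mix) - 1) > 1e-8) {
    stop("context_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (any(diagnosis_mix < 0) || abs(sum(diagnosis_mix) - 1) > 1e-8) {
    stop("diagnosis_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!all(names(diagnosis_mix) %in% DIAGNOSIS_GROUPS)) {
    stop("diagnosis_mix names must be diagnosis groups", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 docs_min = as.integer(docs_min),
                 docs_max = as.integer(docs_max),
                 concepts = concepts,
                 mention_rate = mention_rate,
                 context_mix = context_mix[CONTEXT_CLASSES],
                 diagnosis_mix = diagnosis_mix,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.GROUP_CODES <- list(
  F20 = c("F20.0", "F20.3", "F20.5"),
  F25 = c("F25.0", "F25.1"),
  F31 = c("F31.1", "F31.2", "F31.6"),
  NonSMI = c("F32.1", "F33.0", "F41.2", "F43.1", "F60.3"),
  Unclassified = c("Z00.0"))

sample_codes <- function(group) {
  if (group == "Multiple") {
    fams <- sample(SMI_FAMILIES, 2L)
    vapply(fams, function(f) sample(.GROUP_CODES[[f]], 1L), "")
  } else {
    sample(.GROUP_CODES[[group]], 1L)
  }
}

# Realize the mention phrase for a concept: keyword (one pattern, chosen at
# random) plus a modifier where the concept's mode requires or optionally
# allows one. Modifiers whose surface form is itself a context-trigger token
# (e.g. "not") are never used in plants, so a planted class is produced by
# the template alone.
realize_mention <- function(concept, trigger_tokens) {
  kw <- realize_pattern(concept$keyword_patterns[[
    sample.int(length(concept$keyword_patterns), 1L)]])
  mods <- concept$modifier_patterns
  if (length(mods)) {
    surf <- vapply(mods, realize_pattern, "")
    ok <- !vapply(strsplit(surf, " "), function(t) any(t %in% trigger_tokens),
                  TRUE)
    mods <- mods[ok]; surf <- surf[ok]
  }
  use_mod <- concept$modifier_mode == "mandatory" ||
    (concept$modifier_mode == "optional" && length(mods) &&
       stats::runif(1) < 0.5)
  if (use_mod) {
    if (!length(mods)) stop("no usable modifier for mandatory concept ",
                            concept$name, call. = FALSE)
    m <- sample.int(length(mods), 1L)
    paste(surf[m], kw)
  } else {
    kw
  }
}

#' Generate a synthetic discharge-summary corpus with a gold ledger
#'
#' Emits a corpus in the standard document format plus a ledger recording
#' every planted mention (document, sentence span, concept, planted context
#' class, expected label) and a per-patient truth table of symptoms. Planted
#' sentences are template instantiations using lexicon keywords/modifiers
#' and, for non-affirmed classes, trigger phrases from the shipped context
#' tables; filler sentences contain no lexicon keywords. The expected label
#' is positive iff the planted class is affirmed. Identical config produces
#' an identical corpus.
#'
#' @param config a [generator_config].
#' @param lexicon an [smi_lexicon]; the shipped curated edition by default.
#' @return list of class `synthetic_corpus`: `corpus` (document data.frame),
#'   `ledger` (planted-mention data.frame), `truth` (patient x concept truth
#'   table), `config`.
#' @export
generate_corpus <- function(config, lexicon = default_lexicon()) {
  stopifnot(inherits(config, "generator_config"))
  missing_c <- setdiff(config$concepts, names(lexicon$concepts))
  if (length(missing_c)) {
    stop("concept(s) absent from lexicon: ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  trigger_tokens <- unique(unlist(lapply(
    attr(default_triggers(), "compiled"), `[[`, "tokens")))

  # stream 1: patient assembly (groups, codes, document counts)
  set.seed(sub_seed(config$seed, 1L))
  groups <- sample(names(config$diagnosis_mix), config$n_patients,
                   replace = TRUE, prob = config$diagnosis_mix)
  codes <- lapply(groups, sample_codes)
  n_docs <- config$docs_min +
    sample.int(config$docs_max - config$docs_min + 1L, config$n_patients,
               replace = TRUE) - 1L

  corpus <- list(); ledger <- list(); truth <- list()
  doc_index <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    affirmed_concepts <- character()
    for (d in seq_len(n_docs[p])) {
      doc_index <- doc_index + 1L
      doc_id <- sprintf("D%05d", doc_index)
      # stream 2: per-document planting, seeded by document index only
      set.seed(sub_seed(config$seed, 2L, doc_index))
      plants <- list()
      for (cn in config$concepts) {
        cc <- lexicon$concepts[[cn]]
        k <- stats::rpois(1L, config$mention_rate)
        if (k == 0L) next
        cls <- sample(CONTEXT_CLASSES, k, replace = TRUE,
                      prob = config$context_mix)
        for (cl in cls) {
          tmpl <- sample(.TEMPLATES[[cl]], 1L)
          sent <- sprintf(tmpl, realize_mention(cc, trigger_tokens))
          plants[[length(plants) + 1L]] <- list(concept = cn, class = cl,
                                                sentence = sent)
        }
      }
      fillers <- sample(.FILLERS, 2L + stats::rpois(1L, 1), replace = TRUE)
      slots <- c(rep("plant", length(plants)), rep("filler", length(fillers)))
      ord <- sample(seq_along(slots))
      sentences <- character(length(slots))
      plant_at <- integer(0)
      pi <- 0L; fi <- 0L
      for (s in seq_along(ord)) {
        if (slots[ord[s]] == "plant") {
          pi <- pi + 1L
          sentences[s] <- plants[[pi]]$sentence
          plant_at[pi] <- s
        } else {
          fi <- fi + 1L
          sentences[s] <- fillers[fi]
        }
      }
      starts <- cumsum(c(0L, nchar(sentences) + 1L))[seq_along(sentences)]
      text <- paste(sentences, collapse = " ")
      corpus[[doc_index]] <- data.frame(
        doc_id = doc_id, patient_id = pid, doc_type = "discharge_summary",
        date = sprintf("2013-%02d-15", (doc_index %% 12L) + 1L),
        icd10_codes = I(list(codes[[p]])), text = text,
        stringsAsFactors = FALSE)
      for (j in seq_along(plants)) {
        s <- plant_at[j]
        ledger[[length(ledger) + 1L]] <- data.frame(
          doc_id = doc_id, patient_id = pid,
          sent_start = starts[s], sent_end = starts[s] + nchar(sentences[s]),
          concept = plants[[j]]$concept, class = plants[[j]]$class,
          expected_label = ifelse(plants[[j]]$class == "affirmed",
                                  "positive", "negative"),
          stringsAsFactors = FALSE)
        if (plants[[j]]$class == "affirmed") {
          affirmed_concepts <- union(affirmed_concepts, plants[[j]]$concept)
        }
      }
    }
    if (length(affirmed_concepts)) {
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, concept = sort(affirmed_concepts),
        stringsAsFactors = FALSE)
    }
  }
  empty_ledger <- data.frame(doc_id = character(), patient_id = character(),
                             sent_start = integer(), sent_end = integer(),
                             concept = character(), class = character(),
                             expected_label = character(),
                             stringsAsFactors = FALSE)
  structure(list(corpus = do.call(rbind, corpus),
                 ledger = if (length(ledger)) do.call(rbind, ledger)
                          else empty_ledger,
                 truth = if (length(truth)) do.call(rbind, truth)
                         else data.frame(patient_id = character(),
                                         concept = character(),
                                         stringsAsFactors = FALSE),
                 config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$corpus), " documents, ",
      length(unique(x$corpus$patient_id)), " patients, ",
      nrow(x$ledger), " planted mentions (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Build a human-equivalent training set from a synthetic corpus
#'
#' Runs [build_instances] + [add_context] over the corpus and joins the
#' found instances for one concept to the gold ledger on (document, sentence
#' span, concept). Instances found in the text but absent from the ledger
#' (homograph plants, incidental keyword collisions) are labelled negative.
#'
#' @param sc a `synthetic_corpus`.
#' @param concept concept label to extract.
#' @param lexicon the lexicon the corpus was generated with.
#' @param triggers trigger table for context flags.
#' @return list of [labelled_instance] with `source = "human"`.
#' @export
make_training_set <- function(sc, concept, lexicon = default_lexicon(),
                              triggers = default_triggers()) {
  stopifnot(inherits(sc, "synthetic_corpus"))
  bad <- setdiff(sc$ledger$doc_id, sc$corpus$doc_id)
  if (length(bad)) {
    stop("ledger/corpus mismatch; ledger documents missing from corpus: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  led <- sc$ledger[sc$ledger$concept == concept, , drop = FALSE]
  lk <- paste(led$doc_id, led$sent_start, led$sent_end, sep = "|")
  lexicon <- compile_lexicon(lexicon)
  out <- list()
  for (i in seq_len(nrow(sc$corpus))) {
    inst <- build_instances(sc$corpus$text[i], sc$corpus$doc_id[i], lexicon)
    inst <- Filter(function(x) x$concept == concept, inst)
    if (!length(inst)) next
    inst <- add_context(inst, triggers)
    for (x in inst) {
      key <- paste(x$doc_id, x$sentence$start, x$sentence$end, sep = "|")
      hit <- match(key, lk)
      lab <- if (!is.na(hit)) led$expected_label[hit] else "negative"
      out[[length(out) + 1L]] <- labelled_instance(x, lab, source = "human")
    }
  }
  out
}

#' Fraction of planted mentions recovered as candidate instances
#'
#' A planted mention is recovered when [build_instances] emits an instance
#' for its (document, sentence span, concept). All shipped templates respect
#' the instance definition, so the rate should be effectively 1; a shortfall
#' indicates a matcher bug.
#'
#' @param sc a `synthetic_corpus`.
#' @param lexicon the lexicon the corpus was generated with.
#' @return list: `overall` recovery rate, `by_class` named vector.
#' @export
planted_recovery <- function(sc, lexicon = default_lexicon()) {
  stopifnot(inherits(sc, "synthetic_corpus"))
  lexicon <- compile_lexicon(lexicon)
  found <- character()
  for (i in seq_len(nrow(sc$corpus))) {
    inst <- build_instances(sc$corpus$text[i], sc$corpus$doc_id[i], lexicon)
    found <- c(found, vapply(inst, function(x) {
      paste(x$doc_id, x$sentence$start, x$sentence$end, x$concept, sep = "|")
    }, ""))
  }
  key <- paste(sc$ledger$doc_id, sc$ledger$sent_start, sc$ledger$sent_end,
               sc$ledger$concept, sep = "|")
  hit <- key %in% found
  by_class <- tapply(hit, sc$ledger$class, mean)
  list(overall = mean(hit), by_class = by_class)
}

#' Write the synthetic corpus, ledger and truth table to files
#'
#' @param sc a `synthetic_corpus`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_corpus <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(corpus = file.path(dir, "corpus.ndjson"),
             ledger = file.path(dir, "ledger.ndjson"),
             truth = file.path(dir, "truth.csv"))
  write_corpus(sc$corpus, paths["corpus"])
  con <- file(paths["ledger"], open = "w", encoding = "UTF-8")
  for (i in seq_len(nrow(sc$ledger))) {
    writeLines(jsonlite::toJSON(as.list(sc$ledger[i, ]), auto_unbox = TRUE),
               con)
  }
  close(con)
  utils::write.csv(sc$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
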