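# End-to-end synthetic benchmark: generate a corpus, train per-concept
# models with margin calibration at a target precision, and score the hybrid
# (rules + SVM + margin) arm against context rules alone on a held-out
# split. This is the package's reference experiment for the paired
# comparison of the two arms under a precision-favouring operating point.

#' Train and evaluate the pipeline on a synthetic corpus
#'
#' Generates a seeded corpus, builds the labelled instance set per concept,
#' splits it into train/calibration/test, trains the SVM, calibrates the
#' confidence margin to the target precision on the calibration split, and
#' evaluates both the hybrid arm and the rules-only arm on the test split.
#'
#' @param seed master seed for generation, folds and splits.
#' @param concepts concept labels to benchmark.
#' @param n_patients,docs_min,docs_max,mention_rate,context_mix generator
#'   settings (see [generator_config]).
#' @param target_precision margin-calibration target.
#' @param train_frac,cal_frac split fractions (the remainder is the test
#'   split).
#' @param n_folds cross-validation folds.
#' @return list: `per_concept` data.frame with one row per concept and arm
#'   (`precision`, `recall`, `f1`, `n_train`, `n_test`, `margin`), plus
#'   `n_instances` per concept.
#' @export
synthetic_benchmark <- function(seed = 1L,
                                concepts = c("Hallucinations", "Paranoia",
                                             "Pressured speech",
                                             "Disturbed sleep",
                                             "Poor rapport"),
                                n_patients = 160L, docs_min = 2L,
                                docs_max = 2L, mention_rate = 1.8,
                                context_mix = c(affirmed = 0.5, negated = 0.2,
                                                hypothetical = 0.1,
                                                other_experiencer = 0.1,
                                                irrelevant_homograph = 0.1),
                                target_precision = 0.85,
                                train_frac = 0.6, cal_frac = 0.2,
                                n_folds = 10L) {
  cfg <- generator_config(n_patients = n_patients, docs_min = docs_min,
                          docs_max = docs_max, concepts = concepts,
                          mention_rate = mention_rate,
                          context_mix = context_mix, seed = seed)
  lex <- compile_lexicon(default_lexicon())
  sc <- generate_corpus(cfg, lex)
  rows <- list(); n_instances <- integer()
  for (cn in concepts) {
    data <- make_training_set(sc, cn, lex)
    n <- length(data)
    n_instances[[cn]] <- n
    set.seed(sub_seed(seed, 4L, match(cn, concepts)))
    idx <- sample(n)
    n_tr <- floor(train_frac * n)
    n_cal <- floor(cal_frac * n)
    tr <- idx[seq_len(n_tr)]
    cal <- idx[n_tr + seq_len(n_cal)]
    te <- idx[(n_tr + n_cal + 1L):n]
    model <- train_model(data[tr], list(n_folds = n_folds), seed = seed)
    calib <- calibrate_margin(model, data[cal],
                              target_precision = target_precision)
    model <- set_margin(model, calib)
    gold <- data[te]
    inst <- lapply(gold, `[[`, "instance")
    hybrid <- predict(model, inst)
    rules <- lapply(inst, function(x) {
      labelled_instance(x, context_only_label(x$context), source = "model",
                        confidence = 0)
    })
    for (arm in c("hybrid", "rules")) {
      rep_ <- score_predictions(gold, if (arm == "hybrid") hybrid else rules)
      rows[[length(rows) + 1L]] <- data.frame(
        concept = cn, arm = arm, precision = rep_$precision,
        recall = rep_$recall, f1 = rep_$f1, n_train = length(tr),
        n_test = length(te), margin = model$margin_threshold,
        stringsAsFactors = FALSE)
    }
  }
  list(per_concept = do.call(rbind, rows), n_instances = n_instances,
       config = cfg)
}
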