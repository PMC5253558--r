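# training sets come from the seeded synthetic corpus (classifier_fixture in
# helper-fixtures.R) so the classifier is exercised over the real feature
# pipeline

test_that("feature extraction is deterministic and covers the advertised groups", {
  x <- instance_with_context(
    "For the past week has been having auditory command hallucinations.")
  f1 <- extract_features(x)
  f2 <- extract_features(x)
  expect_identical(f1, f2)
  expect_true("kw=hallucinations" %in% names(f1))
  expect_true("mod=audit*" %in% names(f1))
  expect_true("has_modifier" %in% names(f1))
  expect_true(any(startsWith(names(f1), "b=")))       # bigrams
  expect_true(any(startsWith(names(f1), "p[-1]=")))   # positional window
  expect_true(any(startsWith(names(f1), "pt[+")))     # POS window
  expect_false("ctx_negated" %in% names(f1))

  # negating the sentence changes only context features and the n-grams /
  # window cells that cover the trigger tokens
  y <- instance_with_context(
    "has not been having auditory command hallucinations.")
  z <- instance_with_context(
    "has been having auditory command hallucinations.")
  fy <- names(extract_features(y)); fz <- names(extract_features(z))
  changed <- c(setdiff(fy, fz), setdiff(fz, fy))
  expect_true("ctx_negated" %in% changed)
  expect_true(all(grepl("^(ctx_|w=not$|b=(has|not|been)_|p\\[|pt\\[)", changed)))

  x$context <- NULL
  expect_error(extract_features(x), "context")
})

test_that("separable synthetic data reach perfect cross-validated F1", {
  data <- classifier_fixture()
  expect_gte(length(data), 100L)
  model <- train_model(data, seed = 2)
  expect_identical(nrow(model$cv_report), 10L)
  expect_identical(mean(model$cv_report$f1), 1)
})

test_that("label-permuted data score no better than the uninformative bound", {
  data <- classifier_fixture()
  labels <- vapply(data, `[[`, "", "label")
  set.seed(31)
  permuted <- sample(labels)
  data2 <- lapply(seq_along(data), function(i) {
    labelled_instance(data[[i]]$instance, permuted[i], source = "human")
  })
  model <- train_model(data2, seed = 2)
  p <- mean(permuted == "positive")
  # the best label-independent strategy (always predict positive) has
  # F1 = 2p / (1 + p); an honest model on permuted labels cannot beat it by
  # more than CV noise
  bound <- 2 * p / (1 + p)
  cv_f1 <- mean(ifelse(is.na(model$cv_report$f1), 0, model$cv_report$f1))
  expect_lt(cv_f1, bound + 0.1)
})

test_that("training is reproducible from the seed", {
  data <- classifier_fixture(n_patients = 30)
  m1 <- train_model(data, seed = 9)
  m2 <- train_model(data, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$cv_report, m2$cv_report)
})

test_that("degenerate training inputs raise instructive errors", {
  data <- classifier_fixture(n_patients = 30)
  pos <- Filter(function(d) d$label == "positive", data)
  expect_error(train_model(pos, seed = 1), "single class")
  expect_error(train_model(data[1:8], seed = 1), "n_folds")
  expect_error(labelled_instance(data[[1]]$instance, "positive",
                                 confidence = 1), "confidence")
})

test_that("the margin rule demotes low-confidence positives to negative", {
  data <- classifier_fixture()
  model <- train_model(data[1:80], seed = 4)
  rest <- lapply(data[81:length(data)], `[[`, "instance")
  d <- decision_values(model, rest)
  i_pos <- which(d > 0)[1]
  expect_false(is.na(i_pos))
  # threshold zero: plain sign rule
  expect_identical(predict(set_margin(model, 0), rest[[i_pos]])$label,
                   "positive")
  # threshold above this decision value: demoted
  expect_identical(predict(set_margin(model, d[i_pos] + 1), rest[[i_pos]])$label,
                   "negative")
  # confidence is the absolute decision value
  expect_equal(predict(model, rest[[i_pos]])$confidence, abs(d[i_pos]))
})

test_that("margin calibration matches an exhaustive sweep", {
  data <- classifier_fixture()
  model <- train_model(data[1:80], seed = 4)
  held <- data[81:length(data)]
  cal <- calibrate_margin(model, held, target_precision = 0.85)
  # independent sweep: recompute precision at every candidate threshold
  d <- decision_values(model, lapply(held, `[[`, "instance"))
  gold <- vapply(held, `[[`, "", "label") == "positive"
  best <- Inf
  for (t in sort(unique(c(0, d[d > 0])))) {
    pred <- d > 0 & abs(d) >= t
    if (sum(pred) > 0 && sum(pred & gold) / sum(pred) >= 0.85) {
      best <- t
      break
    }
  }
  expect_identical(cal$threshold, best)
  expect_gte(cal$precision, 0.85)

  # perfectly ranked predictions: threshold 0 reaches precision 1
  perfect <- Filter(function(x) {
    dv <- decision_values(model, list(x$instance))
    (dv > 0) == (x$label == "positive")
  }, held)
  cal2 <- calibrate_margin(model, perfect, target_precision = 1)
  expect_identical(cal2$threshold, 0)
  expect_identical(cal2$precision, 1)
})

test_that("high-margin false positives push the calibrated threshold above them", {
  data <- classifier_fixture()
  model <- train_model(data[1:80], seed = 4)
  held <- data[81:length(data)]
  d <- decision_values(model, lapply(held, `[[`, "instance"))
  # relabel the two highest-margin positives as negative: hard false positives
  top2 <- order(-d)[1:2]
  flipped <- held
  for (i in top2) {
    flipped[[i]] <- labelled_instance(held[[i]]$instance, "negative")
  }
  cal <- suppressWarnings(calibrate_margin(model, flipped,
                                           target_precision = 1))
  if (cal$reached) {
    expect_gt(cal$threshold, max(d))
  } else {
    # unreachable: the maximum observed decision value is returned
    expect_identical(cal$threshold, max(d[d > 0]))
  }
})

test_that("recall and the predicted-positive set shrink monotonically in the margin", {
  data <- classifier_fixture()
  model <- train_model(data[1:80], seed = 4)
  held <- data[81:length(data)]
  inst <- lapply(held, `[[`, "instance")
  gold <- vapply(held, `[[`, "", "label") == "positive"
  prev_set <- NULL
  prev_recall <- Inf
  for (t in c(0, 0.2, 0.5, 1, 2, 5)) {
    m <- set_margin(model, t)
    labs <- vapply(predict(m, inst), `[[`, "", "label")
    set <- which(labs == "positive")
    if (!is.null(prev_set)) expect_true(all(set %in% prev_set))
    recall <- if (sum(gold)) sum(gold & labs == "positive") / sum(gold) else 0
    expect_lte(recall, prev_recall)
    prev_set <- set
    prev_recall <- recall
  }
})

test_that("known discriminative cues surface in the top weights", {
  data <- classifier_fixture()
  model <- train_model(data, seed = 2)
  w <- sort(model$weights)
  neg_cues <- names(w)[1:15]
  # negation templates plant these cue words in the negative class
  expect_true(any(grepl("no|denied|not|evidence|negative", neg_cues)))
})

test_that("models survive a plain-text save/load round trip", {
  data <- classifier_fixture(n_patients = 30)
  model <- set_margin(train_model(data, seed = 5), 0.4)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_identical(back$concept, model$concept)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  expect_equal(back$margin_threshold, 0.4)
  inst <- lapply(data[1:10], `[[`, "instance")
  expect_equal(decision_values(back, inst), decision_values(model, inst),
               tolerance = 1e-10)
})
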