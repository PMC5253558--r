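# Per-concept binary sentence classification: a linear SVM (LibSVM via
# e1071) over sparse binary bag-of-words + rule features, tuned by
# stratified 10-fold cross-validation over the regularisation strength, with
# a confidence-margin filter that demotes low-margin positive predictions to
# negative in order to favour precision.

FEATURE_CONFIG_VERSION <- "bow-ctx-1"

#' Default feature-extraction configuration
#'
#' @param window half-width (in tokens) of the position-indexed window around
#'   the keyword span.
#' @return a feature configuration list (versioned).
#' @export
default_feature_config <- function(window = 5L) {
  list(version = FEATURE_CONFIG_VERSION, window = as.integer(window))
}

#' Labelled instance
#'
#' A candidate instance with a binary label from a human annotator or a
#' model. Human labels carry no confidence; model labels carry the absolute
#' SVM decision value.
#'
#' @param instance a `candidate_instance`.
#' @param label `"positive"` or `"negative"`.
#' @param source `"human"` or `"model"`.
#' @param confidence numeric margin for model labels; must be `NULL` for
#'   human labels.
#' @return object of class `labelled_instance`.
#' @export
labelled_instance <- function(instance, label, source = "human",
                              confidence = NULL) {
  stopifnot(inherits(instance, "candidate_instance"))
  label <- match.arg(label, c("positive", "negative"))
  source <- match.arg(source, c("human", "model"))
  if (source == "human" && !is.null(confidence)) {
    stop("human labels carry no confidence", call. = FALSE)
  }
  structure(list(instance = instance, label = label, source = source,
                 confidence = confidence),
            class = "labelled_instance")
}

#' Extract a sparse feature vector from a candidate instance
#'
#' Features (all binary presence indicators): sentence unigrams and bigrams
#' over lower-cased word tokens; the matched keyword string; position-indexed
#' tokens within the window around the keyword span; part-of-speech tags of
#' that window; a modifier-present flag and the matched modifier patterns;
#' and the non-default ConText flags. Deterministic for a given instance and
#' configuration.
#'
#' @param instance a `candidate_instance` with context flags filled (see
#'   [add_context]).
#' @param config feature configuration from [default_feature_config].
#' @return named numeric vector (sparse map feature-name -> 1).
#' @export
extract_features <- function(instance, config = default_feature_config()) {
  stopifnot(inherits(instance, "candidate_instance"))
  if (is.null(instance$context)) {
    stop("instance has no context flags; run add_context()/apply_context() first",
         call. = FALSE)
  }
  toks <- instance$sentence$tokens
  low <- tolower(toks$text)
  words <- low[toks$is_word]
  feats <- character()
  feats <- c(feats, paste0("w=", unique(words)))
  if (length(words) >= 2L) {
    bg <- paste0("b=", words[-length(words)], "_", words[-1])
    feats <- c(feats, unique(bg))
  }
  feats <- c(feats, paste0("kw=", tolower(instance$keyword$matched_text)))
  w <- config$window
  kf <- instance$keyword$first; kl <- instance$keyword$last
  n <- nrow(toks)
  for (d in seq_len(w)) {
    i <- kf - d
    if (i >= 1L) feats <- c(feats, paste0("p[-", d, "]=", low[i]),
                            paste0("pt[-", d, "]=", toks$pos[i]))
    j <- kl + d
    if (j <= n) feats <- c(feats, paste0("p[+", d, "]=", low[j]),
                           paste0("pt[+", d, "]=", toks$pos[j]))
  }
  if (nrow(instance$modifiers)) {
    feats <- c(feats, "has_modifier",
               paste0("mod=", unique(instance$modifiers$pattern)))
  }
  ctx <- instance$context
  if (ctx$negated) feats <- c(feats, "ctx_negated")
  if (ctx$experiencer == "other") feats <- c(feats, "ctx_experiencer_other")
  if (ctx$temporality == "historical") feats <- c(feats, "ctx_historical")
  if (ctx$temporality == "hypothetical") feats <- c(feats, "ctx_hypothetical")
  out <- rep(1, length(unique(feats)))
  names(out) <- unique(feats)
  out
}

# Dense design matrix over a fixed vocabulary.
feature_matrix <- function(feature_list, vocab) {
  X <- matrix(0, nrow = length(feature_list), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(feature_list)) {
    f <- intersect(names(feature_list[[i]]), vocab)
    X[i, f] <- 1
  }
  X
}

prf_counts <- function(gold_pos, pred_pos) {
  tp <- sum(gold_pos & pred_pos)
  fp <- sum(!gold_pos & pred_pos)
  fn <- sum(gold_pos & !pred_pos)
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

# Fit a linear SVM and return an oriented linear form: decision(x) = x.w + b
# with decision > 0 favouring the positive class.
fit_linear_svm <- function(X, y, cost) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # LibSVM's decision-value sign follows the order in which labels appear in
  # the training data, so orient empirically against the fitted machine's own
  # decision values instead of trusting factor levels.
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  manual <- drop(X %*% w) + b
  if (sum(abs(manual - dv[, 1])) > sum(abs(manual + dv[, 1]))) {
    w <- -w; b <- -b
  }
  pos_first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (pos_first != "positive") {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b)
}

linear_decision <- function(weights, bias, feature_list) {
  vapply(feature_list, function(f) {
    sum(weights[intersect(names(f), names(weights))]) + bias
  }, 0)
}

#' Train a per-concept symptom model
#'
#' Stratified k-fold cross-validation (k = 10 by default) grid-searches the
#' SVM regularisation strength over `config$costs`; the selection metric is
#' mean positive-class F1 across folds, ties broken towards the smaller
#' strength; the final model is refit on all data at the chosen strength.
#' Fully reproducible from `seed`.
#'
#' @param data list of [labelled_instance], all for the same concept, with
#'   both labels present.
#' @param config optional list: `n_folds` (default 10), `costs` (default
#'   `c(0.01, 0.1, 1, 10, 100)`), `feature_config`.
#' @param seed integer seed controlling fold assignment.
#' @return object of class `symptom_model` with linear weights, the chosen
#'   strength, a per-fold CV report and a zero margin threshold (see
#'   [calibrate_margin]).
#' @export
train_model <- function(data, config = list(), seed = 1L) {
  stopifnot(is.list(data), length(data) > 0L)
  ok <- vapply(data, inherits, TRUE, what = "labelled_instance")
  if (!all(ok)) stop("data must be a list of labelled_instance", call. = FALSE)
  concepts <- unique(vapply(data, function(d) d$instance$concept, ""))
  if (length(concepts) != 1L) {
    stop("all instances must belong to one concept; got: ",
         paste(concepts, collapse = ", "), call. = FALSE)
  }
  labels <- vapply(data, `[[`, "", "label")
  if (length(unique(labels)) < 2L) {
    stop("training data contain a single class ('", labels[1],
         "'); both labels are required", call. = FALSE)
  }
  n_folds <- if (!is.null(config$n_folds)) as.integer(config$n_folds) else 10L
  costs <- if (!is.null(config$costs)) config$costs else c(0.01, 0.1, 1, 10, 100)
  fconf <- if (!is.null(config$feature_config)) config$feature_config
           else default_feature_config()
  n <- length(data)
  if (n < n_folds) {
    stop("only ", n, " instances for ", n_folds, "-fold cross-validation; ",
         "request fewer folds via config$n_folds", call. = FALSE)
  }
  feats <- lapply(data, function(d) extract_features(d$instance, fconf))
  vocab <- sort(unique(unlist(lapply(feats, names))))
  X <- feature_matrix(feats, vocab)
  y <- factor(labels, levels = c("negative", "positive"))

  # stratified, seeded fold assignment
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  if (any(tabulate(fold, n_folds) == 0L)) {
    stop("empty cross-validation fold; request fewer folds via config$n_folds",
         call. = FALSE)
  }

  cv <- expand.grid(fold = seq_len(n_folds), cost = costs)
  cv$precision <- cv$recall <- cv$f1 <- NA_real_
  for (ci in seq_along(costs)) {
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      # guard: a fold's training part must still contain both classes
      if (length(unique(y[tr])) < 2L) next
      m <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], costs[ci])
      d <- drop(X[!tr, , drop = FALSE] %*% m$weights) + m$bias
      res <- prf_counts(y[!tr] == "positive", d > 0)
      row <- which(cv$fold == k & cv$cost == costs[ci])
      cv$precision[row] <- res$precision
      cv$recall[row] <- res$recall
      cv$f1[row] <- res$f1
    }
  }
  mean_f1 <- vapply(costs, function(cc) {
    v <- cv$f1[cv$cost == cc]
    mean(ifelse(is.na(v), 0, v))
  }, 0)
  best_cost <- costs[which.max(mean_f1)]   # which.max takes the first maximum;
                                           # costs ascend, so ties break small
  final <- fit_linear_svm(X, y, best_cost)
  structure(
    list(concept = concepts,
         weights = final$weights,
         bias = final$bias,
         feature_config = fconf,
         margin_threshold = 0,
         best_cost = best_cost,
         cv_report = cv[cv$cost == best_cost,
                        c("fold", "cost", "precision", "recall", "f1")],
         cv_grid = data.frame(cost = costs, mean_f1 = mean_f1),
         seed = as.integer(seed),
         n_train = n),
    class = "symptom_model")
}

#' @export
print.symptom_model <- function(x, ...) {
  cat("<symptom_model> ", x$concept, ": ", length(x$weights), " features, ",
      "cost=", x$best_cost, ", margin=", format(x$margin_threshold, digits = 4),
      ", CV mean F1=",
      format(mean(ifelse(is.na(x$cv_report$f1), 0, x$cv_report$f1)), digits = 3),
      " (", nrow(x$cv_report), " folds, n=", x$n_train, ")\n", sep = "")
  invisible(x)
}

#' Predict labels for candidate instances
#'
#' An instance is labelled positive iff its decision value is strictly
#' positive and its absolute value reaches the model's margin threshold;
#' positive predictions failing the margin are demoted to negative
#' (abstention folds into the negative class). Confidence is the absolute
#' decision value.
#'
#' @param object a `symptom_model`.
#' @param newdata a `candidate_instance` or list of them, with context flags
#'   filled.
#' @param ... unused.
#' @return a `labelled_instance` (or list of them, matching the input shape)
#'   with `source = "model"`.
#' @export
predict.symptom_model <- function(object, newdata, ...) {
  single <- inherits(newdata, "candidate_instance")
  if (single) newdata <- list(newdata)
  if (!identical(object$feature_config$version, FEATURE_CONFIG_VERSION)) {
    stop("model feature_config version '", object$feature_config$version,
         "' does not match this package's extractor ('",
         FEATURE_CONFIG_VERSION, "')", call. = FALSE)
  }
  feats <- lapply(newdata, function(x) extract_features(x, object$feature_config))
  d <- linear_decision(object$weights, object$bias, feats)
  out <- lapply(seq_along(newdata), function(i) {
    lab <- if (d[i] > 0 && abs(d[i]) >= object$margin_threshold) "positive"
           else "negative"
    labelled_instance(newdata[[i]], lab, source = "model",
                      confidence = abs(d[i]))
  })
  if (single) out[[1]] else out
}

#' Decision values for candidate instances
#'
#' @param model a `symptom_model`.
#' @param instances list of `candidate_instance` with context flags.
#' @return numeric vector of signed decision values (positive favours the
#'   positive class).
#' @export
decision_values <- function(model, instances) {
  stopifnot(inherits(model, "symptom_model"))
  feats <- lapply(instances, function(x) extract_features(x, model$feature_config))
  linear_decision(model$weights, model$bias, feats)
}

#' Calibrate the confidence-margin threshold for a target precision
#'
#' Sweeps candidate thresholds at the observed decision values on a held-out
#' labelled set and returns the smallest threshold whose filtered predictions
#' reach the target precision, together with the precision and recall
#' achieved there. If the target is unreachable, the maximum observed
#' decision value is returned with a warning.
#'
#' @param model a `symptom_model`.
#' @param held_out list of [labelled_instance] with human labels.
#' @param target_precision required precision in (0, 1].
#' @return list of class `margin_calibration`: `threshold`, `precision`,
#'   `recall`, `reached` and the full `sweep` table.
#' @export
calibrate_margin <- function(model, held_out, target_precision = 0.85) {
  stopifnot(inherits(model, "symptom_model"),
            target_precision > 0, target_precision <= 1)
  gold <- vapply(held_out, `[[`, "", "label") == "positive"
  if (!any(gold)) stop("held-out set contains no positive labels", call. = FALSE)
  d <- decision_values(model, lapply(held_out, `[[`, "instance"))
  if (!any(d > 0)) {
    stop("no positive predictions at any threshold; cannot calibrate margin",
         call. = FALSE)
  }
  cand <- sort(unique(c(0, d[d > 0])))
  sweep <- do.call(rbind, lapply(cand, function(t) {
    pred <- d > 0 & abs(d) >= t
    res <- prf_counts(gold, pred)
    data.frame(threshold = t, n_predicted = sum(pred),
               precision = res$precision, recall = res$recall)
  }))
  ok <- !is.na(sweep$precision) & sweep$precision >= target_precision &
        sweep$n_predicted > 0
  if (any(ok)) {
    row <- sweep[which(ok)[1], ]
    reached <- TRUE
  } else {
    warning("target precision ", target_precision,
            " unreachable on held-out data; returning the maximum observed ",
            "decision value")
    row <- sweep[nrow(sweep), ]
    reached <- FALSE
  }
  structure(list(threshold = row$threshold, precision = row$precision,
                 recall = row$recall, reached = reached, sweep = sweep),
            class = "margin_calibration")
}

#' Set a model's margin threshold
#'
#' @param model a `symptom_model`.
#' @param threshold non-negative margin threshold (or a `margin_calibration`).
#' @return the model with the threshold applied.
#' @export
set_margin <- function(model, threshold) {
  stopifnot(inherits(model, "symptom_model"))
  if (inherits(threshold, "margin_calibration")) threshold <- threshold$threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  model$margin_threshold <- threshold
  model
}

# ---- model persistence ------------------------------------------------------

#' Save a symptom model as a plain-text artefact directory
#'
#' Writes `weights.tsv`, `meta.yaml` (concept, bias, margin threshold, chosen
#' strength, seed, feature configuration) and `cv_report.csv`.
#'
#' @param model a `symptom_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "symptom_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- data.frame(feature = names(model$weights), weight = model$weights)
  utils::write.table(wt, file.path(dir, "weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  meta <- list(concept = model$concept, bias = model$bias,
               margin_threshold = model$margin_threshold,
               best_cost = model$best_cost, seed = model$seed,
               n_train = model$n_train,
               feature_config = model$feature_config)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"), precision = 15L)
  utils::write.csv(model$cv_report, file.path(dir, "cv_report.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a symptom model saved by [save_model]
#'
#' @param dir artefact directory.
#' @return a `symptom_model`.
#' @export
load_model <- function(dir) {
  wt <- utils::read.table(file.path(dir, "weights.tsv"), sep = "\t",
                          header = TRUE, quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  weights <- wt$weight
  names(weights) <- wt$feature
  fconf <- meta$feature_config
  fconf$window <- as.integer(fconf$window)
  structure(
    list(concept = meta$concept, weights = weights, bias = meta$bias,
         feature_config = fconf,
         margin_threshold = meta$margin_threshold,
         best_cost = meta$best_cost,
         cv_report = utils::read.csv(file.path(dir, "cv_report.csv")),
         cv_grid = NULL, seed = meta$seed, n_train = meta$n_train),
    class = "symptom_model")
}
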