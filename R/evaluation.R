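# Gold-standard validation (positive-class precision/recall/F1),
# inter-annotator agreement (Cohen's kappa) and cross-concept summaries for
# comparing the hybrid (rules + SVM) arm against context rules alone.
# Undefined ratios (zero denominators) propagate as NA, never as 0, and are
# excluded from aggregate means/medians with a footnote count.

instance_key <- function(li) {
  x <- li$instance
  paste(x$doc_id, x$sentence$start, x$sentence$end, x$concept,
        x$keyword$start, sep = "|")
}

#' Score predictions against a gold standard
#'
#' Gold and predicted instances are aligned on (document, sentence span,
#' concept, keyword offset); alignment failures are errors, not misses.
#' Counts are computed over the positive class only, per concept.
#'
#' @param gold list of [labelled_instance] with human labels.
#' @param predicted list of [labelled_instance] with model (or rule) labels.
#' @return data.frame of class `prf_report`, one row per concept:
#'   `concept`, `true_pos`, `false_pos`, `false_neg`, `precision`, `recall`,
#'   `f1` (`NA` where undefined).
#' @export
score_predictions <- function(gold, predicted) {
  stopifnot(is.list(gold), is.list(predicted), length(gold) > 0L)
  gk <- vapply(gold, instance_key, "")
  pk <- vapply(predicted, instance_key, "")
  if (anyDuplicated(gk)) {
    stop("duplicate instance keys in gold: ",
         paste(utils::head(gk[duplicated(gk)], 3), collapse = "; "),
         call. = FALSE)
  }
  if (anyDuplicated(pk)) {
    stop("duplicate instance keys in predictions: ",
         paste(utils::head(pk[duplicated(pk)], 3), collapse = "; "),
         call. = FALSE)
  }
  only_g <- setdiff(gk, pk)
  only_p <- setdiff(pk, gk)
  if (length(only_g) || length(only_p)) {
    stop("gold and predictions are not aligned; unmatched keys: ",
         paste(utils::head(c(only_g, only_p), 5), collapse = "; "),
         call. = FALSE)
  }
  ord <- match(gk, pk)
  g_lab <- vapply(gold, `[[`, "", "label") == "positive"
  p_lab <- vapply(predicted, `[[`, "", "label")[ord] == "positive"
  concept <- vapply(gold, function(li) li$instance$concept, "")
  out <- do.call(rbind, lapply(unique(concept), function(cc) {
    sel <- concept == cc
    res <- prf_counts(g_lab[sel], p_lab[sel])
    data.frame(concept = cc, true_pos = res$tp, false_pos = res$fp,
               false_neg = res$fn, precision = res$precision,
               recall = res$recall, f1 = res$f1, stringsAsFactors = FALSE)
  }))
  class(out) <- c("prf_report", "data.frame")
  out
}

#' Cohen's kappa for two raters
#'
#' Observed agreement and chance-corrected agreement, with chance agreement
#' computed from the raters' marginal label frequencies:
#' kappa = (p_o - p_e) / (1 - p_e). When both raters assign the identical
#' constant label, kappa is reported as 1 by convention and flagged.
#'
#' @param labels_a,labels_b equal-length vectors of paired binary labels.
#' @param concept optional concept name carried into the report.
#' @return list of class `agreement_report`: `concept`, `n_instances`,
#'   `observed_agreement`, `kappa`, `degenerate` (constant-rater flag).
#' @export
cohens_kappa <- function(labels_a, labels_b, concept = NA_character_) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have the same length (", length(labels_a),
         " vs ", length(labels_b), ")", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 1L) stop("need at least one paired label", call. = FALSE)
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  p_o <- mean(a == b)
  cats <- union(unique(a), unique(b))
  p_e <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), 0))
  degenerate <- FALSE
  if (p_e >= 1) {      # both raters constant and identical
    kappa <- 1
    degenerate <- TRUE
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(concept = concept, n_instances = n,
                 observed_agreement = p_o, kappa = kappa,
                 degenerate = degenerate),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", if (!is.na(x$concept)) x$concept, "n =",
      x$n_instances, " observed =", format(x$observed_agreement, digits = 3),
      " kappa =", format(x$kappa, digits = 3),
      if (x$degenerate) " (degenerate: both raters constant)", "\n")
  invisible(x)
}

#' Validate a gold standard's positive-mention count
#'
#' A per-concept gold standard passes iff it contains at least
#' `min_positives` positive labels (default 100).
#'
#' @param gold list of [labelled_instance].
#' @param min_positives required number of positive labels.
#' @return list: `pass`, `n_positive`, `n_negative`, `n_total`,
#'   `min_positives`.
#' @export
validate_gold_standard <- function(gold, min_positives = 100L) {
  labels <- vapply(gold, `[[`, "", "label")
  n_pos <- sum(labels == "positive")
  list(pass = n_pos >= min_positives,
       n_positive = n_pos,
       n_negative = sum(labels == "negative"),
       n_total = length(labels),
       min_positives = as.integer(min_positives))
}

#' Summarise per-concept reports across evaluation arms
#'
#' Mean and median of precision, recall and F1 per arm, mirroring the paired
#' hybrid-vs-rules comparison. Undefined (NA) metrics are excluded from the
#' aggregates and counted in a footnote; listed concepts (e.g.
#' hand-annotated or keyword-only ones) are excluded and recorded.
#'
#' @param reports data.frame with columns `concept`, `arm`, `precision`,
#'   `recall`, `f1` (rbind of [score_predictions] outputs with an `arm`
#'   column added).
#' @param exclude concept names to drop before aggregating.
#' @return list of class `arm_summary`: `summary` (one row per arm and
#'   statistic), `excluded_concepts`, `n_undefined` (per arm and metric).
#' @export
summarize_across_concepts <- function(reports, exclude = character()) {
  stopifnot(is.data.frame(reports),
            all(c("concept", "arm", "precision", "recall", "f1") %in%
                names(reports)))
  kept <- reports[!reports$concept %in% exclude, , drop = FALSE]
  arms <- unique(kept$arm)
  if (length(arms) == 0L || nrow(kept) == 0L) {
    stop("no reports left to summarise", call. = FALSE)
  }
  rows <- list(); foot <- list()
  for (arm in arms) {
    sub <- kept[kept$arm == arm, ]
    if (nrow(sub) == 0L) stop("empty arm: ", arm, call. = FALSE)
    for (stat in c("mean", "median")) {
      f <- if (stat == "mean") function(v) mean(v, na.rm = TRUE)
           else function(v) stats::median(v, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, statistic = stat,
        precision = f(sub$precision), recall = f(sub$recall), f1 = f(sub$f1),
        n_concepts = nrow(sub), stringsAsFactors = FALSE)
    }
    foot[[arm]] <- c(precision = sum(is.na(sub$precision)),
                     recall = sum(is.na(sub$recall)),
                     f1 = sum(is.na(sub$f1)))
  }
  structure(list(summary = do.call(rbind, rows),
                 excluded_concepts = intersect(exclude, reports$concept),
                 n_undefined = foot),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat("<arm_summary>\n")
  print(x$summary, row.names = FALSE)
  if (length(x$excluded_concepts)) {
    cat("excluded concepts:", paste(x$excluded_concepts, collapse = ", "), "\n")
  }
  und <- vapply(x$n_undefined, sum, 0)
  if (any(und > 0)) {
    cat("undefined metrics excluded from aggregates:",
        paste(names(und), und, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write per-concept reports and an arm summary to CSV + text
#'
#' @param reports data.frame as taken by [summarize_across_concepts].
#' @param summary an `arm_summary`.
#' @param csv_path,txt_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_evaluation <- function(reports, summary, csv_path, txt_path) {
  utils::write.csv(reports, csv_path, row.names = FALSE)
  con <- file(txt_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("Evaluation summary (positive class)", con)
  writeLines(utils::capture.output(print(summary)), con)
  invisible(csv_path)
}
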