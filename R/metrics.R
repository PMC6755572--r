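#' Threshold classification of activity scores
#'
#' A chemical is called active when its continuous activity score strictly
#' exceeds the threshold (default 0.1, the conventional cutoff separating
#' likely-true actives from assay noise on the `[0, 1]` score scale).
#'
#' @param score activity score(s) in `[0, 1]`.
#' @param threshold activity cutoff.
#' @return logical vector, `TRUE` = active.
#' @export
binarize <- function(score, threshold = 0.1) {
  check_scores(score)
  score > threshold
}

#' Confusion counts at an activity threshold
#'
#' Both the reference scores and the predicted scores are binarized at the
#' same threshold, then tallied.
#'
#' @param truth reference activity scores (or logicals).
#' @param predicted predicted activity scores (or logicals).
#' @param threshold activity cutoff applied to both sides.
#' @return named list `tp`, `fp`, `fn`, `tn` (class `confusion_counts`).
#' @export
confusion <- function(truth, predicted, threshold = 0.1) {
  if (length(truth) != length(predicted) || length(truth) == 0)
    stop_gknn("truth and predicted must be non-empty and equal length",
              class = "gknn_value_error")
  t_act <- if (is.logical(truth)) truth else binarize(truth, threshold)
  p_act <- if (is.logical(predicted)) predicted
           else binarize(predicted, threshold)
  structure(list(tp = sum(t_act & p_act), fp = sum(!t_act & p_act),
                 fn = sum(t_act & !p_act), tn = sum(!t_act & !p_act)),
            class = "confusion_counts")
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Probability that a randomly chosen active chemical receives a higher
#' predicted score than a randomly chosen inactive one, with ties counted
#' one half. Invariant under strictly monotone transforms of the scores.
#'
#' @param truth_active logical vector of reference classes.
#' @param scores continuous predicted scores.
#' @return AUC in `[0, 1]`; `NaN` when only one class is present.
#' @export
roc_auc <- function(truth_active, scores) {
  n1 <- sum(truth_active)
  n0 <- sum(!truth_active)
  if (n1 == 0 || n0 == 0) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth_active]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy metrics for continuous activity predictions
#'
#' Binarizes reference and predicted scores at the threshold and reports
#' the seven standard accuracy metrics: sensitivity (TPR), specificity
#' (TNR), balanced accuracy (`0.5 (TPR + TNR)`, robust to class
#' imbalance), accuracy, precision (PPV), negative predictive value (NPV)
#' and ROC AUC (computed from the continuous predicted scores against the
#' binarized reference, since AUC over binary predictions is degenerate).
#' The composite score — the product of balanced accuracy, accuracy and
#' ROC AUC — is the quantity [grid_search()] ranks parameterizations by.
#'
#' Metrics with a zero denominator (e.g. PPV with no predicted actives,
#' or AUC with single-class truth) are reported as `NaN` and named in the
#' `undefined` attribute rather than silently zeroed; the composite score
#' is `NaN` whenever any of its factors is.
#'
#' @param truth reference activity scores in `[0, 1]` (or logicals).
#' @param predicted_scores continuous predicted activity scores.
#' @param threshold activity cutoff.
#' @return object of class `metrics_report`: list with fields
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `accuracy`,
#'   `precision`, `npv`, `roc_auc`, `score`, `counts`, `threshold`, `n`,
#'   and `undefined` (character vector of undefined metric names).
#' @export
qsar_metrics <- function(truth, predicted_scores, threshold = 0.1) {
  if (length(truth) != length(predicted_scores) || length(truth) == 0)
    stop_gknn("truth and predictions must be non-empty and equal length",
              class = "gknn_value_error")
  t_act <- if (is.logical(truth)) truth else binarize(truth, threshold)
  cc <- confusion(t_act, predicted_scores, threshold)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  tpr <- ratio(cc$tp, cc$tp + cc$fn)
  tnr <- ratio(cc$tn, cc$tn + cc$fp)
  ner <- 0.5 * (tpr + tnr)
  acc <- (cc$tp + cc$tn) / length(truth)
  ppv <- ratio(cc$tp, cc$tp + cc$fp)
  npv <- ratio(cc$tn, cc$tn + cc$fn)
  auc <- roc_auc(t_act, predicted_scores)
  score <- ner * acc * auc
  vals <- c(sensitivity = tpr, specificity = tnr, balanced_accuracy = ner,
            accuracy = acc, precision = ppv, npv = npv, roc_auc = auc,
            score = score)
  structure(c(as.list(vals),
              list(counts = cc, threshold = threshold, n = length(truth),
                   undefined = names(vals)[is.nan(vals)])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cc <- x$counts
  cat(sprintf("n = %d at threshold %g (tp %d, fp %d, fn %d, tn %d)\n",
              x$n, x$threshold, cc$tp, cc$fp, cc$fn, cc$tn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  balanced acc %.3f\n",
              x$sensitivity, x$specificity, x$balanced_accuracy))
  cat(sprintf("  accuracy %.3f  precision %.3f  npv %.3f  ROC AUC %.3f\n",
              x$accuracy, x$precision, x$npv, x$roc_auc))
  cat(sprintf("  composite score %.4f\n", x$score))
  if (length(x$undefined))
    cat("  undefined: ", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

metrics_row <- function(rep) {
  data.frame(sensitivity = rep$sensitivity, specificity = rep$specificity,
             balanced_accuracy = rep$balanced_accuracy,
             accuracy = rep$accuracy, precision = rep$precision,
             npv = rep$npv, roc_auc = rep$roc_auc, score = rep$score,
             n = rep$n)
}

#' Metrics stratified by prediction confidence
#'
#' Recomputes the accuracy metrics on the subsets of predictions whose
#' confidence `q` (similarity to the nearest training chemical) meets each
#' cutoff, showing how performance depends on distance to the model's
#' applicability domain. Strata left empty by a cutoff are skipped with a
#' message.
#'
#' @param predictions a [predict.gknn()] result (needs `estimate` and
#'   `confidence` columns).
#' @param truth reference activity scores aligned with `predictions`.
#' @param cutoffs confidence cutoffs; each stratum is `q >= cutoff`.
#' @param threshold activity cutoff for binarization.
#' @return data.frame with one row per non-empty stratum: `q_min`, `n`,
#'   and the metric columns.
#' @export
stratify_by_confidence <- function(predictions, truth,
                                   cutoffs = c(0, 0.5, 0.7, 0.9),
                                   threshold = 0.1) {
  if (nrow(predictions) != length(truth))
    stop_gknn("truth must align with predictions",
              class = "gknn_value_error")
  rows <- lapply(cutoffs, function(q0) {
    sel <- predictions$confidence >= q0
    if (!any(sel)) {
      message(sprintf("stratum q >= %g is empty; skipped", q0))
      return(NULL)
    }
    rep <- qsar_metrics(truth[sel], predictions$estimate[sel], threshold)
    cbind(data.frame(q_min = q0), metrics_row(rep))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Leave-one-out cross-validation metrics for a fitted model
#'
#' Collects the model's leave-one-out estimates (each training chemical
#' predicted from all the others, sharing one precomputed similarity
#' matrix) and scores them against the observed activities.
#'
#' @param object fitted [gknn()] model.
#' @param threshold activity cutoff (defaults to the model's).
#' @return a [qsar_metrics()] report.
#' @export
loo_cv <- function(object, threshold = object$threshold) {
  qsar_metrics(object$data[[object$endpoint]], object$loo_estimate,
               threshold)
}
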