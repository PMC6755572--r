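#' Fit a k-nearest-neighbor QSAR activity model
#'
#' Builds a nearest-neighbor activity model over a training set of
#' chemicals: fingerprints (or a supplied similarity matrix) define the
#' chemical space, and one of four neighbor-averaging estimators turns the
#' `k` most similar training chemicals' activities into an estimate. The
#' fit precomputes the training self-similarity matrix and sorted neighbor
#' lists, and evaluates the model by leave-one-out cross-validation
#' (each chemical predicted from all the others), so `fitted()`,
#' `residuals()` and `summary()` report out-of-sample behavior.
#'
#' Each prediction also carries a confidence `q`, the similarity to the
#' closest training chemical — a proxy for the applicability domain:
#' estimates for chemicals far from the training set (low `q`) are less
#' trustworthy.
#'
#' @param data training dataset data.frame (see [validate_dataset()]).
#' @param endpoint activity column to model.
#' @param family estimator family: `"gknn"`, `"knn_arithmetic"`,
#'   `"knn_geometric"` or `"knn_exponential"`.
#' @param k number of nearest neighbors (>= 1).
#' @param x activity-space exponent (`gknn`) or exponential decay rate
#'   (`knn_exponential`); ignored by the arithmetic and geometric families
#'   but preserved for provenance.
#' @param y structure-space exponent (`gknn` only).
#' @param fp an [fp_config()] used to fingerprint the structures.
#' @param similarity optional precomputed self-similarity matrix of
#'   `data` (same row order); when supplied, structures are not needed
#'   and `fp` is ignored.
#' @param threshold activity threshold separating actives from inactives
#'   (default 0.1); used by `summary()` and the tuning machinery.
#' @return object of class `gknn`.
#' @seealso [predict.gknn()], [loo_cv()], [grid_search()]
#' @export
gknn <- function(data, endpoint = "activity",
                 family = c("gknn", "knn_arithmetic", "knn_geometric",
                            "knn_exponential"),
                 k = 5, x = 1, y = 1,
                 fp = fp_config(), similarity = NULL, threshold = 0.1) {
  family <- match.arg(family)
  validate_dataset(data, endpoint, require_structure = is.null(similarity))
  n <- nrow(data)
  if (n == 0)
    stop_gknn("training set is empty", class = "gknn_value_error")
  k <- as.integer(k)
  if (k < 1) stop_gknn("k must be >= 1", class = "gknn_value_error")
  if (n < k + 1)
    stop_gknn("leave-one-out with k = ", k, " needs at least ", k + 1,
              " training chemicals, got ", n, class = "gknn_value_error")
  if (x < 0 || y < 0)
    stop_gknn("x and y must be >= 0", class = "gknn_value_error")
  if (is.null(similarity)) {
    S <- similarity_matrix(data, config = fp)
  } else {
    S <- unclass(similarity)
    if (nrow(S) != n || ncol(S) != n)
      stop_gknn("similarity matrix does not match the training set",
                class = "gknn_value_error")
    dimnames(S) <- list(data$chem_id, data$chem_id)
  }
  object <- structure(list(
    data = data, endpoint = endpoint,
    params = list(family = family, k = k, x = x, y = y),
    fp = fp, S = S, threshold = threshold,
    precomputed_sim = !is.null(similarity),
    neighbor_order = precompute_loo_order(S)), class = "gknn")
  loo <- loo_estimates(object, k = k, x = x, y = y, family = family)
  object$loo_estimate <- loo$estimate
  object$loo_confidence <- loo$confidence
  object
}

# For each training chemical, the other chemicals sorted by descending
# similarity with stable (dataset-order) tie-break; shared by every grid
# point and every leave-one-out fold.
precompute_loo_order <- function(S) {
  n <- nrow(S)
  lapply(seq_len(n), function(i) {
    idx <- setdiff(seq_len(n), i)
    s <- S[i, idx]
    idx[order(-s, seq_along(idx))]
  })
}

loo_estimates <- function(object, k, x, y, family) {
  S <- object$S
  act <- object$data[[object$endpoint]]
  ord <- object$neighbor_order
  n <- nrow(S)
  est <- conf <- numeric(n)
  for (i in seq_len(n)) {
    nb <- ord[[i]][seq_len(min(k, length(ord[[i]])))]
    est[i] <- estimate_activity(family, act[nb], S[i, nb], x, y)
    conf[i] <- S[i, ord[[i]][1]]
  }
  list(estimate = est, confidence = conf)
}

#' @export
print.gknn <- function(x, ...) {
  p <- x$params
  cat(sprintf("k-nearest-neighbor QSAR model (%s)\n", p$family))
  cat(sprintf("  endpoint: %s; training chemicals: %d\n",
              x$endpoint, nrow(x$data)))
  cat(sprintf("  k = %d%s%s\n", p$k,
              if (p$family %in% c("gknn", "knn_exponential"))
                sprintf(", x = %g", p$x) else "",
              if (p$family == "gknn") sprintf(", y = %g", p$y) else ""))
  if (!isTRUE(x$precomputed_sim))
    cat(sprintf("  fingerprints: %s (%d bits)\n", x$fp$kind, x$fp$n_bits))
  invisible(x)
}

#' @export
coef.gknn <- function(object, ...) {
  with(object$params, c(k = k, x = x, y = y))
}

#' @export
fitted.gknn <- function(object, ...) {
  stats::setNames(object$loo_estimate, object$data$chem_id)
}

#' @export
residuals.gknn <- function(object, ...) {
  stats::setNames(object$data[[object$endpoint]] - object$loo_estimate,
                  object$data$chem_id)
}

#' @export
summary.gknn <- function(object, ...) {
  rep <- loo_cv(object)
  out <- list(model = object, metrics = rep)
  class(out) <- "summary.gknn"
  out
}

#' @export
print.summary.gknn <- function(x, ...) {
  print(x$model)
  cat("\nleave-one-out cross-validation:\n")
  print(x$metrics)
  invisible(x)
}

#' @export
plot.gknn <- function(x, which = c("landscape", "confidence"), ...) {
  which <- match.arg(which)
  act <- x$data[[x$endpoint]]
  if (which == "landscape") {
    graphics::plot(x$loo_confidence, act - x$loo_estimate,
                   xlab = "confidence q (nearest-neighbor similarity)",
                   ylab = "LOO residual",
                   main = "residuals vs applicability domain", ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::hist(x$loo_confidence, breaks = 20,
                   xlab = "confidence q", main = "confidence distribution",
                   ...)
  }
  invisible(x)
}

#' Predict activities for new chemicals
#'
#' For each query chemical the `k` most similar training chemicals are
#' selected (by Tanimoto similarity under the model's fingerprint
#' configuration, or from a supplied cross-similarity matrix), the model
#' family's estimator is applied to their activities, and the confidence
#' `q` — the maximum similarity to any training chemical — is attached.
#' A query whose `chem_id` also appears in the training set never uses
#' itself as a neighbor (leave-one-out semantics).
#'
#' With `newdata = NULL` the training set's leave-one-out predictions are
#' returned.
#'
#' @param object fitted [gknn()] model.
#' @param newdata query dataset data.frame, or `NULL`.
#' @param similarity optional precomputed query-by-training similarity
#'   matrix (rows follow `newdata` order).
#' @param ... unused.
#' @return data.frame of class `gknn_prediction` with columns `chem_id`,
#'   `estimate`, `confidence`, `neighbor_ids`, `neighbor_sims`,
#'   `neighbor_activities` (the latter three semicolon-joined).
#' @export
predict.gknn <- function(object, newdata = NULL, similarity = NULL, ...) {
  if (is.null(newdata)) {
    nb <- lapply(seq_len(nrow(object$data)), function(i) {
      idx <- object$neighbor_order[[i]][seq_len(min(object$params$k,
                                                    length(object$neighbor_order[[i]])))]
      list(ids = object$data$chem_id[idx], sims = object$S[i, idx],
           acts = object$data[[object$endpoint]][idx])
    })
    return(prediction_frame(object$data$chem_id, object$loo_estimate,
                            object$loo_confidence, nb))
  }
  validate_dataset(newdata, endpoint = NULL,
                   require_structure = is.null(similarity))
  if (is.null(similarity)) {
    Sq <- similarity_matrix(newdata, object$data, config = object$fp)
  } else {
    Sq <- unclass(similarity)
    if (nrow(Sq) != nrow(newdata) || ncol(Sq) != nrow(object$data))
      stop_gknn("similarity matrix must be query x training",
                class = "gknn_value_error")
  }
  Sq <- unclass(Sq)
  act <- object$data[[object$endpoint]]
  train_ids <- object$data$chem_id
  p <- object$params
  est <- conf <- numeric(nrow(newdata))
  nb <- vector("list", nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    s <- Sq[i, ]
    keep <- which(train_ids != newdata$chem_id[i])
    ord <- keep[order(-s[keep], seq_along(keep))]
    idx <- ord[seq_len(min(p$k, length(ord)))]
    if (length(idx) == 0)
      stop_gknn("no training neighbors available for '",
                newdata$chem_id[i], "'", class = "gknn_value_error")
    est[i] <- estimate_activity(p$family, act[idx], s[idx], p$x, p$y)
    conf[i] <- max(s[keep])
    nb[[i]] <- list(ids = train_ids[idx], sims = s[idx], acts = act[idx])
  }
  prediction_frame(newdata$chem_id, est, conf, nb)
}

prediction_frame <- function(ids, est, conf, neighbors) {
  out <- data.frame(
    chem_id = ids, estimate = est, confidence = conf,
    neighbor_ids = vapply(neighbors, function(x)
      paste(x$ids, collapse = ";"), character(1)),
    neighbor_sims = vapply(neighbors, function(x)
      paste(format(x$sims, digits = 15, trim = TRUE), collapse = ";"),
      character(1)),
    neighbor_activities = vapply(neighbors, function(x)
      paste(format(x$acts, digits = 15, trim = TRUE), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("gknn_prediction", "data.frame")
  out
}

#' Write model predictions to CSV
#'
#' @param predictions a [predict.gknn()] result.
#' @param path output CSV file.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE)
  invisible(path)
}
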