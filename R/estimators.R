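#' kNN activity estimators
#'
#' The four neighbor-averaging rules used to turn the activities of a
#' chemical's `k` nearest training-set neighbors into an activity estimate.
#'
#' `gknn_estimate()` is the generalized estimator: a similarity-weighted
#' power mean
#' \deqn{\hat A = \left(\frac{\sum_j A_j^x S_j^y}{\sum_j S_j^y}\right)^{1/x}}
#' with exponent `x` controlling non-linearity in activity space and `y`
#' in structure space. `x = 1, y = 0` recovers the plain arithmetic mean;
#' `x -> 0` is taken as its analytic limit, the similarity-weighted
#' geometric mean; large `x` drives the estimate toward the largest
#' neighbor activity and large `y` toward the most similar neighbor's.
#' The power mean is evaluated in the log domain
#' (`exp((logsumexp(x log A + y log S) - logsumexp(y log S)) / x)`),
#' with zero-activity neighbors handled by exclusion from the numerator
#' only, so the grid's extreme exponents (up to 50) do not overflow.
#'
#' `knn_arithmetic()` is the unweighted mean; `knn_geometric()` the
#' unweighted geometric mean (any zero activity collapses it to 0);
#' `knn_exponential()` weights activities by `exp(-x d_j)` with the
#' similarity-derived distance `d_j = 1/S_j - 1`.
#'
#' Every estimator's output lies within the range of the neighbor
#' activities used.
#'
#' @param activities neighbor activity scores in `[0, 1]`.
#' @param similarities neighbor Tanimoto similarities in `[0, 1]`,
#'   same length.
#' @param x activity-space exponent (>= 0; decay rate for
#'   `knn_exponential`).
#' @param y structure-space exponent (>= 0; `gknn_estimate` only).
#' @return activity estimate in `[0, 1]`.
#' @export
gknn_estimate <- function(activities, similarities, x = 1, y = 0) {
  n <- length(activities)
  if (n == 0 || length(similarities) != n)
    stop_gknn("activities and similarities must be non-empty and equal length",
              class = "gknn_value_error")
  if (x < 0 || y < 0)
    stop_gknn("x and y must be >= 0", class = "gknn_value_error")
  check_scores(activities)
  check_scores(similarities, what = "similarity")
  lw <- if (y == 0) rep(0, n) else y * log(similarities)  # S=0 -> -Inf
  if (all(lw == -Inf)) {
    warning("all neighbor similarities are zero; using unweighted power mean",
            call. = FALSE)
    lw <- rep(0, n)
  }
  lse_w <- logsumexp(lw)
  pos <- activities > 0
  if (x == 0) {
    # analytic x->0 limit: weighted geometric mean; any zero-activity
    # neighbor with positive weight drags the limit to 0
    w <- exp(lw - lse_w)
    if (any(w[!pos] > 0)) return(0)
    est <- exp(sum((w[pos] * log(activities[pos]))[w[pos] > 0]))
  } else if (!any(pos)) {
    est <- 0
  } else {
    num <- logsumexp(x * log(activities[pos]) + lw[pos])
    est <- exp((num - lse_w) / x)
  }
  min(max(est, min(activities)), max(activities))
}

#' @rdname gknn_estimate
#' @export
knn_arithmetic <- function(activities) {
  if (length(activities) == 0)
    stop_gknn("no neighbor activities", class = "gknn_value_error")
  check_scores(activities)
  mean(activities)
}

#' @rdname gknn_estimate
#' @export
knn_geometric <- function(activities) {
  if (length(activities) == 0)
    stop_gknn("no neighbor activities", class = "gknn_value_error")
  check_scores(activities)
  if (any(activities == 0)) return(0)
  exp(mean(log(activities)))
}

#' @rdname gknn_estimate
#' @export
knn_exponential <- function(activities, similarities, x = 1) {
  n <- length(activities)
  if (n == 0 || length(similarities) != n)
    stop_gknn("activities and similarities must be non-empty and equal length",
              class = "gknn_value_error")
  if (x < 0) stop_gknn("x must be >= 0", class = "gknn_value_error")
  check_scores(activities)
  check_scores(similarities, what = "similarity")
  d <- ifelse(similarities > 0, 1 / similarities - 1, Inf)
  lw <- if (x == 0) rep(0, n) else -x * d
  if (all(!is.finite(lw))) {
    warning("all exponential weights vanished; using most similar neighbor",
            call. = FALSE)
    return(activities[[which.max(similarities)]])
  }
  w <- exp(lw - max(lw))
  sum(activities * w) / sum(w)
}

estimator_families <- c("gknn", "knn_arithmetic", "knn_geometric",
                        "knn_exponential")

# Dispatch one estimate for a neighbor slice under a given family.
estimate_activity <- function(family, activities, similarities, x, y) {
  switch(family,
         gknn = gknn_estimate(activities, similarities, x, y),
         knn_arithmetic = knn_arithmetic(activities),
         knn_geometric = knn_geometric(activities),
         knn_exponential = knn_exponential(activities, similarities, x),
         stop_gknn("unknown estimator family '", family, "'",
                   class = "gknn_value_error"))
}
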