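#' Parameter grid specification
#'
#' Default lists are the full tuning grid: `k` over ten values from 1 to
#' 50 and the exponents `x` and `y` over seventeen values from 0 to 50.
#' The realized combination count depends on the families swept, because
#' family-irrelevant parameters are collapsed (arithmetic and geometric
#' averaging ignore both exponents; exponential averaging ignores `y`).
#'
#' @param k_values admissible neighbor counts.
#' @param x_values admissible activity-space exponents (also the
#'   exponential model's decay rates).
#' @param y_values admissible structure-space exponents (gknn only).
#' @param families estimator families to sweep.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(k_values = c(1, 2, 3, 5, 7, 10, 15, 20, 30, 50),
                      x_values = c(0.0, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0, 1.5,
                                   2.0, 3.0, 5.0, 7.0, 10.0, 15.0, 20.0,
                                   30.0, 50.0),
                      y_values = x_values,
                      families = "gknn") {
  families <- match.arg(families, estimator_families, several.ok = TRUE)
  if (length(k_values) == 0 || any(k_values < 1))
    stop_gknn("k_values must be positive", class = "gknn_value_error")
  if (any(x_values < 0) || any(y_values < 0))
    stop_gknn("x_values and y_values must be >= 0",
              class = "gknn_value_error")
  structure(list(k_values = sort(unique(as.integer(k_values))),
                 x_values = sort(unique(x_values)),
                 y_values = sort(unique(y_values)),
                 families = families),
            class = "grid_spec")
}

grid_rows <- function(grid) {
  rows <- lapply(grid$families, function(fam) {
    xs <- switch(fam, gknn = grid$x_values,
                 knn_exponential = grid$x_values, NA_real_)
    ys <- if (fam == "gknn") grid$y_values else NA_real_
    expand.grid(family = fam, k = grid$k_values, x = xs, y = ys,
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  })
  out <- do.call(rbind, rows)
  # deterministic sweep order: family, then k, x, y ascending
  out[order(match(out$family, estimator_families), out$k, out$x, out$y,
            na.last = TRUE), , drop = FALSE]
}

#' Leave-one-out grid search over model parameterizations
#'
#' Runs leave-one-out cross-validation for every (family, k, x, y)
#' combination in the grid and ranks parameterizations by the composite
#' score (balanced accuracy x accuracy x ROC AUC). The training
#' self-similarity matrix and the per-chemical sorted neighbor lists are
#' computed once and shared across all folds and all grid points, which
#' is what makes the thousands of leave-one-out sweeps tractable.
#'
#' Rows whose composite score is undefined (degenerate confusion counts)
#' rank below all defined scores; ties are ordered by family, `k`, `x`,
#' `y` ascending, so reruns are byte-identical.
#'
#' @param data training dataset data.frame.
#' @param grid a [grid_spec()].
#' @param endpoint activity column to model.
#' @param fp an [fp_config()] for structure-based similarity.
#' @param similarity optional precomputed self-similarity matrix.
#' @param threshold activity cutoff for the metrics.
#' @return object of class `gknn_grid`: list with `table` (one row per
#'   combination, sorted by score descending), `best` (its top row),
#'   `ties` (rows within `tie_tol` of the best score), `n_combinations`,
#'   and `errors` (per-row failure messages, if any).
#' @param tie_tol score tolerance for reporting ties with the best row.
#' @export
grid_search <- function(data, grid = grid_spec(), endpoint = "activity",
                        fp = fp_config(), similarity = NULL,
                        threshold = 0.1, tie_tol = 1e-6) {
  validate_dataset(data, endpoint, require_structure = is.null(similarity))
  n <- nrow(data)
  if (n < 2)
    stop_gknn("grid search needs at least 2 chemicals",
              class = "gknn_value_error")
  if (is.null(similarity)) {
    S <- similarity_matrix(data, config = fp)
  } else {
    S <- unclass(similarity)
  }
  S <- unclass(S)
  act <- data[[endpoint]]
  ord <- precompute_loo_order(S)
  combos <- grid_rows(grid)
  message(sprintf("grid search: %d combinations over %d chemicals",
                  nrow(combos), n))
  errors <- character(0)
  res <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    cmb <- combos[r, ]
    res[[r]] <- tryCatch({
      if (n < cmb$k + 1)
        stop_gknn("k = ", cmb$k, " needs at least ", cmb$k + 1,
                  " chemicals", class = "gknn_value_error")
      est <- vapply(seq_len(n), function(i) {
        nb <- ord[[i]][seq_len(min(cmb$k, length(ord[[i]])))]
        estimate_activity(cmb$family, act[nb], S[i, nb],
                          if (is.na(cmb$x)) 1 else cmb$x,
                          if (is.na(cmb$y)) 0 else cmb$y)
      }, numeric(1))
      metrics_row(qsar_metrics(act, est, threshold))
    }, error = function(e) {
      errors[[length(errors) + 1]] <<- sprintf(
        "%s k=%s x=%s y=%s: %s", cmb$family, cmb$k, cmb$x, cmb$y,
        conditionMessage(e))
      metrics_row(list(sensitivity = NA_real_, specificity = NA_real_,
                       balanced_accuracy = NA_real_, accuracy = NA_real_,
                       precision = NA_real_, npv = NA_real_,
                       roc_auc = NA_real_, score = NA_real_, n = n))
    })
  }
  table <- cbind(combos, do.call(rbind, res))
  rownames(table) <- NULL
  score_key <- ifelse(is.finite(table$score), -table$score, Inf)
  table <- table[order(score_key, match(table$family, estimator_families),
                       table$k, table$x, table$y, na.last = TRUE), ,
                 drop = FALSE]
  rownames(table) <- NULL
  best <- table[1, , drop = FALSE]
  ties <- if (is.finite(best$score))
    table[is.finite(table$score) &
            abs(table$score - best$score) <= tie_tol, , drop = FALSE]
  else table[0, , drop = FALSE]
  structure(list(table = table, best = best, ties = ties,
                 n_combinations = nrow(combos), errors = errors,
                 endpoint = endpoint, threshold = threshold),
            class = "gknn_grid")
}

#' @export
print.gknn_grid <- function(x, ...) {
  cat(sprintf("grid search (%s): %d combinations evaluated\n",
              x$endpoint, x$n_combinations))
  b <- x$best
  cat(sprintf("  best: %s k=%d x=%s y=%s  score %.4f (bal acc %.3f, acc %.3f, AUC %.3f)\n",
              b$family, b$k, format(b$x), format(b$y), b$score,
              b$balanced_accuracy, b$accuracy, b$roc_auc))
  if (nrow(x$ties) > 1)
    cat(sprintf("  %d parameterizations within tolerance of the best score\n",
                nrow(x$ties)))
  if (length(x$errors))
    cat(sprintf("  %d combinations failed\n", length(x$errors)))
  invisible(x)
}

#' Export a grid-search table as CSV
#'
#' @param result a [grid_search()] result.
#' @param path output CSV.
#' @export
write_grid <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
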