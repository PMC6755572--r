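#' Distribution of pairwise molecular similarities
#'
#' Histogram of the pairwise similarity values — the chemical-space analog
#' of a radial distribution function. For a self-similarity matrix only the
#' off-diagonal upper triangle enters (each unordered pair once); for a
#' cross-set matrix all entries enter. Counts are normalized to sum to 1.
#'
#' @param sm similarity matrix.
#' @param bins number of equal-width bins over `[0, 1]`.
#' @param self treat `sm` as a self-similarity matrix; default guesses from
#'   symmetry of the dimnames.
#' @return data.frame with `lower`, `upper`, `frac` columns.
#' @export
similarity_distribution <- function(sm, bins = 20,
                                    self = is_self_matrix(sm)) {
  if (bins < 1) stop_gknn("bins must be >= 1", class = "gknn_value_error")
  if (self) {
    if (nrow(sm) < 2)
      stop_gknn("need at least 2 chemicals for a self-set distribution",
                class = "gknn_value_error")
    vals <- sm[upper.tri(sm)]
  } else {
    vals <- as.vector(unclass(sm))
  }
  edges <- seq(0, 1, length.out = bins + 1)
  cut_idx <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L),
                  bins)
  counts <- tabulate(cut_idx, nbins = bins)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             frac = counts / length(vals))
}

is_self_matrix <- function(sm) {
  nrow(sm) == ncol(sm) &&
    (is.null(rownames(sm)) || identical(rownames(sm), colnames(sm)))
}

#' Eigenprojection of a chemical set
#'
#' Projects chemicals onto the leading eigenvectors of the double-centered
#' self-similarity matrix (the kernel-PCA convention with the Tanimoto
#' matrix as kernel). Coordinates are fingerprint-length independent, and
#' new chemicals can be placed in the same space from their similarity rows
#' to the training set via `predict()`.
#'
#' @param sm symmetric self-similarity matrix of the training set.
#' @param m number of leading eigen-directions to keep (default 3).
#' @return object of class `chem_projection` with `coordinates`
#'   (n x m matrix), `eigenvalues` (nonincreasing, full spectrum), and the
#'   centering information needed for out-of-sample projection.
#' @export
eigenprojection <- function(sm, m = 3) {
  n <- nrow(sm)
  if (m < 1 || m > n)
    stop_gknn("m must lie in [1, number of chemicals]",
              class = "gknn_value_error")
  K <- unclass(sm)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-8)
    stop_gknn("eigenprojection needs a symmetric self-similarity matrix",
              class = "gknn_value_error")
  K <- (K + t(K)) / 2
  rowmu <- rowMeans(K)
  mu <- mean(K)
  Kc <- K - outer(rowmu, rep(1, n)) - outer(rep(1, n), rowmu) + mu
  e <- eigen(Kc, symmetric = TRUE)
  lam <- e$values
  V <- e$vectors[, seq_len(m), drop = FALSE]
  lam_m <- pmax(lam[seq_len(m)], 0)
  coords <- V %*% diag(sqrt(lam_m), m)
  rownames(coords) <- rownames(sm)
  colnames(coords) <- paste0("pc", seq_len(m))
  structure(list(coordinates = coords, eigenvalues = lam, m = m,
                 vectors = V, lambda_m = lam_m, row_means = rowmu,
                 grand_mean = mu, train_ids = rownames(sm)),
            class = "chem_projection")
}

#' @export
print.chem_projection <- function(x, ...) {
  cat(sprintf("chemical-space eigenprojection: %d chemicals, %d components\n",
              nrow(x$coordinates), x$m))
  tot <- sum(pmax(x$eigenvalues, 0))
  cat(sprintf("  leading eigenvalues: %s (%.1f%% of positive spectrum)\n",
              paste(signif(x$eigenvalues[seq_len(x$m)], 4), collapse = ", "),
              if (tot > 0) 100 * sum(x$lambda_m) / tot else 0))
  invisible(x)
}

#' Project new chemicals into a fitted eigenprojection
#'
#' @param object a [eigenprojection()] result.
#' @param newdata similarity matrix (rows = new chemicals, columns = the
#'   training chemicals in original order).
#' @param ... unused.
#' @return coordinate matrix, one row per new chemical.
#' @export
predict.chem_projection <- function(object, newdata, ...) {
  Kq <- unclass(newdata)
  if (ncol(Kq) != length(object$row_means))
    stop_gknn("newdata must have one column per training chemical",
              class = "gknn_value_error")
  n <- length(object$row_means)
  Kqc <- Kq - matrix(rowMeans(Kq), nrow(Kq), n) -
    matrix(object$row_means, nrow(Kq), n, byrow = TRUE) + object$grand_mean
  denom <- sqrt(object$lambda_m)
  denom[denom == 0] <- Inf  # degenerate directions map to 0
  coords <- Kqc %*% object$vectors %*% diag(1 / denom, object$m)
  colnames(coords) <- paste0("pc", seq_len(object$m))
  rownames(coords) <- rownames(Kq)
  coords
}

#' Export projection coordinates as CSV
#'
#' @param projection a `chem_projection`.
#' @param path output CSV (`chem_id, pc1..pcm`).
#' @export
write_projection <- function(projection, path) {
  df <- data.frame(chem_id = rownames(projection$coordinates),
                   projection$coordinates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Nearest neighbors of a chemical
#'
#' Returns the `k` reference chemicals most similar to `chem`, in
#' descending similarity, self excluded when the query set is the
#' reference set (matching identifiers). Ties are broken by reference
#' dataset order, so the list is deterministic.
#'
#' @param sm similarity matrix (rows = queries, columns = references).
#' @param chem query chemical identifier (must be a row of `sm`).
#' @param k number of neighbors; if fewer are available the list is
#'   truncated with a warning.
#' @return data.frame with `chem_id` and `similarity` columns.
#' @export
neighbor_list <- function(sm, chem, k) {
  if (k < 1) stop_gknn("k must be >= 1", class = "gknn_value_error")
  i <- match(chem, rownames(sm))
  if (is.na(i))
    stop_gknn("chemical '", chem, "' not found among query rows",
              class = "gknn_value_error")
  s <- as.numeric(sm[i, ])
  ids <- colnames(sm)
  keep <- if (!is.null(ids)) ids != chem else rep(TRUE, length(s))
  s <- s[keep]; ids <- ids[keep]
  if (k > length(s)) {
    warning(sprintf("only %d neighbors available for '%s' (k = %d)",
                    length(s), chem, k), call. = FALSE)
    k <- length(s)
  }
  ord <- order(-s, seq_along(s))[seq_len(k)]
  data.frame(chem_id = ids[ord], similarity = s[ord],
             stringsAsFactors = FALSE)
}

#' Overlap fraction between two neighbor lists
#'
#' `|ids(a) intersect ids(b)| / max(|a|, |b|)`; order is ignored, so the
#' measure captures how much two fingerprint choices agree on who the
#' neighbors are, not on their ranking.
#'
#' @param a,b neighbor lists ([neighbor_list()] data.frames or id vectors).
#' @return overlap fraction in `[0, 1]`.
#' @export
neighbor_overlap <- function(a, b) {
  ids <- function(x) if (is.data.frame(x)) x$chem_id else as.character(x)
  a <- ids(a); b <- ids(b)
  if (length(a) == 0 || length(b) == 0)
    stop_gknn("neighbor lists must be non-empty", class = "gknn_value_error")
  length(intersect(a, b)) / max(length(a), length(b))
}
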