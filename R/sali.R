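#' Structure-activity landscape index (SALI)
#'
#' `sali()` scores one pair of chemicals:
#' `|A_i - A_j| / (1 - S_ij)`. Structurally similar pairs with very
#' different activities (activity cliffs) score high; identical
#' fingerprints (`S_ij == 1`) make the index undefined and return `Inf`,
#' which downstream analyses report separately rather than plot.
#'
#' @param activity_i,activity_j activity scores in `[0, 1]`.
#' @param s_ij Tanimoto similarity of the pair, in `[0, 1]`.
#' @return nonnegative SALI value; `Inf` when `s_ij == 1`.
#' @export
sali <- function(activity_i, activity_j, s_ij) {
  check_scores(c(activity_i, activity_j))
  check_scores(s_ij, what = "similarity")
  ifelse(s_ij == 1, Inf, abs(activity_i - activity_j) / (1 - s_ij))
}

#' SALI analysis of a chemical set
#'
#' Computes the SALI index for every unordered pair in a dataset, the
#' maximum SALI per chemical (which singles out the chemicals forming
#' activity cliffs), and the list of identical-fingerprint pairs whose
#' index is undefined.
#'
#' @param data dataset data.frame.
#' @param sm self-similarity matrix of `data` (same order).
#' @param endpoint activity column to analyze.
#' @return object of class `sali_result`: list with `pairwise`
#'   (data.frame `chem_i, chem_j, similarity, sali` over finite pairs),
#'   `max_per_chemical` (named numeric), and `capped_pairs` (data.frame of
#'   `S == 1` pairs, excluded from the finite statistics).
#' @export
sali_analysis <- function(data, sm, endpoint = "activity") {
  validate_dataset(data, endpoint)
  n <- nrow(data)
  if (n < 2)
    stop_gknn("SALI analysis needs at least 2 chemicals",
              class = "gknn_value_error")
  if (nrow(sm) != n || ncol(sm) != n)
    stop_gknn("similarity matrix does not match the dataset",
              class = "gknn_value_error")
  act <- data[[endpoint]]
  ids <- data$chem_id
  ut <- which(upper.tri(sm), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]  # row-major pair order
  s <- unclass(sm)[ut]
  gap <- abs(act[ut[, 1]] - act[ut[, 2]])
  capped <- s == 1
  pairwise <- data.frame(chem_i = ids[ut[!capped, 1]],
                         chem_j = ids[ut[!capped, 2]],
                         similarity = s[!capped],
                         sali = gap[!capped] / (1 - s[!capped]),
                         stringsAsFactors = FALSE)
  max_per <- stats::setNames(rep(0, n), ids)
  for (r in seq_len(nrow(pairwise))) {
    v <- pairwise$sali[r]
    i <- pairwise$chem_i[r]; j <- pairwise$chem_j[r]
    if (v > max_per[[i]]) max_per[[i]] <- v
    if (v > max_per[[j]]) max_per[[j]] <- v
  }
  no_finite <- !(ids %in% c(pairwise$chem_i, pairwise$chem_j))
  max_per[no_finite] <- NA_real_
  structure(list(pairwise = pairwise, max_per_chemical = max_per,
                 capped_pairs = data.frame(
                   chem_i = ids[ut[capped, 1]], chem_j = ids[ut[capped, 2]],
                   activity_gap = gap[capped], stringsAsFactors = FALSE),
                 endpoint = endpoint),
            class = "sali_result")
}

#' @export
print.sali_result <- function(x, ...) {
  cat(sprintf("SALI analysis (%s): %d finite pairs, %d identical-fingerprint pairs\n",
              x$endpoint, nrow(x$pairwise), nrow(x$capped_pairs)))
  if (nrow(x$pairwise) > 0)
    cat(sprintf("  max SALI %.3f; top chemical: %s\n",
                max(x$max_per_chemical, na.rm = TRUE),
                names(which.max(x$max_per_chemical))))
  invisible(x)
}

#' Histogram of finite SALI values on log-spaced bins
#'
#' SALI values span orders of magnitude, so the distribution is binned on a
#' logarithmic grid; zero values are reported as their own bin.
#'
#' @param result a [sali_analysis()] result.
#' @param bins number of log-spaced bins across the positive values.
#' @return data.frame with `lower`, `upper`, `frac` (the first row, with
#'   `lower == upper == 0`, holds the zero-SALI mass).
#' @export
sali_distribution <- function(result, bins = 20) {
  v <- result$pairwise$sali
  if (length(v) == 0)
    stop_gknn("no finite SALI pairs to bin", class = "gknn_value_error")
  pos <- v[v > 0]
  zero_frac <- mean(v == 0)
  if (length(pos) == 0)
    return(data.frame(lower = 0, upper = 0, frac = 1))
  edges <- exp(seq(log(min(pos)), log(max(pos)), length.out = bins + 1))
  idx <- pmin(pmax(findInterval(pos, edges, rightmost.closed = TRUE), 1L),
              bins)
  counts <- tabulate(idx, nbins = bins)
  rbind(data.frame(lower = 0, upper = 0, frac = zero_frac),
        data.frame(lower = edges[-length(edges)], upper = edges[-1],
                   frac = counts / length(v)))
}

#' Export SALI results as CSV
#'
#' Writes the pairwise table (`id_i, id_j, similarity, sali`) and the
#' per-chemical maxima (`chem_id, max_sali`).
#'
#' @param result a [sali_analysis()] result.
#' @param pairwise_path,max_path output CSV paths (either may be `NULL`).
#' @export
write_sali <- function(result, pairwise_path = NULL, max_path = NULL) {
  if (!is.null(pairwise_path))
    utils::write.csv(result$pairwise, pairwise_path, row.names = FALSE)
  if (!is.null(max_path))
    utils::write.csv(data.frame(chem_id = names(result$max_per_chemical),
                                max_sali = unname(result$max_per_chemical)),
                     max_path, row.names = FALSE)
  invisible(NULL)
}
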