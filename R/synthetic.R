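#' Specification for a synthetic chemical set
#'
#' Describes a seeded synthetic dataset with controlled
#' structure-activity landscape ruggedness, standing in for curated
#' screening data so that every operation in the package can be exercised
#' without external downloads.
#'
#' Two modes:
#' \describe{
#'   \item{`abstract_matrix`}{no structures; latent points in the plane
#'     define a similarity matrix `S = 1 - min(1, d/c)` (unit diagonal,
#'     symmetric, and `1 - S` a true metric, so similarity obeys the
#'     triangle inequality). Best for estimator and metric math where
#'     expected outputs are computable by hand.}
#'   \item{`real_smiles`}{a deterministic roster of valid SMILES strings
#'     enumerated from aromatic/aliphatic scaffolds with substituent
#'     decorations; similarities come from actual fingerprints.}
#' }
#'
#' Landscapes:
#' \describe{
#'   \item{`smooth`}{activity is a piecewise-linear (hence Lipschitz)
#'     monotone function of similarity to a designated seed chemical,
#'     calibrated so that exactly `n_actives` chemicals exceed the 0.1
#'     activity threshold in the noise-free case; because `1 - S` is a
#'     metric, the SALI of every pair is bounded by the map's Lipschitz
#'     constant (returned as the `lipschitz` attribute).}
#'   \item{`cliff`}{smooth, plus `n_cliff_pairs` engineered activity
#'     cliffs: near-duplicate chemicals (similarity 0.9) assigned an
#'     activity gap of 0.9, forcing SALI >= 9 for those pairs.}
#'   \item{`random`}{activities i.i.d. uniform — a maximally rugged,
#'     unlearnable landscape.}
#' }
#'
#' Per-chemical source counts and binary per-source calls are also
#' synthesized (most chemicals consistent with their consensus activity in
#' >= 80% of calls, a seeded minority inconsistent) so source-consistency
#' filtering is testable.
#'
#' @param n_chemicals number of chemicals.
#' @param mode `"abstract_matrix"` or `"real_smiles"`.
#' @param landscape `"smooth"`, `"cliff"` or `"random"`.
#' @param n_actives number of chemicals whose activity exceeds 0.1
#'   (exactly, in noise-free smooth/cliff landscapes).
#' @param activity_noise standard deviation of Gaussian noise added to the
#'   activities (clamped back to `[0, 1]`); 0 keeps the landscape exact.
#' @param n_cliff_pairs engineered cliff pairs in `cliff` mode.
#' @param seed integer seed; the same spec always generates byte-identical
#'   data, and the global RNG state is left untouched.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chemicals = 60,
                           mode = c("abstract_matrix", "real_smiles"),
                           landscape = c("smooth", "cliff", "random"),
                           n_actives = max(1L, round(0.2 * n_chemicals)),
                           activity_noise = 0,
                           n_cliff_pairs = 1L,
                           seed = 1L) {
  mode <- match.arg(mode)
  landscape <- match.arg(landscape)
  if (n_chemicals < 2)
    stop_gknn("n_chemicals must be >= 2", class = "gknn_config_error")
  if (n_actives > n_chemicals || n_actives < 0)
    stop_gknn("need 0 <= n_actives <= n_chemicals",
              class = "gknn_config_error")
  if (activity_noise < 0)
    stop_gknn("activity_noise must be >= 0", class = "gknn_config_error")
  structure(list(n_chemicals = as.integer(n_chemicals), mode = mode,
                 landscape = landscape, n_actives = as.integer(n_actives),
                 activity_noise = activity_noise,
                 n_cliff_pairs = as.integer(n_cliff_pairs),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic chemical dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (canonical dataset data.frame) and
#'   `similarity` (a `similarity_matrix` in `abstract_matrix` mode,
#'   otherwise `NULL`; compute one with [similarity_matrix()]). The
#'   `data` element carries a `lipschitz` attribute in smooth/cliff
#'   landscapes (bound on finite SALI values of the noise-free smooth
#'   part) and a `cliff_pairs` attribute listing engineered cliffs.
#' @export
generate_chemicals <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_gknn("spec must be a synthetic_spec", class = "gknn_config_error")
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  n <- spec$n_chemicals
  ids <- sprintf("syn%03d", seq_len(n))
  if (spec$mode == "abstract_matrix") {
    z <- matrix(stats::runif(2 * n), n, 2)
    if (spec$landscape != "random" && spec$n_actives > 0 &&
        spec$n_actives < n)
      z <- enforce_boundary_gap(z, spec$n_actives, margin = 0.04)
    smiles <- rep(NA_character_, n)
  } else {
    smiles <- smiles_roster(n)
    z <- NULL
  }
  cliff_idx <- matrix(integer(0), 0, 2)
  if (spec$mode == "abstract_matrix" && spec$landscape == "cliff" &&
      spec$n_cliff_pairs > 0) {
    # engineer near-duplicates: chemical n-2m+1 cloned into n-2m+2, then
    # the clone pair is separated to similarity 0.9 exactly
    for (m in seq_len(spec$n_cliff_pairs)) {
      a <- n - 2 * m + 2; b <- n - 2 * m + 1
      cliff_idx <- rbind(cliff_idx, c(b, a))
      z[a, ] <- z[b, ]
    }
  }
  if (!is.null(z)) {
    d <- as.matrix(stats::dist(z))
    S <- 1 - d / max(d)  # 1 - S inherits the triangle inequality
    if (nrow(cliff_idx))
      for (r in seq_len(nrow(cliff_idx))) {
        i <- cliff_idx[r, 1]; j <- cliff_idx[r, 2]
        S[i, j] <- S[j, i] <- 0.9
      }
    diag(S) <- 1
    dimnames(S) <- list(ids, ids)
    sim_to_seed <- S[, 1]
  } else {
    S <- NULL
    fps <- fingerprints(smiles, fp_config(), ids = ids)
    sim_self <- unclass(similarity_matrix(fps))
    sim_to_seed <- sim_self[, 1]
    if (spec$landscape == "cliff" && spec$n_cliff_pairs > 0) {
      # designate the most similar distinct-fingerprint pairs as cliffs
      ut <- which(upper.tri(sim_self), arr.ind = TRUE)
      s <- sim_self[ut]
      ok <- which(s < 1)
      ord <- ok[order(-s[ok], seq_along(ok))]
      used <- integer(0)
      for (r in ord) {
        if (nrow(cliff_idx) >= spec$n_cliff_pairs) break
        if (any(ut[r, ] %in% used)) next
        cliff_idx <- rbind(cliff_idx, ut[r, , drop = FALSE])
        used <- c(used, ut[r, ])
      }
    }
  }
  act <- switch(spec$landscape,
                random = stats::runif(n),
                landscape_activities(sim_to_seed, spec$n_actives))
  lipschitz <- attr(act, "lipschitz")
  if (spec$landscape == "cliff" && length(cliff_idx)) {
    for (r in seq_len(nrow(cliff_idx))) {
      act[cliff_idx[r, 1]] <- 0.95
      act[cliff_idx[r, 2]] <- 0.05
    }
  }
  if (spec$activity_noise > 0)
    act <- pmin(1, pmax(0, act + stats::rnorm(n, 0, spec$activity_noise)))
  act <- as.numeric(act)
  active <- act > 0.1
  n_sources <- 1L + stats::rpois(n, 5)
  inconsistent <- stats::runif(n) < 0.2
  calls <- vapply(seq_len(n), function(i) {
    k <- n_sources[i]
    maj <- if (inconsistent[i]) 0.6 else 0.9
    n_major <- max(ceiling(maj * k), ifelse(k == 1, 1, k - floor(k / 2)))
    votes <- c(rep(if (active[i]) 1L else 0L, n_major),
               rep(if (active[i]) 0L else 1L, k - n_major))
    paste(votes[sample.int(k)], collapse = ";")
  }, character(1))
  data <- data.frame(chem_id = ids, smiles = smiles, activity = act,
                     n_sources = n_sources, source_calls = calls,
                     stringsAsFactors = FALSE)
  attr(data, "lipschitz") <- lipschitz
  if (length(cliff_idx))
    attr(data, "cliff_pairs") <- data.frame(chem_i = ids[cliff_idx[, 1]],
                                            chem_j = ids[cliff_idx[, 2]])
  list(data = data,
       similarity = if (!is.null(S))
         structure(S, class = c("similarity_matrix", "matrix")))
}

# Guarantee a seed-distance margin between the least similar active and
# the most similar inactive (relative to the maximum pairwise distance),
# by moving the inactive shell radially away from the seed. Keeps the
# activity map's boundary segment from becoming an accidental cliff.
enforce_boundary_gap <- function(z, n_actives, margin) {
  d0 <- sqrt(colSums((t(z) - z[1, ])^2))
  ds <- sort(d0)
  gap <- ds[n_actives + 1] - ds[n_actives]
  need <- margin * max(stats::dist(z))
  if (gap >= need) return(z)
  far <- d0 >= ds[n_actives + 1]
  dir <- z[far, , drop = FALSE] -
    matrix(z[1, ], sum(far), ncol(z), byrow = TRUE)
  len <- sqrt(rowSums(dir^2))
  z[far, ] <- matrix(z[1, ], sum(far), ncol(z), byrow = TRUE) +
    dir * ((len + need - gap) / len)
  z
}

# Piecewise-linear monotone map from similarity-to-seed to activity,
# calibrated so exactly n_actives chemicals exceed 0.1. The breakpoint is
# the midpoint between the n-th and (n+1)-th largest similarity. Inactive
# chemicals map into [0, 0.01] and actives into (0.1, 1], leaving the
# uncertain (0.01, 0.1) band empty — the score structure of a curated
# training set from which that band has been removed.
landscape_activities <- function(sim_to_seed, n_actives) {
  n <- length(sim_to_seed)
  u <- sim_to_seed
  if (n_actives == 0) {
    act <- 0.01 * u
    attr(act, "lipschitz") <- 0.01
    return(act)
  }
  # calibrate over distinct similarity values so tied chemicals are never
  # split across the class boundary; with ties the realized active count
  # is the closest achievable one (exact when similarities are distinct)
  vals <- sort(unique(u), decreasing = TRUE)
  counts <- vapply(vals, function(v) sum(u >= v), numeric(1))
  pick <- which.min(abs(counts - n_actives))
  if (counts[pick] == n) {
    act <- 0.1 + 0.9 * u
    attr(act, "lipschitz") <- 0.9
    return(act)
  }
  u_act <- vals[pick]            # least similar active
  u_inact <- max(u[u < u_act])   # most similar inactive
  a_act <- 0.101
  lo_slope <- if (u_inact > 0) min(0.01 / u_inact, 3) else 0
  mid_slope <- (a_act - 0.01) / (u_act - u_inact)
  # actives span [0.101, a_max], capping the segment slope at 3 so a
  # tight active cluster cannot masquerade as an activity cliff
  a_max <- if (u_act < max(u))
    min(1, a_act + 3 * (max(u) - u_act)) else a_act
  hi_slope <- if (u_act < max(u)) (a_max - a_act) / (max(u) - u_act) else 0
  act <- ifelse(u <= u_inact, lo_slope * u,
                ifelse(u < u_act, 0.01 + mid_slope * (u - u_inact),
                       pmin(a_max, a_act + hi_slope * (u - u_act))))
  act <- pmin(1, pmax(0, act))
  attr(act, "lipschitz") <- max(lo_slope, mid_slope, hi_slope)
  act
}

# Deterministic roster of valid SMILES: scaffold cores decorated with up
# to two substituents, enumerated in fixed order. R1 sits in a branch,
# R2 is a trailing chain position, so every combination stays parseable.
smiles_roster <- function(n) {
  cores <- c("c1cc(R1)ccc1R2", "c1cc(R1)cnc1R2", "C1CC(R1)CCC1R2",
             "c1cc(R1)oc1R2", "c1cc(R1)sc1R2", "O=C(OR2)c1ccc(R1)cc1",
             "c1ccc2cc(R1)ccc2c1R2", "C(R1)CCCCR2")
  subs <- c("", "C", "O", "N", "Cl", "F", "CC", "OC", "C#N", "C(=O)O",
            "Br", "C(C)C")
  out <- character(0)
  for (s2 in subs) for (s1 in subs) for (core in cores) {
    smi <- if (nzchar(s1)) sub("(R1)", paste0("(", s1, ")"), core,
                               fixed = TRUE)
           else sub("(R1)", "", core, fixed = TRUE)
    smi <- sub("R2", s2, smi, fixed = TRUE)
    out <- c(out, smi)
  }
  out <- unique(out)
  if (length(out) < n)
    stop_gknn("roster exhausted: at most ", length(out),
              " distinct synthetic structures available",
              class = "gknn_config_error")
  out[seq_len(n)]
}
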