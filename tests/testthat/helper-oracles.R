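# Independent oracles: deliberately naive transcriptions of the formulas,
# kept free of the numerical tricks used by the implementation.

# Direct power-mean transcription (no log domain).
naive_gknn <- function(activities, similarities, x, y) {
  w <- similarities^y
  if (x == 0) {
    if (any(activities == 0 & w > 0)) return(0)
    return(prod(activities^(w / sum(w))))
  }
  (sum(activities^x * w) / sum(w))^(1 / x)
}

naive_exponential <- function(activities, similarities, x) {
  d <- 1 / similarities - 1
  w <- exp(-x * d)
  sum(activities * w) / sum(w)
}

# O(n^2) Mann-Whitney pair count, ties scored one half.
brute_auc <- function(truth_active, scores) {
  pos <- scores[truth_active]
  neg <- scores[!truth_active]
  if (length(pos) == 0 || length(neg) == 0) return(NaN)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Element-wise Tanimoto double loop over fingerprint rows.
brute_similarity <- function(fpa, fpb) {
  out <- matrix(NA_real_, nrow(fpa), nrow(fpb))
  for (i in seq_len(nrow(fpa))) for (j in seq_len(nrow(fpb)))
    out[i, j] <- tanimoto(fpa[i, ], fpb[j, ])
  out
}

# Triple-loop SALI over all unordered pairs.
brute_sali <- function(activities, S) {
  n <- length(activities)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (S[i, j] == 1) next
    out <- rbind(out, data.frame(
      i = i, j = j, sali = abs(activities[i] - activities[j]) / (1 - S[i, j])))
  }
  out
}

# Leave-one-out by literally refitting on the n-1 remaining chemicals and
# predicting the held-out one through the public interface.
naive_loo <- function(data, S, family, k, x, y, endpoint = "activity") {
  n <- nrow(data)
  vapply(seq_len(n), function(i) {
    fit <- gknn(data[-i, , drop = FALSE], endpoint = endpoint,
                family = family, k = k, x = x, y = y,
                similarity = S[-i, -i, drop = FALSE])
    predict(fit, newdata = data[i, , drop = FALSE],
            similarity = S[i, -i, drop = FALSE])$estimate
  }, numeric(1))
}

# Arbitrary-precision power-mean oracle (50 significant digits) through
# python/mpmath; returns NULL when the backend is unavailable so the
# caller can fall back to a rescaled double-precision evaluation.
mpmath_gknn <- function(cases, x, y) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  data_file <- tempfile()
  writeLines(vapply(cases, function(cs)
    paste(fmt(cs$A), fmt(cs$S), sep = ";"), character(1)), data_file)
  script_file <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "try:",
    "    import mpmath as mp",
    "except ImportError:",
    "    sys.exit(3)",
    "mp.mp.dps = 50",
    sprintf("x = mp.mpf('%.17g'); y = mp.mpf('%.17g')", x, y),
    "for line in open(sys.argv[1]):",
    "    a_s, s_s = line.strip().split(';')",
    "    A = [mp.mpf(t) for t in a_s.split(',')]",
    "    S = [mp.mpf(t) for t in s_s.split(',')]",
    "    num = mp.fsum(ai**x * si**y for ai, si in zip(A, S))",
    "    den = mp.fsum(si**y for si in S)",
    "    print(mp.nstr((num / den)**(1 / x), 25))"), script_file)
  out <- tryCatch(
    suppressWarnings(system2(py, c(script_file, data_file),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL)
  if (is.null(out) || length(out) != length(cases)) return(NULL)
  vals <- suppressWarnings(as.numeric(out))
  if (anyNA(vals)) return(NULL)
  vals
}

# Random abstract fixture helpers.
abstract_set <- function(n, seed, landscape = "smooth",
                         n_actives = max(1, round(0.25 * n)), noise = 0) {
  generate_chemicals(synthetic_spec(
    n_chemicals = n, mode = "abstract_matrix", landscape = landscape,
    n_actives = n_actives, activity_noise = noise, seed = seed))
}

random_fp_pair <- function(n_bits = 64) {
  a <- runif(n_bits) < 0.3
  b <- runif(n_bits) < 0.3
  list(a = a, b = b)
}
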