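test_that("gknn_estimate reproduces hand-computed cases", {
  expect_equal(gknn_estimate(0.42, 0.3, x = 2.5, y = 7), 0.42)
  expect_equal(gknn_estimate(c(0.2, 0.4, 0.9), c(0.1, 0.5, 0.9),
                             x = 1, y = 0), 0.5)
  expect_equal(gknn_estimate(c(1.0, 0.0), c(0.8, 0.2), x = 1, y = 1), 0.8)
  # power mean approaches the max as x grows
  expect_lt(abs(gknn_estimate(c(0.2, 0.9), c(0.5, 0.5), x = 50, y = 1) -
                  0.9), 0.05)
  expect_error(gknn_estimate(c(0.2), c(0.5, 0.6), x = 1, y = 1),
               class = "gknn_value_error")
  expect_error(gknn_estimate(0.5, 0.5, x = -1, y = 0),
               class = "gknn_value_error")
})

test_that("simple averaging estimators match their definitions", {
  expect_equal(knn_arithmetic(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(knn_arithmetic(0.7), 0.7)
  expect_equal(knn_geometric(c(0.25, 1.0)), 0.5)
  expect_equal(knn_geometric(c(0.0, 0.9, 0.9)), 0.0)
  expect_equal(knn_geometric(0.6), 0.6)
  expect_error(knn_arithmetic(numeric(0)), class = "gknn_value_error")
  expect_error(knn_geometric(numeric(0)), class = "gknn_value_error")
})

test_that("exponential averaging weights by similarity-derived distance", {
  # S = (1, 0.5) -> d = (0, 1); with x = 1, A = (1, 0): e/(e+1)
  expect_equal(knn_exponential(c(1, 0), c(1.0, 0.5), x = 1),
               exp(1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(knn_exponential(c(0.2, 0.8), c(0.9, 0.3), x = 0), 0.5)
  expect_equal(knn_exponential(0.35, 0.4, x = 3), 0.35)
  expect_warning(out <- knn_exponential(c(0.3, 0.9), c(0, 0), x = 2),
                 "most similar")
  expect_equal(out, 0.3)
})

test_that("estimator reductions hold across seeded random instances", {
  withr::with_seed(101, {
    for (r in 1:100) {
      k <- sample(3:20, 1)
      A <- runif(k); S <- runif(k, 0.01, 1)
      expect_equal(gknn_estimate(A, S, x = 1, y = 0), knn_arithmetic(A),
                   tolerance = 1e-12)
      expect_equal(knn_exponential(A, S, x = 0), knn_arithmetic(A),
                   tolerance = 1e-12)
      expect_equal(gknn_estimate(A[1], S[1], x = runif(1, 0.1, 5),
                                 y = runif(1, 0, 5)), A[1],
                   tolerance = 1e-12)
    }
  })
})

test_that("gknn x -> 0 equals the similarity-weighted geometric mean", {
  withr::with_seed(57, {
    for (r in 1:25) {
      k <- sample(2:8, 1)
      A <- runif(k, 0.05, 1); S <- runif(k, 0.1, 1); y <- runif(1, 0, 3)
      w <- S^y / sum(S^y)
      expect_equal(gknn_estimate(A, S, x = 0, y = y), prod(A^w),
                   tolerance = 1e-12)
      # zero activity with positive weight collapses the limit to 0
      expect_equal(gknn_estimate(c(A, 0), c(S, 0.5), x = 0, y = y), 0)
    }
  })
})

test_that("log-domain evaluation matches the naive transcription", {
  withr::with_seed(202, {
    for (r in 1:100) {
      k <- sample(2:15, 1)
      A <- runif(k); S <- runif(k, 0.01, 1)
      x <- runif(1, 0.1, 10); y <- runif(1, 0, 10)
      expect_equal(gknn_estimate(A, S, x, y), naive_gknn(A, S, x, y),
                   tolerance = 1e-10)
      expect_equal(knn_exponential(A, S, x),
                   naive_exponential(A, S, x), tolerance = 1e-10)
    }
  })
})

test_that("estimates stay within the neighbor activity range", {
  withr::with_seed(303, {
    for (r in 1:60) {
      k <- sample(2:10, 1)
      A <- runif(k); S <- runif(k, 0, 1)
      x <- sample(c(0, 0.1, 1, 5, 50), 1); y <- sample(c(0, 1, 10, 50), 1)
      est <- suppressWarnings(gknn_estimate(A, S, x, y))
      expect_gte(est, min(A)); expect_lte(est, max(A))
      expect_gte(knn_geometric(A), min(A) - 1e-15)
      expect_lte(knn_geometric(A), max(A) + 1e-15)
      este <- suppressWarnings(knn_exponential(A, S, x))
      expect_gte(este, min(A) - 1e-12); expect_lte(este, max(A) + 1e-12)
    }
  })
})

test_that("large exponents drive the estimate to the limits", {
  withr::with_seed(404, {
    for (r in 1:20) {
      A <- runif(5); S <- runif(5, 0.05, 0.95)
      # x -> inf: toward the max activity
      expect_lt(abs(gknn_estimate(A, S, x = 50, y = 1) - max(A)), 0.05)
      # y -> inf with a unique most similar neighbor: toward its activity
      S[2] <- 0.99
      expect_lt(abs(gknn_estimate(A, S, x = 1, y = 50) - A[2]), 0.05)
    }
  })
})

test_that("estimates are invariant to neighbor ordering", {
  withr::with_seed(505, {
    A <- runif(6); S <- runif(6, 0.1, 1)
    perm <- sample(6)
    expect_equal(gknn_estimate(A, S, 2.5, 3),
                 gknn_estimate(A[perm], S[perm], 2.5, 3),
                 tolerance = 1e-12)
    expect_equal(knn_exponential(A, S, 1.5),
                 knn_exponential(A[perm], S[perm], 1.5),
                 tolerance = 1e-12)
  })
})

test_that("degenerate all-zero similarities fall back with a warning", {
  expect_warning(out <- gknn_estimate(c(0.2, 0.6), c(0, 0), x = 1, y = 2),
                 "unweighted")
  expect_equal(out, 0.4)
})

test_that("predict matches a literal transcription of the estimator", {
  gen <- abstract_set(10, seed = 77, landscape = "random")
  S <- unclass(gen$similarity)
  act <- gen$data$activity
  fit <- gknn(gen$data, family = "gknn", k = 3, x = 2, y = 1.5,
              similarity = gen$similarity)
  for (i in c(1, 4, 10)) {
    ord <- order(-S[i, -i])
    idx <- setdiff(seq_len(10), i)[ord][1:3]
    expected <- (sum(act[idx]^2 * S[i, idx]^1.5) /
                   sum(S[i, idx]^1.5))^(1 / 2)
    expect_equal(unname(fitted(fit)[i]), expected, tolerance = 1e-10)
  }
})

test_that("query chemicals sharing a training id never use themselves", {
  gen <- abstract_set(8, seed = 12)
  fit <- gknn(gen$data, family = "gknn", k = 1, x = 1, y = 1,
              similarity = gen$similarity)
  # a query identical to a training chemical, at k = 1, under a fresh id,
  # recovers that chemical's activity with confidence 1
  q <- gen$data[3, , drop = FALSE]
  q$chem_id <- "query1"
  sq <- unclass(gen$similarity)[3, , drop = FALSE]
  rownames(sq) <- "query1"
  p <- predict(fit, newdata = q, similarity = sq)
  expect_equal(p$estimate, gen$data$activity[3])
  expect_equal(p$confidence, 1.0)
  # under the original id, the chemical itself is excluded
  p2 <- predict(fit, newdata = gen$data[3, , drop = FALSE],
                similarity = sq)
  expect_false(p2$neighbor_ids == gen$data$chem_id[3])
  expect_lt(p2$confidence, 1.0)
})

test_that("constant training activities give constant estimates", {
  gen <- abstract_set(9, seed = 13)
  gen$data$activity <- rep(0.35, 9)
  for (fam in c("gknn", "knn_arithmetic", "knn_geometric",
                "knn_exponential")) {
    fit <- gknn(gen$data, family = fam, k = 3, x = 2, y = 1,
                similarity = gen$similarity)
    expect_equal(unname(fitted(fit)), rep(0.35, 9), tolerance = 1e-12)
  }
})

test_that("prediction confidence is the maximum training similarity", {
  gen <- abstract_set(10, seed = 14)
  fit <- gknn(gen$data, k = 3, similarity = gen$similarity)
  S <- unclass(gen$similarity)
  expect_equal(fit$loo_confidence,
               vapply(1:10, function(i) max(S[i, -i]), numeric(1)))
})

test_that("fitting is deterministic and methods are coherent", {
  gen <- abstract_set(12, seed = 15)
  f1 <- gknn(gen$data, k = 4, x = 3, y = 2, similarity = gen$similarity)
  f2 <- gknn(gen$data, k = 4, x = 3, y = 2, similarity = gen$similarity)
  expect_identical(fitted(f1), fitted(f2))
  expect_equal(coef(f1), c(k = 4, x = 3, y = 2))
  expect_equal(unname(residuals(f1)),
               gen$data$activity - unname(fitted(f1)))
  expect_s3_class(summary(f1)$metrics, "metrics_report")
  expect_error(gknn(gen$data, k = 12, similarity = gen$similarity),
               class = "gknn_value_error")
})
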