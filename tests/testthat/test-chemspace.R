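test_that("fingerprints are deterministic and respond to structure", {
  fp1 <- fingerprints(c("c1ccccc1", "CCO"), fp_config("morgan"))
  fp2 <- fingerprints(c("c1ccccc1", "CCO"), fp_config("morgan"))
  expect_identical(unclass(fp1), unclass(fp2))
  expect_false(identical(fp1[1, ], fp1[2, ]))

  # single heavy atom still sets at least one bit
  fpm <- fingerprints("C", fp_config("morgan", radius = 2))
  expect_gte(sum(fpm), 1)

  expect_error(fingerprints(c("CC", "xx$$yy"), ids = c("ok", "bad")),
               "bad", class = "gknn_parse_error")
  expect_error(fp_config("morgan", n_bits = 32), class = "gknn_value_error")
})

test_that("all three fingerprint backends produce usable bit matrices", {
  smi <- c("c1ccccc1", "Cc1ccccc1", "CCO")
  for (kind in c("morgan", "path", "maccs")) {
    fp <- fingerprints(smi, fp_config(kind))
    expect_equal(nrow(fp), 3)
    expect_true(all(rowSums(fp) >= 1))
    s <- similarity_matrix(fp)
    expect_true(all(diag(s) == 1))
  }
})

test_that("folding length has little effect on Tanimoto similarities", {
  smi <- c("c1ccccc1", "Cc1ccccc1", "CCCCO")
  s1k <- similarity_matrix(fingerprints(smi, fp_config("morgan", 1024)))
  s16k <- similarity_matrix(fingerprints(smi, fp_config("morgan", 16384)))
  expect_lt(max(abs(unclass(s1k) - unclass(s16k))), 0.05)
})

test_that("tanimoto matches set arithmetic and its edge conventions", {
  mk <- function(bits, n = 8) { v <- rep(FALSE, n); v[bits] <- TRUE; v }
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mk(1:3), mk(1:3)), 1.0)
  expect_equal(tanimoto(mk(1:2), mk(5:6)), 0.0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1.0)
  expect_equal(tanimoto(mk(integer(0)), mk(1)), 0.0)
  expect_error(tanimoto(mk(1, n = 8), mk(1, n = 16)),
               class = "gknn_incompatible_error")
})

test_that("tanimoto is symmetric with unit self-similarity on random sweeps", {
  withr::with_seed(42, {
    for (r in 1:50) {
      p <- random_fp_pair()
      expect_identical(tanimoto(p$a, p$b), tanimoto(p$b, p$a))
      if (any(p$a)) expect_equal(tanimoto(p$a, p$a), 1.0)
    }
  })
})

test_that("similarity_matrix equals the brute-force double loop exactly", {
  gen <- generate_chemicals(synthetic_spec(6, mode = "real_smiles",
                                           landscape = "smooth",
                                           n_actives = 2, seed = 9))
  fps <- fingerprints(gen$data$smiles, fp_config(), ids = gen$data$chem_id)
  sm <- similarity_matrix(fps)
  expect_identical(unname(unclass(sm)), brute_similarity(fps, fps))
  expect_equal(unclass(sm), t(unclass(sm)))
  expect_true(all(diag(sm) == 1))

  sm23 <- similarity_matrix(fps[1:2, , drop = FALSE],
                            fps[3:5, , drop = FALSE])
  expect_equal(dim(sm23), c(2, 3))
  expect_identical(unname(unclass(sm23)),
                   brute_similarity(fps[1:2, , drop = FALSE],
                                    fps[3:5, , drop = FALSE]))
})

test_that("similarity CSV round-trips with identifiers", {
  gen <- abstract_set(8, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_similarity(gen$similarity, path)
  back <- read_similarity(path)
  expect_equal(unclass(back), unclass(gen$similarity), tolerance = 1e-12)
  expect_identical(rownames(back), rownames(gen$similarity))
})

test_that("similarity_distribution normalizes over the right pair set", {
  m <- matrix(0.5, 3, 3); diag(m) <- 1
  dimnames(m) <- list(letters[1:3], letters[1:3])
  h <- similarity_distribution(m, bins = 10)
  expect_equal(sum(h$frac), 1, tolerance = 1e-12)
  expect_equal(max(h$frac), 1)  # all 3 off-diagonal pairs in one bin
  expect_equal(sum(h$frac > 0), 1)

  hx <- similarity_distribution(matrix(runif(6), 2, 3), bins = 5,
                                self = FALSE)
  expect_equal(sum(hx$frac), 1, tolerance = 1e-12)
  expect_error(similarity_distribution(matrix(1, 1, 1), bins = 5,
                                       self = TRUE),
               class = "gknn_value_error")
})

test_that("eigenprojection matches closed forms and is permutation-stable", {
  # identity-like similarity: after double centering the eigenvalues are
  # 1 (n-1 times) and 0
  n <- 6
  I <- diag(n); dimnames(I) <- list(letters[1:n], letters[1:n])
  p <- eigenprojection(I, m = 3)
  expect_equal(p$eigenvalues, c(rep(1, n - 1), 0), tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))

  gen <- abstract_set(10, seed = 21)
  S <- unclass(gen$similarity)
  pr <- eigenprojection(gen$similarity, m = 10)
  # reconstruction from the full eigensystem reproduces the centered matrix
  rowmu <- rowMeans(S); mu <- mean(S)
  Sc <- S - outer(rowmu, rep(1, 10)) - outer(rep(1, 10), rowmu) + mu
  e <- eigen(Sc, symmetric = TRUE)
  expect_lt(max(abs(e$vectors %*% diag(e$values) %*% t(e$vectors) - Sc)),
            1e-8)

  # duplicate similarity rows get identical coordinates
  S2 <- S; S2[2, ] <- S2[1, ]; S2[, 2] <- S2[, 1]; S2[2, 2] <- 1
  S2[1, 2] <- S2[2, 1] <- 1
  p2 <- eigenprojection(structure(S2, dimnames = dimnames(S)), m = 3)
  expect_equal(p2$coordinates[1, ], p2$coordinates[2, ], tolerance = 1e-8)

  # row permutation permutes coordinates (up to sign of the eigenvectors)
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  pp <- eigenprojection(structure(S[perm, perm],
                                  dimnames = list(rownames(S)[perm],
                                                  rownames(S)[perm])), m = 3)
  p3 <- eigenprojection(gen$similarity, m = 3)
  expect_equal(abs(unname(pp$coordinates)),
               abs(unname(p3$coordinates[perm, ])), tolerance = 1e-8)

  # out-of-sample projection of the training rows reproduces the fit
  expect_equal(predict(p3, S), p3$coordinates, tolerance = 1e-8)
  expect_error(eigenprojection(gen$similarity, m = 11),
               class = "gknn_value_error")
})

test_that("neighbor_list sorts, truncates and breaks ties by dataset order", {
  sm <- matrix(c(1, 0.9, 0.5, 0.7,
                 0.9, 1, 0.8, 0.8,
                 0.5, 0.8, 1, 0.2,
                 0.7, 0.8, 0.2, 1), 4, 4, byrow = TRUE)
  dimnames(sm) <- list(letters[1:4], letters[1:4])
  nl <- neighbor_list(sm, "a", k = 2)
  expect_equal(nl$chem_id, c("b", "d"))
  expect_equal(nl$similarity, c(0.9, 0.7))

  # tie at 0.8: earlier dataset record wins
  nl2 <- neighbor_list(sm, "b", k = 3)
  expect_equal(nl2$chem_id, c("a", "c", "d"))

  expect_warning(nl3 <- neighbor_list(sm, "a", k = 5), "only 3")
  expect_equal(nrow(nl3), 3)
  expect_error(neighbor_list(sm, "zz", k = 1), class = "gknn_value_error")
})

test_that("neighbor_list is stable under permutation of non-selected records", {
  gen <- abstract_set(12, seed = 8)
  S <- unclass(gen$similarity)
  base <- neighbor_list(gen$similarity, "syn001", k = 3)
  keep <- match(base$chem_id, colnames(S))
  others <- setdiff(seq_len(12), c(1, keep))
  perm <- c(1, keep, rev(others))
  Sp <- S[perm, perm]
  expect_equal(neighbor_list(structure(Sp, class = class(gen$similarity)),
                             "syn001", k = 3)$chem_id,
               base$chem_id)
})

test_that("neighbor_overlap counts shared identifiers", {
  expect_equal(neighbor_overlap(c("A", "B", "C"), c("B", "C", "D")), 2 / 3)
  expect_equal(neighbor_overlap(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(neighbor_overlap(c("A"), c("B")), 0.0)
  expect_error(neighbor_overlap(character(0), "A"),
               class = "gknn_value_error")
})
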