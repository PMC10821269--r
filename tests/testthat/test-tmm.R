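# TMM normalization: reference choice, pairwise factors against the frozen
# reference-implementation oracle, rescaling, application.

test_that("choose_reference picks the quartile closest to the mean", {
  # 3 samples: middle upper quartile wins
  m <- cbind(s1 = c(10, 20, 30, 40, 50, 60),
             s2 = c(10, 20, 30, 40, 50, 600),
             s3 = c(10, 20, 30, 40, 50, 61))
  rownames(m) <- sprintf("g%d", 1:6)
  # f75 scaled by library size: s2's inflated library drags its quartile low
  expect_equal(choose_reference(as_long_counts(m)), "s3")
  # identical columns tie -> first sample
  m2 <- cbind(s1 = c(5, 5, 5), s2 = c(5, 5, 5))
  rownames(m2) <- sprintf("g%d", 1:3)
  expect_equal(choose_reference(as_long_counts(m2)), "s1")
  # single sample -> itself; all-zero matrix -> error
  m3 <- cbind(only = c(1, 2, 3)); rownames(m3) <- sprintf("g%d", 1:3)
  expect_equal(choose_reference(as_long_counts(m3)), "only")
  m0 <- cbind(s1 = c(0, 0), s2 = c(0, 0)); rownames(m0) <- c("a", "b")
  expect_error(choose_reference(as_long_counts(m0)), "all-zero")
})

test_that("factors are 1 for identical and globally scaled columns", {
  set.seed(21)
  base <- rnbinom(50, mu = 300, size = 8) + 1
  m <- cbind(s1 = base, s2 = base, s3 = 3 * base)
  rownames(m) <- sprintf("g%02d", 1:50)
  counts <- as_long_counts(m)
  expect_equal(tmm_factor(counts, "s2", "s1"), 1)
  expect_equal(tmm_factor(counts, "s3", "s1"), 1)
  fit <- tmm_normalize(counts)
  expect_equal(fit$factors$factor, rep(1, 3))
})

test_that("factors match the frozen reference-implementation oracle", {
  fixtures <- tmm_fixture_matrices()
  for (nm in names(fixtures)) {
    counts <- as_long_counts(fixtures[[nm]])
    fit <- suppressWarnings(tmm_normalize(counts))
    expect_equal(fit$factors$factor, tmm_reference_factors[[nm]],
                 tolerance = 1e-6, info = nm)
  }
})

test_that("no-composition-bias matrices give unit factors within 1e-12", {
  set.seed(22)
  profile <- rlnorm(80, 4, 1)
  scales <- c(1, 0.3, 2.5, 7)
  m <- sapply(scales, function(s) profile * s)
  dimnames(m) <- list(sprintf("g%02d", 1:80), sprintf("s%d", 1:4))
  fit <- tmm_normalize(as_long_counts(m))
  expect_equal(fit$factors$factor, rep(1, 4), tolerance = 1e-12)
})

test_that("factors are invariant to scaling one column", {
  fixtures <- tmm_fixture_matrices()
  m <- fixtures$nb
  counts <- as_long_counts(m)
  m5 <- m; m5[, 3] <- m5[, 3] * 5
  counts5 <- as_long_counts(m5)
  # unweighted trimmed mean: M values and trim ranks are untouched by a
  # global column scale, so invariance is exact
  f1 <- tmm_normalize(counts, weighted = FALSE)$factors$factor
  f2 <- tmm_normalize(counts5, weighted = FALSE)$factors$factor
  expect_equal(f2, f1, tolerance = 1e-12)
  # precision weights depend on absolute counts, so the weighted factor
  # moves only slightly
  w1 <- tmm_normalize(counts)$factors$factor
  w2 <- tmm_normalize(counts5)$factors$factor
  expect_equal(w2, w1, tolerance = 0.02)
})

test_that("permuting sample order permutes factors identically", {
  m <- tmm_fixture_matrices()$nb
  counts <- as_long_counts(m)
  fit <- tmm_normalize(counts)
  perm <- c(4, 1, 6, 2, 5, 3)
  counts_p <- as_long_counts(m[, perm])
  # keep the same reference: factor against an explicit reference column
  ref <- fit$reference
  for (s in colnames(m)) {
    expect_equal(tmm_factor(counts_p, s, ref), tmm_factor(counts, s, ref))
  }
})

test_that("too few co-expressed genes falls back to factor 1 with warning", {
  m <- cbind(s1 = c(100, 200, 0, 0, 50), s2 = c(90, 0, 210, 0, 60))
  rownames(m) <- sprintf("g%d", 1:5)
  expect_warning(f <- tmm_factor(as_long_counts(m), "s2", "s1"),
                 "co-positive")
  expect_equal(f, 1)
})

test_that("rescale_factors enforces unit geometric mean", {
  expect_equal(rescale_factors(c(2, 0.5)), c(2, 0.5))
  expect_equal(rescale_factors(c(4, 4, 4)), c(1, 1, 1))
  expect_equal(rescale_factors(7), 1)
  expect_equal(prod(rescale_factors(c(0.2, 3, 1.7, 0.9))), 1)
  expect_error(rescale_factors(c(1, -2)), "> 0")
})

test_that("apply_normalization cancels library scale and keeps zeros", {
  m <- cbind(s1 = c(10, 20, 0), s2 = c(20, 40, 0))
  rownames(m) <- c("g1", "g2", "g3")
  counts <- as_long_counts(m)
  f <- c(s1 = 1, s2 = 1)
  norm <- apply_normalization(counts, f)
  nm <- capcnv:::long_to_matrix(norm, "normalized")
  # doubling one sample's counts leaves its normalized column unchanged
  expect_equal(nm[, "s1"], nm[, "s2"])
  expect_equal(nm["g3", ], c(s1 = 0, s2 = 0))
  # zero library size -> missing column with warning
  m0 <- cbind(s1 = c(1, 2), s2 = c(0, 0)); rownames(m0) <- c("a", "b")
  expect_warning(n0 <- apply_normalization(as_long_counts(m0),
                                           c(s1 = 1, s2 = 1)), "zero library")
  n0m <- capcnv:::long_to_matrix(n0, "normalized")
  expect_true(all(is.na(n0m[, "s2"])))
})

test_that("tidy and glance expose the factor table and fit summary", {
  fit <- tmm_normalize(as_long_counts(tmm_fixture_matrices()$nb))
  td <- tidy(fit)
  expect_tibble(td)
  expect_equal(names(td), c("sample_id", "library_size", "factor",
                            "is_reference"))
  expect_equal(sum(td$is_reference), 1)
  gl <- glance(fit)
  expect_equal(gl$trim_m, 0.3)
  expect_equal(gl$reference, fit$reference)
})
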