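# Copy-number quantification: geometric-mean scaling, family totals,
# bootstrap-ratio estimator, estimator cross-validation.

mk_normalized <- function(m) as_long_counts(m, value = "normalized")

test_that("copy number is normalized value over the standards' geometric mean", {
  m <- rbind(hc1 = c(s1 = 4, s2 = 2), hc2 = c(4, 8), hc3 = c(4, 2),
             tgt = c(4, 40))
  # s1: geomean(4,4,4) = 4 -> tgt cn 1; s2: geomean(2,8,2) with hc3 dropped
  m2 <- m[c("hc1", "hc2", "tgt"), ]
  cn <- copy_number(mk_normalized(m2), c("hc1", "hc2"))
  cnm <- capcnv:::long_to_matrix(cn, "cn")
  expect_equal(cnm["tgt", "s1"], 1)
  expect_equal(cnm["tgt", "s2"], 10)  # geomean(2, 8) = 4; 40 / 4
})

test_that("standards' copy numbers have geometric mean exactly 1 per sample", {
  set.seed(41)
  m <- matrix(rlnorm(20 * 6, 1, 0.8), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  hc <- sprintf("g%02d", 1:12)
  cn <- copy_number(mk_normalized(m), hc)
  per_sample <- cn |>
    dplyr::filter(gene_id %in% hc) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(g = exp(mean(log(cn))))
  expect_equal(per_sample$g, rep(1, 6), tolerance = 1e-12)
  # invariance to rescaling one sample's normalized column
  m2 <- m; m2[, 2] <- m2[, 2] * 9.1
  cn2 <- copy_number(mk_normalized(m2), hc)
  expect_equal(cn2$cn, cn$cn)
})

test_that("zero standards are excluded; all-zero samples are flagged", {
  m <- rbind(hc1 = c(s1 = 2, s2 = 0), hc2 = c(8, 0), tgt = c(40, 5))
  expect_warning(
    expect_warning(cn <- copy_number(mk_normalized(m), c("hc1", "hc2")),
                   "zero internal-standard"),
    "no usable internal standard")
  cnm <- capcnv:::long_to_matrix(cn, "cn")
  expect_equal(cnm["tgt", "s1"], 10)
  expect_true(is.na(cnm["tgt", "s2"]))
  expect_error(copy_number(mk_normalized(m), character(0)), "non-empty")
  expect_error(copy_number(mk_normalized(m), c("hc1", "nope")), "absent")
})

test_that("family totals sum gene models, with a complete-only restriction", {
  cn <- tibble::tibble(
    sample_id = "s1", gene_id = c("m1", "m2", "m3", "u1"),
    cn = c(100, 50, 10, 1))
  fam <- tibble::tibble(gene_id = c("m1", "m2", "m3", "u1"),
                        family = c("bglu1", "bglu1", "bglu1", "ugt5b"),
                        model_status = c("complete", "near_complete",
                                         "fragmented", "complete"))
  totals <- total_family_cn(cn, fam)
  expect_equal(totals$total_cn[totals$family == "bglu1"], 160)
  expect_equal(totals$total_cn[totals$family == "ugt5b"], 1)
  complete <- total_family_cn(cn, fam, complete_only = TRUE)
  expect_equal(complete$total_cn[complete$family == "bglu1"], 150)
  fam_dup <- dplyr::bind_rows(fam, fam[1, ])
  expect_error(total_family_cn(cn, fam_dup), "more than one family")
})

test_that("fold_range reproduces the extreme-totals arithmetic", {
  expect_equal(round(fold_range(c(56, 381)), 1), 6.8)
  expect_equal(fold_range(c(5, 5, 5)), 1)
  expect_error(fold_range(c(-1, 2)), "positive")
})

test_that("bootstrap ratio is exactly 1 for a target behaving like the refs", {
  m <- matrix(rep(c(2, 6, 3, 5), each = 4), nrow = 4,
              dimnames = list(c("r1", "r2", "r3", "tgt"),
                              sprintf("s%d", 1:4)))
  boot <- bootstrap_ratio_cn(mk_normalized(m), c("r1", "r2", "r3"), "tgt",
                             baseline_samples = "s1", n_boot = 200, seed = 9)
  expect_equal(boot$mean_ratio, rep(1, 4))
  expect_equal(boot$ci_low, rep(1, 4))
  expect_equal(boot$ci_high, rep(1, 4))
})

test_that("bootstrap is bit-identical under the same seed and needs one", {
  set.seed(43)
  m <- matrix(rlnorm(10 * 5, 2, 0.3), 10, 5,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:5)))
  norm <- mk_normalized(m)
  refs <- sprintf("g%02d", 1:8)
  b1 <- bootstrap_ratio_cn(norm, refs, "g10", "s1", n_boot = 500, seed = 77)
  b2 <- bootstrap_ratio_cn(norm, refs, "g10", "s1", n_boot = 500, seed = 77)
  expect_identical(b1, b2)
  b3 <- bootstrap_ratio_cn(norm, refs, "g10", "s1", n_boot = 500, seed = 78)
  expect_false(identical(b1$mean_ratio, b3$mean_ratio))
  expect_error(bootstrap_ratio_cn(norm, refs, "g10", "s1", n_boot = 10),
               "seed")
  expect_error(bootstrap_ratio_cn(norm, "g01", "g10", "s1", seed = 1),
               ">= 2 reference")
  expect_true(all(b1$ci_low <= b1$mean_ratio & b1$mean_ratio <= b1$ci_high))
})

test_that("a 2x planted target is recovered by the bootstrap", {
  set.seed(44)
  n_ref <- 20; n_s <- 12
  baseline <- sprintf("s%02d", 1:6)
  doubled <- sprintf("s%02d", 7:12)
  mu <- matrix(500, n_ref + 1, n_s)
  mu[n_ref + 1, 7:12] <- 1000  # target at 2x outside the baseline group
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.01), n_ref + 1,
                   n_s, dimnames = list(c(sprintf("r%02d", 1:n_ref), "tgt"),
                                        sprintf("s%02d", 1:n_s)))
  boot <- bootstrap_ratio_cn(mk_normalized(counts),
                             sprintf("r%02d", 1:n_ref), "tgt",
                             baseline_samples = baseline,
                             n_boot = 10000, seed = 45)
  est_2x <- mean(boot$mean_ratio[boot$sample_id %in% doubled])
  expect_gt(est_2x, 1.9)
  expect_lt(est_2x, 2.1)
  expect_equal(mean(boot$mean_ratio[boot$sample_id %in% baseline]), 1,
               tolerance = 0.05)
})

test_that("cross_validate_estimators reports Pearson r on paired samples", {
  direct <- tibble::tibble(sample_id = c("a", "b", "c"), cn = c(1, 2, 3))
  boot <- tibble::tibble(sample_id = c("a", "b", "c"),
                         mean_ratio = c(2, 4, 6))
  expect_equal(cross_validate_estimators(direct, boot)$r, 1)
  boot$mean_ratio <- c(3, 2, 1)
  expect_equal(cross_validate_estimators(direct, boot)$r, -1)
  expect_error(cross_validate_estimators(direct[1:2, ], boot[1:2, ]),
               ">= 3")
})
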