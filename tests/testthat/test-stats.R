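# Inferential statistics, checked against independent oracles: hand-computed
# sums of squares, full enumeration of rank-sum assignments, the studentized
# range CDF and the closed-form Welch statistic.

# Exact two-sided rank-sum p by enumerating all label assignments.
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  w_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  ids <- utils::combn(length(pooled), n)
  w_all <- apply(ids, 2, function(i) {
    sum(rank(pooled)[i]) - n * (n + 1) / 2
  })
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

test_that("two-way ANOVA reproduces hand-computed sequential SS", {
  tab <- two_way_anova(anova_fixture(), "total_cn", "provenance",
                       "gene_model")
  expect_s3_class(tab, "cnv_anova")
  expect_equal(tab$term, c("provenance", "gene_model",
                           "provenance:gene_model", "Residuals"))
  expect_equal(tab$sum_sq, c(32, 2, 0, 8))
  expect_equal(tab$df, c(1, 1, 1, 4))
  expect_equal(tab$statistic[1:3], c(16, 1, 0))
  # df conservation: term dfs + residual df = n - 1
  expect_equal(sum(tab$df), nrow(anova_fixture()) - 1)
})

test_that("balanced designs are order-invariant, unbalanced ones are not", {
  bal <- anova_fixture()
  t_ab <- two_way_anova(bal, "total_cn", "provenance", "gene_model")
  t_ba <- two_way_anova(bal, "total_cn", "gene_model", "provenance")
  expect_equal(sort(t_ab$sum_sq), sort(t_ba$sum_sq))
  # unbalance the design: drop one observation
  unbal <- bal[-1, ]
  u_ab <- two_way_anova(unbal, "total_cn", "provenance", "gene_model")
  u_ba <- two_way_anova(unbal, "total_cn", "gene_model", "provenance")
  ss_a_first <- u_ab$sum_sq[u_ab$term == "provenance"]
  ss_a_second <- u_ba$sum_sq[u_ba$term == "provenance"]
  expect_false(isTRUE(all.equal(ss_a_first, ss_a_second)))
})

test_that("ANOVA degenerate inputs are handled explicitly", {
  const <- dplyr::mutate(anova_fixture(), total_cn = 5)
  expect_warning(tab <- two_way_anova(const, "total_cn", "provenance",
                                      "gene_model"), "constant response")
  expect_true(all(is.na(tab$p_value[tab$term != "Residuals"])))
  # zero residual SS but real effects -> Inf sentinel
  perfect <- dplyr::mutate(anova_fixture(),
                           total_cn = as.numeric(factor(provenance)))
  expect_warning(tabp <- two_way_anova(perfect, "total_cn", "provenance",
                                       "gene_model"), "Inf")
  expect_equal(tabp$statistic[tabp$term == "provenance"], Inf)
  expect_equal(tabp$p_value[tabp$term == "provenance"], 0)
  one_level <- dplyr::mutate(anova_fixture(), provenance = "only")
  expect_error(two_way_anova(one_level, "total_cn", "provenance",
                             "gene_model"), "fewer than 2")
})

test_that("ANOVA is invariant to permuting observation order", {
  set.seed(51)
  d <- anova_fixture()
  tab <- two_way_anova(d, "total_cn", "provenance", "gene_model")
  perm <- two_way_anova(d[sample(nrow(d)), ], "total_cn", "provenance",
                        "gene_model")
  expect_equal(perm$sum_sq, tab$sum_sq)
  expect_equal(perm$p_value, tab$p_value)
})

test_that("exact Wilcoxon p matches full enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 0.1)
  expect_equal(w$p_value, enumerate_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  # a less extreme arrangement, still against the enumeration oracle
  x <- c(1.2, 5.1, 2.8, 7.4); y <- c(3.3, 6.0, 8.8, 9.1, 4.4)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, enumerate_wilcoxon_p(x, y))
  # identical groups have ties -> approximate branch, p = 1
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "normal_approx")
  expect_equal(same$p_value, 1)
})

test_that("exact and approximate Wilcoxon p agree at n = m = 10", {
  set.seed(52)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    p_exact <- wilcoxon_rank_sum(x, y)$p_value
    p_approx <- wilcoxon_rank_sum(x, y, exact_when_small = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Tukey HSD matches a studentized-range oracle and the k = 2 t test", {
  set.seed(53)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), times = c(5, 7, 6)),
    y = rnorm(18, mean = rep(c(0, 1, 0.3), times = c(5, 7, 6))))
  hsd <- tukey_hsd(d, "y", "g")
  # oracle: adjusted p from the q distribution with Tukey-Kramer SE
  fit <- aov(y ~ g, data = d)
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfe <- summary(fit)[[1]]$Df[2]
  means <- tapply(d$y, d$g, mean)
  ns <- tapply(d$y, d$g, length)
  pairs <- utils::combn(names(means), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- abs(means[[b]] - means[[a]]) / se
    p_oracle <- stats::ptukey(q, nmeans = 3, df = dfe, lower.tail = FALSE)
    row <- hsd[hsd$contrast == paste(b, a, sep = "-"), ]
    expect_equal(row$p_adj, p_oracle, tolerance = 1e-8)
  }
  # two groups: Tukey collapses to the pooled two-sample t test
  d2 <- dplyr::filter(d, g != "c")
  hsd2 <- tukey_hsd(d2, "y", "g")
  p_t <- t.test(y ~ g, data = d2, var.equal = TRUE)$p.value
  expect_equal(hsd2$p_adj, p_t, tolerance = 1e-6)
  # identical group means -> adjusted p 1
  flat <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(1:3, 2))
  expect_equal(tukey_hsd(flat, "y", "g")$p_adj, 1, tolerance = 1e-8)
  single <- tibble::tibble(g = c("a", "a", "b"), y = 1:3)
  expect_error(tukey_hsd(single, "y", "g"), "singleton")
})

test_that("Welch t matches the closed formulas and its conventions", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1)
  w <- welch_t_test(x, y)
  # closed-form Welch statistic and Satterthwaite df
  se2 <- var(x) / length(x) + var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                        (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(w$statistic, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p_value, 2 * stats::pt(-abs(t_hand), df_hand))
  # antisymmetry and degenerate conventions
  w_rev <- welch_t_test(y, x)
  expect_equal(w_rev$statistic, -w$statistic)
  expect_equal(w_rev$p_value, w$p_value)
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p_value, 1)
})

test_that("Pearson correlation handles collinear and independent data", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(pearson_cor(1:5, -3 * (1:5))$r, -1)
  set.seed(54)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(pearson_cor(x, y)$r), 0.1)
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("Type II sums of squares agree with Type I on balanced designs", {
  bal <- anova_fixture()
  t1 <- two_way_anova(bal, "total_cn", "provenance", "gene_model")
  t2 <- two_way_anova(bal, "total_cn", "provenance", "gene_model",
                      ss_type = "II")
  for (term in c("provenance", "gene_model")) {
    expect_equal(t2$sum_sq[t2$term == term], t1$sum_sq[t1$term == term])
  }
  # on an unbalanced design Type II is order-invariant where Type I is not
  unbal <- bal[-1, ]
  u_ab <- two_way_anova(unbal, "total_cn", "provenance", "gene_model",
                        ss_type = "II")
  u_ba <- two_way_anova(unbal, "total_cn", "gene_model", "provenance",
                        ss_type = "II")
  expect_equal(u_ab$sum_sq[u_ab$term == "provenance"],
               u_ba$sum_sq[u_ba$term == "provenance"])
})
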