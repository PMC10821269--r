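# Downstream inferential statistics applied to copy-number tables. These are
# thin tidy wrappers over the standard R implementations (aov, wilcox.test,
# TukeyHSD, t.test, cor.test); all p-values are reported raw — no multiple
# testing correction is added beyond Tukey's own adjustment.

#' Two-way ANOVA of copy number on provenance and gene model
#'
#' Sequential (Type I) sums of squares in the order factor_a, factor_b,
#' interaction — the convention the totals tables of a provenance x
#' gene-model design use. A Type II option (via car) is provided for
#' unbalanced provenance panels, where sequential SS depend on term order.
#' A zero residual mean square yields F = Inf with p = 0 and a warning; a
#' constant response yields missing F and p.
#'
#' @param data data frame of observations.
#' @param response,factor_a,factor_b column names (strings) of the response
#'   and the two factors (e.g. "total_cn", "provenance", "gene_id"). Each
#'   factor needs >= 2 observed levels.
#' @param ss_type "I" (sequential, default) or "II".
#' @return tibble of class `cnv_anova` with `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic`, `p_value`; the last row is `Residuals`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          ss_type = c("I", "II")) {
  ss_type <- match.arg(ss_type)
  stopifnot_cols(data, c(response, factor_a, factor_b), "data")
  d <- tibble(
    y = data[[response]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]]))
  for (f in c("a", "b")) {
    if (nlevels(droplevels(d[[f]])) < 2) {
      abort(sprintf("factor '%s' has fewer than 2 levels",
                    if (f == "a") factor_a else factor_b))
    }
  }
  tab <- if (ss_type == "I") {
    fit <- aov(y ~ a + b + a:b, data = d)
    s <- summary(fit)[[1]]
    tibble(term = trimws(rownames(s)), df = s$Df, sum_sq = s$`Sum Sq`,
           mean_sq = s$`Mean Sq`, statistic = s$`F value`,
           p_value = s$`Pr(>F)`)
  } else {
    if (!requireNamespace("car", quietly = TRUE)) {
      abort("ss_type = 'II' requires the car package")
    }
    fit <- lm(y ~ a + b + a:b, data = d)
    s <- as.data.frame(car::Anova(fit, type = 2))
    tibble(term = rownames(s), df = s$Df, sum_sq = s$`Sum Sq`,
           mean_sq = s$`Sum Sq` / s$Df, statistic = s$`F value`,
           p_value = s$`Pr(>F)`)
  }
  tab$term <- sub("^a:b$", paste0(factor_a, ":", factor_b), tab$term)
  tab$term <- sub("^a$", factor_a, tab$term)
  tab$term <- sub("^b$", factor_b, tab$term)
  # degenerate designs: compare sums of squares on the scale of the data,
  # not against exact zero (aov leaves ~1e-30 rounding residue)
  total_ss <- sum((d$y - mean(d$y))^2)
  resid_ss <- tab$sum_sq[tab$term == "Residuals"]
  terms <- tab$term != "Residuals"
  if (sd(d$y) == 0) {
    tab$sum_sq <- 0
    tab$mean_sq <- 0
    tab$statistic[terms] <- NA_real_
    tab$p_value[terms] <- NA_real_
    warn("constant response: F undefined, reported as missing")
  } else if (length(resid_ss) == 1 && resid_ss <= 1e-10 * total_ss) {
    big <- tab$sum_sq[terms] > 1e-10 * total_ss
    tab$statistic[terms] <- ifelse(big, Inf, 0)
    tab$p_value[terms] <- ifelse(big, 0, 1)
    warn("zero residual mean square: F reported as Inf with p = 0")
  }
  class(tab) <- c("cnv_anova", class(tab))
  tab
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when `min(n, m) <= 10` and there are no ties
#' (the regime where exactness is affordable and well-defined); otherwise
#' the continuity-corrected normal approximation with tie correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_when_small allow the exact branch (default TRUE).
#' @return one-row tibble with `statistic` (W), `p_value` (two-sided),
#'   `method` ("exact" or "normal_approx").
#' @export
wilcoxon_rank_sum <- function(x, y, exact_when_small = TRUE) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- exact_when_small && min(length(x), length(y)) <= 10 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (use_exact) "exact" else "normal_approx")
}

#' Tukey HSD pairwise comparisons
#'
#' Pairwise group mean differences with studentized-range adjusted p-values
#' and simultaneous confidence intervals honouring unequal group sizes.
#'
#' @param data data frame of observations.
#' @param response,group column names (strings); >= 2 groups, each with
#'   >= 2 observations.
#' @param conf_level simultaneous confidence level (default 0.95).
#' @return tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data, response, group, conf_level = 0.95) {
  stopifnot_cols(data, c(response, group), "data")
  d <- tibble(y = data[[response]], g = factor(data[[group]]))
  sizes <- table(droplevels(d$g))
  if (length(sizes) < 2) abort("need >= 2 groups")
  if (any(sizes < 2)) {
    abort(sprintf("singleton group(s): %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  hsd <- TukeyHSD(aov(y ~ g, data = d), conf.level = conf_level)$g
  tibble(contrast = rownames(hsd), estimate = unname(hsd[, "diff"]),
         conf_low = unname(hsd[, "lwr"]), conf_high = unname(hsd[, "upr"]),
         p_adj = unname(hsd[, "p adj"]))
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided. Both
#' groups constant with equal means is reported as t = 0, p = 1 (there is
#' no evidence of a difference, but the usual statistic is 0/0).
#'
#' @param x,y numeric vectors, each n >= 2.
#' @return one-row tibble with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1))
    }
    warn("both groups constant with different means: p = 0")
    return(tibble(statistic = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                  p_value = 0))
  }
  tt <- t.test(x, y)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, non-constant.
#' @return one-row tibble with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
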