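# From-scratch trimmed-mean-of-M-values (TMM) between-sample normalization.
# For sample k against reference r, over genes positive in both columns:
#   M_g = log2[(y_gk/N_k) / (y_gr/N_r)]     (log-ratio)
#   A_g = 1/2 log2[(y_gk/N_k) (y_gr/N_r)]   (log-abundance)
# Genes in the extreme trim_m quantiles of M and trim_a quantiles of A are
# dropped (double trimming); the scaling factor is 2^(weighted mean of the
# surviving M_g) with inverse delta-method variances as precision weights:
#   w_g^-1 = (N_k - y_gk)/(N_k y_gk) + (N_r - y_gr)/(N_r y_gr)
# Factors are rescaled to geometric mean 1 across samples.

#' Choose the TMM reference sample
#'
#' The reference is the sample whose upper quartile of scaled counts
#' (counts / library size, over genes with any positive count) is closest to
#' the mean upper quartile across samples; ties break to the first sample in
#' input order. When all upper quartiles are numerically zero the sample
#' with the largest sum of square-root counts is used instead.
#'
#' @param counts long tibble with `gene_id`, `sample_id`, `count`.
#' @return the chosen `sample_id`.
#' @export
choose_reference <- function(counts) {
  m <- long_to_matrix(counts, "count")
  if (any(m < 0)) abort("counts must be >= 0")
  lib <- colSums(m)
  if (all(m == 0)) abort("all-zero count matrix")
  m <- m[rowSums(m > 0) > 0, , drop = FALSE]
  f75 <- apply(m, 2, quantile, probs = 0.75) / lib
  if (median(f75) < 1e-20) {
    return(colnames(m)[which.max(colSums(sqrt(m)))])
  }
  colnames(m)[which.min(abs(f75 - mean(f75)))]
}

# Core pairwise factor on raw numeric vectors; mirrors the canonical TMM
# definition including rank-based double trimming.
tmm_factor_vec <- function(obs, ref, lib_obs, lib_ref, trim_m = 0.30,
                           trim_a = 0.05, weighted = TRUE, min_genes = 10) {
  log_r <- log2((obs / lib_obs) / (ref / lib_ref))
  abs_e <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0) {
    warn("no gene with positive counts in both samples; factor set to 1")
    return(1)
  }
  if (length(log_r) < min_genes) {
    warn(sprintf("only %d co-positive gene(s) (< %d); factor set to 1",
                 length(log_r), min_genes))
    return(1)
  }
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * trim_m) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1; hi_s <- n + 1 - lo_s
  keep <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
    (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
  f <- if (weighted) {
    sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(log_r[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Pairwise TMM scaling factor
#'
#' @param counts long tibble with `gene_id`, `sample_id`, `count`.
#' @param sample,reference sample ids of the column to scale and the
#'   reference column.
#' @param trim_m fraction trimmed from each tail of the M (log-ratio)
#'   distribution (default 0.30).
#' @param trim_a fraction trimmed from each tail of the A (log-abundance)
#'   distribution (default 0.05).
#' @param weighted use inverse delta-method precision weights (default TRUE);
#'   FALSE gives the unweighted trimmed mean, for diagnostics.
#' @param min_genes minimum number of genes positive in both columns needed
#'   to estimate a factor; below this the factor is 1 with a warning.
#' @return positive scaling factor (not yet rescaled across samples).
#' @export
tmm_factor <- function(counts, sample, reference, trim_m = 0.30,
                       trim_a = 0.05, weighted = TRUE, min_genes = 10) {
  m <- long_to_matrix(counts, "count")
  for (s in c(sample, reference)) {
    if (!s %in% colnames(m)) abort(sprintf("unknown sample '%s'", s))
  }
  lib <- colSums(m)
  if (lib[sample] <= 0 || lib[reference] <= 0) {
    abort("both samples must have positive library size")
  }
  tmm_factor_vec(m[, sample], m[, reference], lib[sample], lib[reference],
                 trim_m, trim_a, weighted, min_genes)
}

#' Rescale factors to geometric mean 1
#'
#' @param raw_factors positive numeric vector.
#' @return factors divided by their geometric mean (product of outputs is 1).
#' @export
rescale_factors <- function(raw_factors) {
  if (any(!is.finite(raw_factors)) || any(raw_factors <= 0)) {
    abort("all factors must be finite and > 0")
  }
  raw_factors / geom_mean(raw_factors)
}

#' Apply normalization factors to a count table
#'
#' `normalized = count / (library_size * factor)`, rescaled by the mean
#' effective library size so magnitudes stay on the input scale. Doubling a
#' sample's counts leaves its normalized column unchanged (the effective
#' library size absorbs the scale).
#'
#' @param counts long tibble with `gene_id`, `sample_id`, `count`.
#' @param factors named numeric vector (sample_id -> factor) or a tibble
#'   with `sample_id` and `factor` columns.
#' @return long tibble with `gene_id`, `sample_id`, `normalized`; samples
#'   with zero library size get all-missing values with a warning.
#' @export
apply_normalization <- function(counts, factors) {
  m <- long_to_matrix(counts, "count")
  if (is.data.frame(factors)) {
    stopifnot_cols(factors, c("sample_id", "factor"), "factors")
    factors <- setNames(factors$factor, factors$sample_id)
  }
  if (!all(colnames(m) %in% names(factors))) {
    abort("factors must cover every sample")
  }
  f <- factors[colnames(m)]
  if (any(f <= 0)) abort("factors must be positive")
  lib <- colSums(m)
  eff <- lib * f
  if (any(lib == 0)) {
    warn(sprintf("sample(s) with zero library size set to missing: %s",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  scale <- mean(eff[lib > 0])
  norm <- sweep(m, 2, ifelse(lib > 0, eff, NA_real_), "/") * scale
  matrix_to_long(norm, "normalized")
}

#' TMM-normalize a count table
#'
#' One-call wrapper: chooses the reference ([choose_reference()]), computes a
#' pairwise factor per sample ([tmm_factor()]), rescales factors to
#' geometric mean 1 and applies them.
#'
#' @inheritParams tmm_factor
#' @return object of class `tmm_fit`: list with `factors` (tibble:
#'   `sample_id`, `library_size`, `factor`, `is_reference`), `normalized`
#'   (long tibble), `reference`, `trim_m`, `trim_a`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05,
                          weighted = TRUE, min_genes = 10) {
  m <- long_to_matrix(counts, "count")
  ref <- choose_reference(counts)
  lib <- colSums(m)
  raw <- vapply(colnames(m), function(s) {
    tmm_factor_vec(m[, s], m[, ref], lib[s], lib[ref], trim_m, trim_a,
                   weighted, min_genes)
  }, numeric(1))
  f <- rescale_factors(raw)
  fit <- list(
    factors = tibble(sample_id = colnames(m), library_size = unname(lib),
                     factor = unname(f),
                     is_reference = colnames(m) == ref),
    normalized = apply_normalization(counts, f),
    reference = ref, trim_m = trim_m, trim_a = trim_a)
  class(fit) <- "tmm_fit"
  fit
}

#' @export
print.tmm_fit <- function(x, ...) {
  cat(sprintf("TMM normalization: %d samples, reference '%s' (trim M %.2f, A %.2f)\n",
              nrow(x$factors), x$reference, x$trim_m, x$trim_a))
  print(x$factors)
  invisible(x)
}
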