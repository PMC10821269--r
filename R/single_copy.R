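# Selection of high-confidence single-copy internal standards: a gene must
# sit within k standard deviations of the candidate mean in log-normalized
# coverage AND be classified single-copy in the local assembly.

BUSCO_CLASSES <- c("single_copy", "duplicated", "fragmented", "missing")

#' Per-gene log-normalized coverage summary
#'
#' Mean over samples of `log(normalized + pseudocount)` per gene. With the
#' default pseudocount of 0, zero normalized values become missing (with a
#' warning) rather than -Inf and are excluded from the per-gene mean; genes
#' with no finite value at all get a missing summary.
#'
#' @param norm normalized-coverage tibble with `sample_id`, `gene_id`,
#'   `normalized` (see [normalized_coverage()]; region-level tables are
#'   averaged into gene level by mean).
#' @param base logarithm base (default natural). The downstream window is in
#'   SD units, so the retained set is base-invariant.
#' @param pseudocount added before taking logs (default 0).
#' @return tibble with `gene_id`, `log_norm_cov`, `n_samples`, `n_missing`.
#' @export
log_normalized_coverage <- function(norm, base = exp(1), pseudocount = 0) {
  stopifnot_cols(norm, c("sample_id", "gene_id", "normalized"),
                 "normalized coverage")
  if (any(norm$normalized < 0, na.rm = TRUE)) {
    abort("normalized coverage must be >= 0")
  }
  x <- norm$normalized + pseudocount
  zero <- !is.na(x) & x == 0
  if (any(zero)) {
    warn(sprintf(
      "%d zero normalized value(s) with pseudocount 0 treated as missing",
      sum(zero)))
    x[zero] <- NA_real_
  }
  norm$log_value <- log(x, base = base)
  norm |>
    group_by(.data$gene_id) |>
    summarise(
      log_norm_cov = if (all(is.na(.data$log_value))) NA_real_
                     else mean(.data$log_value, na.rm = TRUE),
      n_samples = n(), n_missing = sum(is.na(.data$log_value)),
      .groups = "drop")
}

#' High-confidence single-copy filter
#'
#' Retains a candidate gene iff (a) its log-normalized coverage lies within
#' `k_sd` standard deviations of the mean, where mean and SD are computed
#' over the candidate genes themselves (the putative single-copy list, not
#' the whole panel), and (b) it is classified `single_copy`. The window is
#' inclusive by default ("within one SD" reads most naturally as <=). With
#' SD = 0 and more than one gene, all candidates pass the coverage window.
#'
#' @param log_cov tibble from [log_normalized_coverage()] restricted to the
#'   candidate genes (requires >= 2 genes with finite values).
#' @param statuses tibble with `gene_id`, `busco_class` (one of single_copy,
#'   duplicated, fragmented, missing).
#' @param k_sd half-width of the coverage window in SD units (default 1).
#' @param inclusive whether the window boundary is inclusive (default TRUE).
#' @return audit tibble with `gene_id`, `log_norm_cov`, `busco_class`,
#'   `in_window`, `high_confidence`, `reason` (one of "ok",
#'   "coverage_window", "busco_class", "missing_coverage"); window mean and
#'   SD are attached as attributes `"mu"` and `"sigma"`.
#' @seealso [hc_genes()] to extract the retained set.
#' @export
high_confidence_filter <- function(log_cov, statuses, k_sd = 1,
                                   inclusive = TRUE) {
  stopifnot_cols(log_cov, c("gene_id", "log_norm_cov"), "log coverage")
  stopifnot_cols(statuses, c("gene_id", "busco_class"), "statuses")
  if (!all(statuses$busco_class %in% BUSCO_CLASSES)) {
    abort(sprintf("busco_class must be one of: %s",
                  paste(BUSCO_CLASSES, collapse = ", ")))
  }
  if (k_sd < 0) abort("k_sd must be >= 0")
  x <- log_cov$log_norm_cov
  if (sum(is.finite(x)) < 2) {
    abort("need >= 2 candidate genes with finite log-normalized coverage")
  }
  mu <- mean(x[is.finite(x)])
  sigma <- sd(x[is.finite(x)])
  dev <- abs(x - mu)
  in_window <- if (sigma == 0) {
    is.finite(x)
  } else if (inclusive) {
    is.finite(x) & dev <= k_sd * sigma
  } else {
    is.finite(x) & dev < k_sd * sigma
  }
  out <- log_cov |>
    left_join(select(statuses, "gene_id", "busco_class"), by = "gene_id") |>
    mutate(
      in_window = in_window,
      high_confidence = .data$in_window &
        !is.na(.data$busco_class) & .data$busco_class == "single_copy",
      reason = dplyr::case_when(
        high_confidence ~ "ok",
        !is.finite(log_cov$log_norm_cov) ~ "missing_coverage",
        !in_window ~ "coverage_window",
        TRUE ~ "busco_class"))
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Extract the retained high-confidence gene set
#'
#' @param audit tibble from [high_confidence_filter()].
#' @return sorted character vector of retained gene ids.
#' @export
hc_genes <- function(audit) {
  stopifnot_cols(audit, c("gene_id", "high_confidence"), "audit table")
  sort(audit$gene_id[audit$high_confidence])
}

#' Intersect high-confidence panels across species
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return stable sorted character vector of shared ids.
#' @export
intersect_panels <- function(set_a, set_b) {
  sort(intersect(set_a, set_b))
}
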