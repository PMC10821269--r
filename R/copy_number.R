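# Absolute copy-number quantification: normalized values scaled by the
# geometric mean of high-confidence single-copy internal standards, family
# totals, and a gene-resampling bootstrap cross-estimator.

#' Absolute copy number against single-copy internal standards
#'
#' For each sample, the scaling constant is the geometric mean of the
#' normalized values of the high-confidence single-copy genes; every gene's
#' copy number is its normalized value divided by that constant. Zero
#' internal-standard values are capture failures and are excluded from the
#' geometric mean (count surfaced as attribute `"n_zero_excluded"`); a
#' sample whose standards are all zero gets missing copy numbers and is
#' flagged with a warning.
#'
#' By construction the geometric mean of copy number over the (nonzero)
#' standards is exactly 1 per sample, and copy numbers are invariant to
#' rescaling a sample's normalized column.
#'
#' @param normalized long tibble with `gene_id`, `sample_id`, `normalized`
#'   (e.g. `tmm_normalize(counts)$normalized`).
#' @param hc_single_copy non-empty character vector of high-confidence
#'   single-copy gene ids, all present in `normalized`.
#' @return tibble with `sample_id`, `gene_id`, `cn` (copies per haploid
#'   genome; not rounded to integers).
#' @export
copy_number <- function(normalized, hc_single_copy) {
  stopifnot_cols(normalized, c("gene_id", "sample_id", "normalized"),
                 "normalized table")
  if (length(hc_single_copy) == 0) abort("hc_single_copy must be non-empty")
  missing_hc <- setdiff(hc_single_copy, unique(normalized$gene_id))
  if (length(missing_hc) > 0) {
    abort(sprintf("high-confidence gene(s) absent from matrix: %s",
                  paste(head(missing_hc, 5), collapse = ", ")))
  }
  scale <- normalized |>
    filter(.data$gene_id %in% hc_single_copy) |>
    group_by(.data$sample_id) |>
    summarise(
      n_zero = sum(.data$normalized == 0, na.rm = TRUE),
      g = {
        v <- .data$normalized[!is.na(.data$normalized) & .data$normalized > 0]
        if (length(v) == 0) NA_real_ else geom_mean(v)
      },
      .groups = "drop")
  if (any(scale$n_zero > 0)) {
    warn(sprintf("%d zero internal-standard value(s) excluded from geometric mean",
                 sum(scale$n_zero)))
  }
  if (anyNA(scale$g)) {
    warn(sprintf("sample(s) with no usable internal standard flagged missing: %s",
                 paste(scale$sample_id[is.na(scale$g)], collapse = ", ")))
  }
  out <- normalized |>
    left_join(select(scale, "sample_id", "g"), by = "sample_id") |>
    mutate(cn = .data$normalized / .data$g) |>
    select("sample_id", "gene_id", "cn")
  attr(out, "n_zero_excluded") <- sum(scale$n_zero)
  out
}

#' Per-sample family copy-number totals
#'
#' Sums copy numbers over the gene models of each family. When `families`
#' carries a `model_status` column and `complete_only = TRUE`, only models
#' flagged "complete" or "near_complete" are summed (the family totals of
#' interest are those of functional gene forms).
#'
#' @param cn copy-number tibble from [copy_number()].
#' @param families tibble with `gene_id`, `family` (each gene in at most one
#'   family), optionally `model_status`.
#' @param complete_only restrict to complete/near-complete models (default
#'   FALSE: all models in the family).
#' @return tibble with `sample_id`, `family`, `total_cn`.
#' @export
total_family_cn <- function(cn, families, complete_only = FALSE) {
  stopifnot_cols(cn, c("sample_id", "gene_id", "cn"), "copy-number table")
  stopifnot_cols(families, c("gene_id", "family"), "family map")
  if (anyDuplicated(families$gene_id)) {
    abort("family map assigns a gene to more than one family")
  }
  fam <- families
  if (complete_only && "model_status" %in% names(fam)) {
    fam <- filter(fam, .data$model_status %in% c("complete", "near_complete"))
  }
  empty <- setdiff(unique(families$family), unique(fam$family))
  out <- cn |>
    inner_join(select(fam, "gene_id", "family"), by = "gene_id") |>
    group_by(.data$sample_id, .data$family) |>
    summarise(total_cn = sum(.data$cn), .groups = "drop")
  if (length(empty) > 0 || !all(unique(fam$family) %in% out$family)) {
    missing <- setdiff(unique(families$family), unique(out$family))
    if (length(missing) > 0) {
      warn(sprintf("family(ies) with no contributing gene model: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Fold range (max / min) of a set of totals
#'
#' @param x positive numeric vector (e.g. per-sample family totals).
#' @return `max(x) / min(x)`.
#' @export
fold_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || any(x <= 0)) {
    abort("fold_range needs positive finite values")
  }
  max(x) / min(x)
}

#' Bootstrap-ratio copy-number estimator
#'
#' A simplified panel-oriented analogue of subsampling-based CNV callers for
#' capture panels: in each of `n_boot` replicates the reference genes are
#' resampled with replacement, each sample's target/reference-mean ratio is
#' computed, and ratios are normalized to the mean ratio of the
#' `baseline_samples`. The reported estimate is the mean ratio over
#' replicates with an empirical 2.5/97.5 percentile interval. This resamples
#' genes, not reads, and is an approximation of read-level subsampling, not
#' a reimplementation of any external caller.
#'
#' @param normalized long tibble with `gene_id`, `sample_id`, `normalized`.
#' @param reference_genes >= 2 reference (internal standard) gene ids.
#' @param target_gene single target gene id.
#' @param baseline_samples sample ids of the baseline group the ratios are
#'   expressed against.
#' @param n_boot number of replicates (default 10000).
#' @param seed mandatory integer seed; identical seeds give bit-identical
#'   results. RNG state is restored afterwards.
#' @return tibble of class `bootstrap_cn`: `sample_id`, `gene_id`,
#'   `mean_ratio`, `ci_low`, `ci_high`, `n_boot`, `n_discarded`, `seed`.
#'   Replicates with a zero reference mean are discarded (count reported).
#' @export
bootstrap_ratio_cn <- function(normalized, reference_genes, target_gene,
                               baseline_samples, n_boot = 10000, seed) {
  stopifnot_cols(normalized, c("gene_id", "sample_id", "normalized"),
                 "normalized table")
  if (missing(seed)) abort("seed is mandatory")
  if (length(reference_genes) < 2) abort("need >= 2 reference genes")
  if (length(target_gene) != 1) abort("target_gene must be a single gene id")
  m <- long_to_matrix(normalized, "normalized")
  for (g in c(reference_genes, target_gene)) {
    if (!g %in% rownames(m)) abort(sprintf("unknown gene '%s'", g))
  }
  if (!all(baseline_samples %in% colnames(m))) {
    abort("baseline_samples must all be present in the table")
  }
  refs <- m[reference_genes, , drop = FALSE]
  tgt <- m[target_gene, ]
  n_ref <- length(reference_genes)
  draws <- withr::with_seed(seed,
    matrix(sample.int(n_ref, n_boot * n_ref, replace = TRUE), n_boot, n_ref))
  # replicate b uses gene multiset draws[b, ]; its reference mean per sample
  # is a weighted column mean of `refs`
  w <- t(vapply(seq_len(n_boot), function(b) tabulate(draws[b, ], n_ref),
                integer(n_ref))) / n_ref
  ref_means <- w %*% refs                      # n_boot x n_samples
  ratio <- sweep(1 / ref_means, 2, tgt, "*")   # target / resampled ref mean
  base <- rowMeans(ratio[, baseline_samples, drop = FALSE])
  ok <- is.finite(base) & base > 0 &
    apply(is.finite(ratio), 1, all)
  n_discarded <- sum(!ok)
  if (n_discarded > 0) {
    warn(sprintf("%d replicate(s) with zero/undefined reference mean discarded",
                 n_discarded))
  }
  rel <- ratio[ok, , drop = FALSE] / base[ok]
  out <- tibble(
    sample_id = colnames(m),
    gene_id = target_gene,
    mean_ratio = unname(colMeans(rel)),
    ci_low = unname(apply(rel, 2, quantile, probs = 0.025, names = FALSE)),
    ci_high = unname(apply(rel, 2, quantile, probs = 0.975, names = FALSE)),
    n_boot = as.integer(n_boot),
    n_discarded = as.integer(n_discarded),
    seed = as.integer(seed))
  class(out) <- c("bootstrap_cn", class(out))
  out
}

#' Congruence between direct and bootstrap copy-number estimators
#'
#' Pearson correlation (and two-sided p) between the per-sample direct
#' copy-number estimates and the bootstrap mean ratios.
#'
#' @param cn_direct copy-number tibble filtered to one gene (`sample_id`,
#'   `cn`).
#' @param cn_bootstrap `bootstrap_cn` tibble (`sample_id`, `mean_ratio`).
#' @return one-row tibble with `r`, `p_value`, `n`.
#' @export
cross_validate_estimators <- function(cn_direct, cn_bootstrap) {
  stopifnot_cols(cn_direct, c("sample_id", "cn"), "direct estimates")
  stopifnot_cols(cn_bootstrap, c("sample_id", "mean_ratio"),
                 "bootstrap estimates")
  paired <- inner_join(select(cn_direct, "sample_id", "cn"),
                       select(cn_bootstrap, "sample_id", "mean_ratio"),
                       by = "sample_id") |>
    filter(is.finite(.data$cn), is.finite(.data$mean_ratio))
  if (nrow(paired) < 3) abort("need >= 3 paired samples")
  ct <- cor.test(paired$cn, paired$mean_ratio, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(paired))
}
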