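# Per-sample, per-region capture coverage statistics: mean target-base depth,
# within-sample normalized coverage, enrichment factor and sensitivity.

#' Per-region coverage statistics from a depth track
#'
#' For every panel region: mean target-base depth (summed per-base depth over
#' the region divided by region length) and the number of target bases at
#' depth >= `min_depth`. Bases absent from the track count as depth 0; a
#' region on a contig with no track at all gets mean depth 0 with a warning
#' (capture dropout is a biological outcome, not a parse failure).
#'
#' @param track depth-track tibble (see [read_depth_track()]).
#' @param regions panel tibble (see [read_bed()]).
#' @param sample_id optional sample label to stamp on the output.
#' @param min_depth depth threshold for the breadth column (default 1).
#' @return tibble with `sample_id` (if given), `region_id`, `gene_id`,
#'   `region_class`, `mean_depth`, `bases_covered`, `region_length`.
#' @export
region_coverage <- function(track, regions, sample_id = NULL, min_depth = 1) {
  stopifnot_cols(regions, c("region_id", "contig", "start", "end"), "regions")
  track <- validate_depth_track(track)
  missing_contigs <- setdiff(unique(regions$contig), unique(track$contig))
  if (length(missing_contigs) > 0) {
    warn(sprintf("no depth track for contig(s) %s; regions there get depth 0",
                 paste(missing_contigs, collapse = ", ")))
  }
  by_contig <- split(track, track$contig)
  stats <- purrr::pmap(
    list(regions$contig, regions$start, regions$end),
    function(contig, rs, re) {
      t <- by_contig[[contig]]
      if (is.null(t)) return(c(0, 0))
      ov <- pmin(t$end, re) - pmax(t$start, rs)
      keep <- ov > 0
      c(sum(ov[keep] * t$depth[keep]),
        sum(ov[keep & t$depth >= min_depth]))
    })
  out <- tibble(
    region_id = regions$region_id,
    gene_id = if ("gene_id" %in% names(regions)) regions$gene_id
              else regions$region_id,
    region_class = if ("region_class" %in% names(regions)) regions$region_class
                   else "acetophenone_target",
    mean_depth = purrr::map_dbl(stats, 1) / (regions$end - regions$start),
    bases_covered = as.integer(purrr::map_dbl(stats, 2)),
    region_length = as.integer(regions$end - regions$start))
  if (!is.null(sample_id)) out <- bind_cols(tibble(sample_id = sample_id), out)
  out
}

#' Within-sample normalized coverage
#'
#' Normalized coverage of a region is its mean target-base depth divided by
#' the average depth over all target bases of that sample:
#' `denom_s = sum_r(mean_depth * length) / sum_r(length)` over the
#' denominator region set (all panel regions by default; restrict with
#' `denominator_regions`, e.g. to internal standards only). The
#' length-weighted mean of normalized coverage is exactly 1 per sample, and
#' the statistic is invariant to rescaling a sample's depths.
#'
#' @param cov long coverage tibble (from [region_coverage()], stacked over
#'   samples) with `sample_id`, `region_id`, `mean_depth`, `region_length`.
#' @param denominator_regions optional character vector of region_ids to
#'   average over in the denominator.
#' @return `cov` with a `normalized` column appended; samples whose
#'   denominator is 0 get all-missing values with a warning.
#' @export
normalized_coverage <- function(cov, denominator_regions = NULL) {
  stopifnot_cols(cov, c("sample_id", "region_id", "mean_depth",
                        "region_length"), "coverage table")
  denom_set <- denominator_regions %||% unique(cov$region_id)
  if (!any(cov$region_id %in% denom_set)) {
    abort("denominator_regions matches no region in the coverage table")
  }
  denom <- cov |>
    filter(.data$region_id %in% denom_set) |>
    group_by(.data$sample_id) |>
    summarise(denom = sum(.data$mean_depth * .data$region_length) /
                sum(.data$region_length), .groups = "drop")
  if (any(denom$denom == 0)) {
    warn(sprintf("sample(s) with zero average target depth: %s",
                 paste(denom$sample_id[denom$denom == 0], collapse = ", ")))
  }
  cov |>
    left_join(denom, by = "sample_id") |>
    mutate(normalized = ifelse(.data$denom > 0,
                               .data$mean_depth / .data$denom, NA_real_)) |>
    select(-"denom")
}

#' Capture enrichment factor (target-to-background ratio)
#'
#' `EF = (on_target_bases / total_bases) / (target_bp / genome_bp)`: the
#' on-target base fraction relative to the target's share of the genome.
#' EF = 1 means no enrichment.
#'
#' @param on_target_bases,total_bases sequenced bases on target / in total.
#' @param target_bp,genome_bp panel size and genome size in bp.
#' @return enrichment factor (dimensionless).
#' @export
enrichment_factor <- function(on_target_bases, total_bases, target_bp,
                              genome_bp) {
  vals <- c(on_target_bases, total_bases, target_bp, genome_bp)
  if (any(vals <= 0)) abort("all inputs must be > 0")
  if (any(on_target_bases > total_bases)) {
    abort("on_target_bases cannot exceed total_bases")
  }
  (on_target_bases / total_bases) / (target_bp / genome_bp)
}

#' Capture sensitivity per sample
#'
#' Fraction of all target bases covered at or above the depth threshold that
#' `bases_covered` was computed with in [region_coverage()].
#'
#' @param cov long coverage tibble with `sample_id`, `bases_covered`,
#'   `region_length`.
#' @return tibble with `sample_id`, `sensitivity` in \[0, 1\].
#' @export
capture_sensitivity <- function(cov) {
  stopifnot_cols(cov, c("sample_id", "bases_covered", "region_length"),
                 "coverage table")
  cov |>
    group_by(.data$sample_id) |>
    summarise(sensitivity = sum(.data$bases_covered) /
                sum(.data$region_length), .groups = "drop")
}
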