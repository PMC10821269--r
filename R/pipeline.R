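# One-command pipeline: validate-sc -> normalize -> quantify -> stats, with a
# manifest that makes every output reproducible bit-exactly.

PIPELINE_KEYS <- c("counts", "status", "samples", "families", "trim_m",
                   "trim_a", "k_sd", "complete_only", "bootstrap_target",
                   "bootstrap_baseline_provenance", "n_boot", "seed")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file of `key: value` pairs)
#' with file paths `counts` (long TSV: gene_id, sample_id, count), `status`
#' (gene_id, busco_class), `samples` (sample metadata TSV) and `families`
#' (gene_id, family), plus stage parameters `trim_m` (0.30), `trim_a`
#' (0.05), `k_sd` (1), `complete_only` (FALSE), optional bootstrap settings
#' (`bootstrap_target`, `bootstrap_baseline_provenance`, `n_boot` 10000)
#' and a mandatory `seed`. Unknown keys are rejected.
#'
#' @param config named list or path to a YAML config file.
#' @return validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in c("counts", "status", "samples", "families", "seed")) {
    if (is.null(config[[key]])) abort(sprintf("config key '%s' is required", key))
  }
  defaults <- list(trim_m = 0.30, trim_a = 0.05, k_sd = 1,
                   complete_only = FALSE, n_boot = 10000)
  for (key in names(defaults)) {
    config[[key]] <- config[[key]] %||% defaults[[key]]
  }
  config$seed <- as.integer(config$seed)
  config
}

#' Run the copy-number pipeline end to end
#'
#' Stages, in order: `validate-sc` (normalized coverage of candidate
#' standards, log summary, high-confidence filter), `normalize` (TMM),
#' `quantify` (copy numbers, family totals, optional bootstrap
#' cross-estimator), `stats` (per-family two-way ANOVA of copy number on
#' provenance and gene model, plus Tukey HSD on family totals across
#' provenances). Every output is a TSV under `out_dir`; `manifest.json`
#' records input paths and checksums, all parameters, the seed and output
#' checksums, so a re-run from the manifest reproduces every file
#' bit-exactly. A failing stage aborts with the stage name.
#'
#' @param config see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) named list of output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  inputs <- stage("load", {
    list(counts = read_tsv_strict(config$counts,
                                  c("gene_id", "sample_id", "count")),
         samples = read_sample_meta(config$samples),
         families = read_tsv_strict(config$families, c("gene_id", "family")))
  })

  audit <- stage("validate-sc", {
    inputs$status <- read_tsv_strict(config$status,
                                     c("gene_id", "busco_class"))
    candidates <- inputs$status$gene_id
    cand_counts <- filter(inputs$counts, .data$gene_id %in% candidates)
    # gene-level counts: normalized coverage with unit lengths
    cov <- cand_counts |>
      rename(region_id = "gene_id", mean_depth = "count") |>
      mutate(region_length = 1L, gene_id = .data$region_id)
    norm <- normalized_coverage(cov)
    log_cov <- log_normalized_coverage(norm)
    high_confidence_filter(log_cov, inputs$status, k_sd = config$k_sd)
  })
  outputs$high_confidence <- write_tsv_out(
    audit, file.path(out_dir, "high_confidence.tsv"))

  fit <- stage("normalize",
               tmm_normalize(inputs$counts, trim_m = config$trim_m,
                             trim_a = config$trim_a))
  outputs$factors <- write_tsv_out(generics::tidy(fit),
                                   file.path(out_dir, "tmm_factors.tsv"))
  outputs$normalized <- write_tsv_out(fit$normalized,
                                      file.path(out_dir, "normalized.tsv"))

  hc <- hc_genes(audit)
  cn <- stage("quantify", {
    if (length(hc) == 0) abort("no high-confidence single-copy gene retained")
    copy_number(fit$normalized, hc)
  })
  cn_annot <- cn |>
    left_join(select(inputs$samples, "sample_id", "provenance"),
              by = "sample_id") |>
    left_join(select(inputs$families, dplyr::any_of(
      c("gene_id", "family", "model_status"))), by = "gene_id")
  outputs$copy_number <- write_tsv_out(
    select(cn_annot, "sample_id", "provenance", "gene_id", "family", "cn"),
    file.path(out_dir, "copy_number.tsv"))
  totals <- stage("quantify",
                  total_family_cn(cn, inputs$families,
                                  complete_only = isTRUE(config$complete_only)))
  totals <- left_join(totals,
                      select(inputs$samples, "sample_id", "provenance"),
                      by = "sample_id")
  outputs$family_totals <- write_tsv_out(
    totals, file.path(out_dir, "family_totals.tsv"))

  if (!is.null(config$bootstrap_target)) {
    boot <- stage("quantify", {
      baseline <- inputs$samples$sample_id[
        inputs$samples$provenance == config$bootstrap_baseline_provenance]
      if (length(baseline) == 0) abort("empty bootstrap baseline provenance")
      bootstrap_ratio_cn(fit$normalized, reference_genes = hc,
                         target_gene = config$bootstrap_target,
                         baseline_samples = baseline,
                         n_boot = config$n_boot, seed = config$seed)
    })
    outputs$bootstrap <- write_tsv_out(boot,
                                       file.path(out_dir, "bootstrap_cn.tsv"))
  }

  anova_tabs <- stage("stats", {
    fam_cn <- filter(cn_annot, !is.na(.data$family))
    purrr::map(split(fam_cn, fam_cn$family), function(d) {
      if (dplyr::n_distinct(d$provenance) < 2 ||
          dplyr::n_distinct(d$gene_id) < 2) return(NULL)
      mutate(two_way_anova(d, "cn", "provenance", "gene_id"),
             family = d$family[1], .before = 1)
    }) |> purrr::compact() |> bind_rows()
  })
  outputs$anova <- write_tsv_out(anova_tabs, file.path(out_dir, "anova.tsv"))

  manifest <- list(
    package = "capcnv",
    inputs = purrr::map(
      config[c("counts", "status", "samples", "families")],
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = config[intersect(
      setdiff(PIPELINE_KEYS, c("counts", "status", "samples", "families")),
      names(config))],
    outputs = purrr::map(outputs,
                         function(p) list(path = basename(p),
                                          md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs$manifest <- file.path(out_dir, "manifest.json")
  invisible(outputs)
}
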