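# Synthetic capture generator: count matrices with known copy-number truth.
# Model: mu_{g,s} = L_s * e_g * cn_{g,s} with lognormal library sizes L_s and
# lognormal per-gene capture efficiencies e_g; counts are negative binomial
# with mean mu and dispersion phi (Var = mu (1 + phi mu); phi = 0 gives
# deterministic rounded mu). Internal standards have true copy number 1.

#' Build and validate a simulation configuration
#'
#' @param n_samples number of samples (>= 1).
#' @param n_internal_standards number of single-copy internal-standard genes.
#' @param families list of family descriptions; each is a list with `name`,
#'   `n_models`, `total_range` (length-2 numeric: per-sample family total
#'   copy number is drawn uniformly in this range, or a named list of such
#'   ranges keyed by provenance), optional `model_weights` (how the family
#'   total is split across gene models; equal by default) and optional
#'   `planted` (named numeric: sample_id -> exact total, overriding the
#'   draw).
#' @param provenances named integer vector of samples per provenance (must
#'   sum to `n_samples`), or a single integer count of equally-sized
#'   provenances.
#' @param library_size_lognormal_sd SD of log library-size effects
#'   (default 0.5: severalfold depth differences between samples).
#' @param capture_efficiency_lognormal_sd SD of log per-gene capture
#'   efficiency (default 0.05: Tm- and hit-filtered bait sets leave only a
#'   few percent gene-to-gene efficiency spread).
#' @param nb_dispersion negative-binomial dispersion phi >= 0 (default 0.05).
#' @param base_depth expected count for a single-copy gene in an
#'   average-size library (default 500).
#' @param seed mandatory integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_internal_standards, families = list(),
                       provenances = 1, library_size_lognormal_sd = 0.5,
                       capture_efficiency_lognormal_sd = 0.05,
                       nb_dispersion = 0.05, base_depth = 500, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_samples < 1 || n_internal_standards < 1) {
    abort("n_samples and n_internal_standards must be >= 1")
  }
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (library_size_lognormal_sd < 0 || capture_efficiency_lognormal_sd < 0) {
    abort("lognormal SDs must be >= 0")
  }
  if (base_depth <= 0) abort("base_depth must be > 0")
  if (length(provenances) == 1 && is.null(names(provenances))) {
    k <- as.integer(provenances)
    sizes <- rep(n_samples %/% k, k) +
      c(rep(1L, n_samples %% k), rep(0L, k - n_samples %% k))
    provenances <- setNames(sizes, sprintf("P%d", seq_len(k)))
  }
  if (sum(provenances) != n_samples) {
    abort("provenance sizes must sum to n_samples")
  }
  for (fam in families) {
    if (is.null(fam$name) || is.null(fam$n_models) ||
        is.null(fam$total_range)) {
      abort("each family needs name, n_models and total_range")
    }
    if (fam$n_models < 1) abort("n_models must be >= 1")
    rng <- fam$total_range
    ranges <- if (is.list(rng)) rng else list(rng)
    for (r in ranges) {
      if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
        abort("total_range must be a positive (lo, hi) pair")
      }
    }
    if (!is.null(fam$model_weights)) {
      if (length(fam$model_weights) != fam$n_models ||
          any(fam$model_weights <= 0)) {
        abort("model_weights must be positive, one per model")
      }
    }
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_internal_standards = as.integer(n_internal_standards),
              families = families, provenances = provenances,
              library_size_lognormal_sd = library_size_lognormal_sd,
              capture_efficiency_lognormal_sd = capture_efficiency_lognormal_sd,
              nb_dispersion = nb_dispersion, base_depth = base_depth,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a capture count matrix with known truth
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_capture` with elements `counts` (long tibble:
#'   `gene_id`, `sample_id`, `count`), `truth` (list: `cn_true` long tibble,
#'   `efficiency`, `library_size`, `config`), `samples` (tibble:
#'   `sample_id`, `provenance`), `genes` (tibble: `gene_id`, `role`,
#'   `family`) and `statuses` (single-copy classification for the internal
#'   standards, ready for [high_confidence_filter()]). Identical seeds give
#'   identical output; the global RNG state is untouched.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  nS <- config$n_samples
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(nS)),
    provenance = rep(names(config$provenances), config$provenances))
  standards <- sprintf("IS%03d", seq_len(config$n_internal_standards))
  fam_genes <- purrr::map(config$families, function(fam) {
    tibble(gene_id = sprintf("%s_m%d", fam$name, seq_len(fam$n_models)),
           role = "family_model", family = fam$name)
  }) |> bind_rows()
  genes <- bind_rows(
    tibble(gene_id = standards, role = "internal_standard",
           family = NA_character_),
    fam_genes)
  nG <- nrow(genes)

  withr::with_seed(config$seed, {
    lib <- config$base_depth *
      exp(rnorm(nS, 0, config$library_size_lognormal_sd))
    eff <- exp(rnorm(nG, 0, config$capture_efficiency_lognormal_sd))
    cn <- matrix(1, nG, nS, dimnames = list(genes$gene_id, samples$sample_id))
    for (fam in config$families) {
      w <- fam$model_weights %||% rep(1, fam$n_models)
      w <- w / sum(w)
      totals <- draw_family_totals(fam, samples)
      rows <- sprintf("%s_m%d", fam$name, seq_len(fam$n_models))
      cn[rows, ] <- outer(w, totals)
    }
    mu <- sweep(cn * eff, 2, lib, "*")
    counts <- if (config$nb_dispersion == 0) {
      round(mu)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nG, nS)
    }
    dimnames(counts) <- dimnames(mu)
  })

  out <- list(
    counts = matrix_to_long(counts, "count"),
    truth = list(
      cn_true = matrix_to_long(cn, "cn_true"),
      efficiency = tibble(gene_id = genes$gene_id, efficiency = eff),
      library_size = tibble(sample_id = samples$sample_id,
                            library_size = lib),
      config = config),
    samples = samples,
    genes = genes,
    statuses = tibble(gene_id = standards, busco_class = "single_copy"))
  class(out) <- "sim_capture"
  out
}

# Per-sample family totals: uniform in the configured range (possibly per
# provenance), then planted exact totals override the draws.
draw_family_totals <- function(fam, samples) {
  nS <- nrow(samples)
  rng <- fam$total_range
  totals <- if (is.list(rng)) {
    missing_prov <- setdiff(unique(samples$provenance), names(rng))
    if (length(missing_prov) > 0) {
      abort(sprintf("total_range missing provenance(s): %s",
                    paste(missing_prov, collapse = ", ")))
    }
    lo <- vapply(samples$provenance, function(p) rng[[p]][1], numeric(1))
    hi <- vapply(samples$provenance, function(p) rng[[p]][2], numeric(1))
    runif(nS, lo, hi)
  } else {
    runif(nS, rng[1], rng[2])
  }
  names(totals) <- samples$sample_id
  if (!is.null(fam$planted)) {
    unknown <- setdiff(names(fam$planted), samples$sample_id)
    if (length(unknown) > 0) {
      abort(sprintf("planted totals for unknown sample(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    totals[names(fam$planted)] <- fam$planted
  }
  totals
}

#' Simulate a per-base depth track for one region
#'
#' Per-base depths are Poisson around `mean_depth` and emitted as merged
#' bedGraph-style intervals.
#'
#' @param contig contig name.
#' @param start,end 0-based half-open region bounds.
#' @param mean_depth expected per-base depth (>= 0).
#' @param seed mandatory integer seed.
#' @return depth-track tibble (`contig`, `start`, `end`, `depth`).
#' @export
simulate_depth_track <- function(contig, start, end, mean_depth, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (mean_depth < 0) abort("mean_depth must be >= 0")
  L <- end - start
  if (L < 1) abort("region length must be >= 1")
  depths <- withr::with_seed(seed, rpois(L, mean_depth))
  r <- rle(depths)
  ends <- start + cumsum(r$lengths)
  tibble(contig = contig, start = c(start, head(ends, -1)), end = ends,
         depth = as.numeric(r$values))
}

#' Preset panel emulating the study design
#'
#' 40 samples in 9 provenances, 120 single-copy internal standards, one
#' five-model high-copy family ("bglu1") whose per-sample totals are drawn
#' uniformly over \[56, 381\] with the extremes planted exactly (so the true
#' max/min fold range is 381/56 = 6.8 by construction), and one single-copy
#' family ("ugt5b") with planted outlier totals of 14, 12, 11 and 4 in four
#' samples from four different provenances. Negative-binomial dispersion
#' 0.05.
#'
#' @param seed mandatory integer seed.
#' @return `sim_capture` list (see [simulate_counts()]); the family map for
#'   [total_family_cn()] is the `genes` element filtered to family models.
#' @export
study_scale_panel <- function(seed) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- sim_config(
    n_samples = 40,
    n_internal_standards = 120,
    families = list(
      list(name = "bglu1", n_models = 5,
           total_range = c(56, 381),
           model_weights = c(0.30, 0.25, 0.20, 0.15, 0.10),
           planted = c(S05 = 56, S37 = 381)),
      list(name = "ugt5b", n_models = 1,
           total_range = c(1, 1),
           planted = c(S01 = 14, S06 = 12, S11 = 11, S21 = 4))),
    provenances = setNames(c(5L, 5L, 5L, 5L, 4L, 4L, 4L, 4L, 4L),
                           sprintf("P%d", 1:9)),
    seed = seed)
  simulate_counts(cfg)
}
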