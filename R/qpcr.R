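# qPCR validation arm: threshold-cycle (C-half) calling at the inflection of
# the sigmoidal amplification curve, standard-curve fitting from a dilution
# series, and absolute copy estimation.

#' Threshold cycle (C-half) from amplification curves
#'
#' Fits a 4-parameter logistic
#' `F(c) = base + amp / (1 + exp(-(c - m)/s))` per well and returns `m`, the
#' inflection point of the sigmoid, as the threshold cycle. A parametric fit
#' is robust at 1-cycle sampling where a numerical second derivative is not.
#' Initialization: base = min(F), amp = range(F), m = cycle of the largest
#' first difference, s = 1; bounded Levenberg-Marquardt optimization.
#' Curves whose total rise is below `floor_frac` of their signal magnitude
#' are flagged `no_amplification` and get a missing C-half.
#'
#' @param wells tibble with `well_id`, `cycle`, `fluorescence`; >= 8 points
#'   per well, cycles strictly increasing within a well.
#' @param floor_frac no-amplification threshold: minimum rise as a fraction
#'   of the largest absolute fluorescence in the well (default 0.05).
#' @return tibble with `well_id`, `c_half`, `scale` (s), `base`, `amp`,
#'   `resid_sd`, `flag` ("ok", "no_amplification" or "fit_failed").
#' @export
c_half <- function(wells, floor_frac = 0.05) {
  stopifnot_cols(wells, c("well_id", "cycle", "fluorescence"), "wells")
  wells |>
    group_by(.data$well_id) |>
    dplyr::group_modify(~ fit_one_well(.x, floor_frac)) |>
    ungroup()
}

fit_one_well <- function(d, floor_frac) {
  empty <- tibble(c_half = NA_real_, scale = NA_real_, base = NA_real_,
                  amp = NA_real_, resid_sd = NA_real_)
  if (nrow(d) < 8) abort("each amplification curve needs >= 8 points")
  if (any(diff(d$cycle) <= 0)) abort("cycles must be strictly increasing")
  f <- d$fluorescence
  rise <- max(f) - min(f)
  if (rise < floor_frac * max(abs(f), 1e-12)) {
    return(mutate(empty, flag = "no_amplification"))
  }
  start <- list(base = min(f), amp = rise,
                m = d$cycle[which.max(diff(f)) + 1], s = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ base + amp / (1 + exp(-(cycle - m) / s)),
      data = d, start = start,
      lower = c(base = -Inf, amp = 0, m = min(d$cycle), s = 1e-3),
      upper = c(base = Inf, amp = Inf, m = max(d$cycle), s = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(mutate(empty, flag = "fit_failed"))
  cf <- coef(fit)
  tibble(c_half = unname(cf["m"]), scale = unname(cf["s"]),
         base = unname(cf["base"]), amp = unname(cf["amp"]),
         resid_sd = sd(residuals(fit)), flag = "ok")
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares line `Cq = intercept + slope * log10(copies)`. Duplicate
#' wells at a dilution level are averaged into the fit. Amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 = perfect doubling, for which the
#' slope is `-1/log10(2) ~ -3.3219` cycles per decade).
#'
#' @param dilutions tibble with `copies` (> 0) and `cq`; >= 3 distinct
#'   dilution levels.
#' @return object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_levels`, `positive_slope` flag and the
#'   underlying `lm` fit. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
fit_standard_curve <- function(dilutions) {
  stopifnot_cols(dilutions, c("copies", "cq"), "dilution series")
  if (any(dilutions$copies <= 0)) abort("all copies must be > 0")
  levels <- dilutions |>
    group_by(.data$copies) |>
    summarise(cq = mean(.data$cq), .groups = "drop")
  if (nrow(levels) < 3) abort("need >= 3 distinct dilution levels")
  fit <- lm(cq ~ log10(copies), data = levels)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) warn("non-amplifying dilution series: slope >= 0")
  # noise-free series legitimately fit perfectly; silence summary.lm's
  # "essentially perfect fit" advisory
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- list(slope = slope, intercept = unname(coef(fit)[1]),
              r_squared = r2,
              efficiency = 10^(-1 / slope) - 1,
              n_levels = nrow(levels), positive_slope = slope >= 0,
              fit = fit, levels = levels)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f log10(copies)  (R^2 = %.4f, efficiency = %.1f%%)\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute copies from Cq values and a standard curve
#'
#' Inverts the standard curve: `copies_per_reaction =
#' 10^((cq - intercept)/slope)`, then divides by the number of genome
#' equivalents loaded per reaction. Missing Cq values (no amplification)
#' propagate as missing copies.
#'
#' @param cq numeric vector of threshold cycles (NA = no amplification).
#' @param curve a `standard_curve` object with negative slope.
#' @param genomes_per_reaction genome equivalents per reaction (> 0); see
#'   [genomes_per_reaction()].
#' @return tibble with `cq`, `copies_per_reaction`, `copies_per_genome`.
#' @export
absolute_copies <- function(cq, curve, genomes_per_reaction = 1) {
  if (!inherits(curve, "standard_curve")) {
    abort("curve must be a standard_curve object")
  }
  if (curve$slope >= 0) abort("standard curve slope must be negative")
  if (genomes_per_reaction <= 0) abort("genomes_per_reaction must be > 0")
  cpr <- 10^((cq - curve$intercept) / curve$slope)
  tibble(cq = cq, copies_per_reaction = cpr,
         copies_per_genome = cpr / genomes_per_reaction)
}

#' Genome equivalents per qPCR reaction
#'
#' Converts input DNA mass to haploid genome equivalents using the mean
#' molar mass of a double-stranded base pair (~650 g/mol):
#' `genomes = mass_g * N_A / (genome_size_bp * 650)`.
#'
#' @param dna_ng input DNA per reaction in nanograms.
#' @param genome_size_bp haploid genome size in bp (e.g. ~2e10 for spruce).
#' @param bp_molar_mass molar mass per bp in g/mol (default 650).
#' @return genome equivalents per reaction.
#' @export
genomes_per_reaction <- function(dna_ng, genome_size_bp,
                                 bp_molar_mass = 650) {
  if (dna_ng <= 0 || genome_size_bp <= 0) abort("inputs must be > 0")
  dna_ng * 1e-9 * 6.02214076e23 / (genome_size_bp * bp_molar_mass)
}
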