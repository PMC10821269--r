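# broom-style tidy()/glance() methods and ggplot2 visualisations for the
# package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tmm_normalize
#' @param x a `tmm_fit` object.
#' @param ... unused.
#' @method tidy tmm_fit
#' @export
tidy.tmm_fit <- function(x, ...) x$factors

#' @rdname tmm_normalize
#' @method glance tmm_fit
#' @export
glance.tmm_fit <- function(x, ...) {
  tibble(reference = x$reference, n_samples = nrow(x$factors),
         trim_m = x$trim_m, trim_a = x$trim_a,
         factor_min = min(x$factors$factor),
         factor_max = max(x$factors$factor))
}

#' @rdname fit_standard_curve
#' @param x a `standard_curve` object.
#' @param ... unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency = x$efficiency, n_levels = x$n_levels)
}

#' @rdname fit_standard_curve
#' @param object a `standard_curve` object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = log10(.data$copies), y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10 input copies", y = "threshold cycle (C-half)",
                  title = sprintf("slope %.3f, efficiency %.1f%%, R2 %.4f",
                                  object$slope, 100 * object$efficiency,
                                  object$r_squared))
}

#' @rdname bootstrap_ratio_cn
#' @param object a `bootstrap_cn` tibble.
#' @param ... unused.
#' @method autoplot bootstrap_cn
#' @export
autoplot.bootstrap_cn <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id,
                                       y = .data$mean_ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "mean copy-number ratio vs baseline") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar plot of per-gene log-normalized coverage with single-copy status
#'
#' Genes in ascending order of log-normalized coverage, coloured by their
#' classification, with the candidate mean and the +/- k SD window marked —
#' the visual check used to pick high-confidence internal standards.
#'
#' @param audit tibble from [high_confidence_filter()].
#' @param k_sd window half-width to draw (default 1).
#' @return a ggplot object.
#' @export
plot_log_coverage <- function(audit, k_sd = 1) {
  stopifnot_cols(audit, c("gene_id", "log_norm_cov", "busco_class"),
                 "audit table")
  mu <- attr(audit, "mu")
  sigma <- attr(audit, "sigma")
  d <- audit |>
    filter(is.finite(.data$log_norm_cov)) |>
    arrange(.data$log_norm_cov) |>
    mutate(gene_id = factor(.data$gene_id, levels = .data$gene_id))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id,
                                       y = .data$log_norm_cov,
                                       fill = .data$busco_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "log normalized coverage",
                  fill = "classification") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  if (!is.null(mu) && !is.null(sigma)) {
    p <- p + ggplot2::geom_hline(yintercept = mu, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = mu + c(-1, 1) * k_sd * sigma,
                          linetype = "dotted")
  }
  p
}

#' Copy number of gene models across provenances
#'
#' @param cn annotated copy-number tibble with `sample_id`, `provenance`,
#'   `gene_id`, `cn` (e.g. the pipeline's copy_number.tsv).
#' @return a ggplot object: per-provenance mean +/- 1 SE per gene model.
#' @export
plot_copy_number <- function(cn) {
  stopifnot_cols(cn, c("sample_id", "provenance", "gene_id", "cn"),
                 "copy-number table")
  d <- cn |>
    group_by(.data$provenance, .data$gene_id) |>
    summarise(mean_cn = mean(.data$cn),
              se = sd(.data$cn) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$provenance, y = .data$mean_cn,
                                  colour = .data$gene_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_cn - .data$se, ymax = .data$mean_cn + .data$se),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "provenance", y = "copy number", colour = "gene model")
}

#' Amplification curves with fitted threshold cycles
#'
#' @param wells tibble with `well_id`, `cycle`, `fluorescence`.
#' @param fits optional tibble from [c_half()] to mark the inflections.
#' @return a ggplot object.
#' @export
plot_amplification <- function(wells, fits = NULL) {
  stopifnot_cols(wells, c("well_id", "cycle", "fluorescence"), "wells")
  p <- ggplot2::ggplot(wells, ggplot2::aes(x = .data$cycle,
                                           y = .data$fluorescence,
                                           colour = .data$well_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "fluorescence", colour = "well")
  if (!is.null(fits)) {
    p <- p + ggplot2::geom_vline(
      data = filter(fits, .data$flag == "ok"),
      ggplot2::aes(xintercept = .data$c_half, colour = .data$well_id),
      linetype = "dotted")
  }
  p
}
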