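#' Plot an SMCHR curve
#'
#' Draws the SMCHR over time (solid) against the CHR (dashed) and a
#' reference line at 1; Monte Carlo curves get a pointwise
#' \eqn{\pm 2\,\mathrm{SE}} ribbon.
#'
#' @param object An `hr_curve` from [smchr_curve()] or [smchr_mc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.3, colour = "grey70")
  if ("se" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$smchr - 2 * .data$se,
                   ymax = .data$smchr + 2 * .data$se),
      alpha = 0.2)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$chr, linetype = "CHR")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smchr, linetype = "SMCHR")) +
    ggplot2::scale_linetype_manual(NULL,
                                   values = c(CHR = "dashed", SMCHR = "solid")) +
    ggplot2::labs(x = "time", y = "hazard ratio",
                  title = attr(object, "digest")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 8))
}

#' @export
plot.hr_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot a Cox-estimand censoring sweep
#'
#' One line per exponential censoring mean, showing how the estimand of a
#' misspecified proportional-hazards fit moves with the follow-up time.
#'
#' @param sweep A tibble from [cox_sweep()].
#' @return A ggplot object.
#' @export
plot_cox_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$follow_up, y = .data$estimand,
                               colour = factor(.data$censoring_mean))) +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "administrative follow-up time",
                  y = "exp(E[log OHR(T) | uncensored])",
                  colour = "censoring mean") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
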