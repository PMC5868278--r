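#' @importFrom ggplot2 ggplot aes geom_boxplot geom_point geom_line geom_col
#'   geom_hline labs scale_x_log10 autoplot position_dodge
NULL

#' Box-whisker plot of readthrough efficiencies
#'
#' One box per construct: centre line at the median, box at the 25th/75th
#' percentiles (type-7), whiskers to 1.5 interquartile ranges, outliers as
#' dots — the usual dual-luciferase figure conventions. An optional dashed
#' baseline marks background readthrough.
#'
#' @param object An `efficiency_result` from [readthrough_efficiency()].
#' @param baseline Optional percent readthrough drawn as a dashed line
#'   (e.g. the stop-codon-alone background level).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.efficiency_result <- function(object, baseline = NULL, ...) {
  df <- tidyr::unnest(
    tibble(construct = object$construct, efficiency = object$efficiencies),
    "efficiency")
  p <- ggplot(df, aes(x = .data$construct, y = .data$efficiency)) +
    geom_boxplot(coef = 1.5, outlier.shape = 16) +
    labs(x = NULL, y = "% readthrough")
  if (!is.null(baseline)) {
    p <- p + geom_hline(yintercept = baseline, linetype = "dashed")
  }
  p
}

#' Dose-response data and fitted curve
#'
#' @param object A `dose_fit` from [fit_dose_response()].
#' @param ... Unused.
#' @return A ggplot with per-dose observations and the fitted
#'   four-parameter logistic curve on a log dose axis.
#' @export
autoplot.dose_fit <- function(object, ...) {
  d <- object$data
  p <- object$params
  grid <- tibble(dose = 10^seq(log10(min(d$dose)), log10(max(d$dose)),
                               length.out = 200))
  grid$response <- fourpl(log10(grid$dose), p$floor, p$top,
                          log10(p$ec50), p$slope)
  ggplot(d, aes(x = .data$dose, y = .data$response)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(x = "dose", y = "relative luciferase activity",
         title = object$curve_id)
}

#' Observed versus expected motif count
#'
#' @param object A `census_result` from [census()] or [depletion_test()].
#' @param ... Unused.
#' @return A ggplot comparing the observed motif count with its
#'   independence-null expectation.
#' @export
autoplot.census_result <- function(object, ...) {
  df <- tibble(what = factor(c("observed", "expected"),
                             levels = c("observed", "expected")),
               count = c(object$observed, object$expected))
  ggplot(df, aes(x = .data$what, y = .data$count)) +
    geom_col(width = 0.6) +
    labs(x = NULL, y = "motif count",
         title = sprintf("%s: one-sided %s p = %.3g",
                         object$motif %||% "motif", object$direction,
                         object$p_value))
}
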