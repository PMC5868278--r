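fourpl <- function(logdose, floor_, top, log_ec50, slope) {
  floor_ + (top - floor_) / (1 + 10^(slope * (log_ec50 - logdose)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = floor + (top - floor) / (1 + 10^(slope * (log10(EC50) - log10(dose))))`
#' on log10 dose, via Levenberg-Marquardt ([minpack.lm::nlsLM]) with
#' multiple starts: the floor/top start from the extreme per-dose mean
#' responses, the EC50 from horizontal interpolation at half-maximal mean
#' response, and the slope from `{0.5, 1, 2}`; the best converged start by
#' residual sum of squares wins. Convergence tolerance 1e-8, at most 500
#' iterations.
#'
#' @param data Tibble with `dose` and `response` columns (one curve).
#' @param curve_id Label stored in the result.
#' @return A `dose_fit` object: `params` (floor, top, ec50, slope), `rss`,
#'   `data`, `converged`. Has `tidy()`/`glance()` methods.
#' @export
fit_dose_response <- function(data, curve_id = data$curve_id[1] %||% "curve") {
  if (!all(c("dose", "response") %in% names(data))) {
    stop_validation("`data` needs `dose` and `response` columns")
  }
  d <- data[data$dose > 0 & !is.na(data$response), , drop = FALSE]
  if (nrow(d) < 4L) stop_data("need at least 4 positive-dose observations")
  ld <- log10(d$dose)
  means <- summarise(group_by(tibble(ld = ld, y = d$response), ld),
                     y = mean(.data$y), .groups = "drop")
  means <- arrange(means, ld)
  f0 <- min(means$y)
  t0 <- max(means$y)
  half <- (f0 + t0) / 2
  le0 <- interp_at_response(means$ld, means$y, half) %||% stats::median(ld)

  best <- NULL
  for (s0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(x, f, t, le, s),
        data = list(y = d$response, x = ld),
        start = list(f = f0, t = t0, le = le0, s = s0),
        control = minpack.lm::nls.lm.control(ftol = 1e-8, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop_data("dose-response fit failed to converge")
  cf <- stats::coef(best$fit)
  structure(
    list(curve_id = curve_id,
         params = tibble(floor = unname(cf["f"]), top = unname(cf["t"]),
                         ec50 = 10^unname(cf["le"]), slope = unname(cf["s"])),
         rss = best$rss, data = d, converged = TRUE),
    class = "dose_fit"
  )
}

# dose (log10) at which the piecewise-linear response curve crosses `target`;
# NULL if the target is outside the observed response range
interp_at_response <- function(ld, y, target) {
  for (i in seq_len(length(y) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]
    if ((y1 - target) * (y2 - target) <= 0 && y1 != y2) {
      return(ld[i] + (target - y1) / (y2 - y1) * (ld[i + 1L] - ld[i]))
    }
  }
  NULL
}

#' @export
print.dose_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("dose_fit %s: EC50 = %.3g, slope = %.2f, floor = %.2f, top = %.2f (rss %.3g)\n",
              x$curve_id, p$ec50, p$slope, p$floor, p$top, x$rss))
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x A `dose_fit`.
#' @param ... Unused.
#' @export
tidy.dose_fit <- function(x, ...) {
  mutate(x$params, curve_id = x$curve_id, .before = 1)
}

#' @rdname fit_dose_response
#' @export
glance.dose_fit <- function(x, ...) {
  tibble(curve_id = x$curve_id, ec50 = x$params$ec50, rss = x$rss,
         n = nrow(x$data), converged = x$converged)
}

#' Dose shift between two dose-response curves
#'
#' The primary estimate is the ratio `EC50_b / EC50_a` of the fitted
#' four-parameter logistic curves: how much more ligand curve `b` needs to
#' elicit the same response as curve `a`. A fit-free estimate by horizontal
#' interpolation of the per-dose mean responses at the shared half-maximal
#' response is reported alongside; it is `NA` (flagged) when the response
#' ranges of the two curves do not overlap at that level.
#'
#' @param fit_a,fit_b `dose_fit` objects (a = reference curve).
#' @return One-row tibble with `shift_fit`, `shift_interp`,
#'   `interp_available`.
#' @export
dose_shift <- function(fit_a, fit_b) {
  if (!inherits(fit_a, "dose_fit") || !inherits(fit_b, "dose_fit")) {
    stop_validation("`fit_a` and `fit_b` must be dose_fit objects")
  }
  shift_fit <- fit_b$params$ec50 / fit_a$params$ec50
  halfmax <- function(f) (f$params$floor + f$params$top) / 2
  target <- mean(c(halfmax(fit_a), halfmax(fit_b)))
  interp_one <- function(f) {
    means <- summarise(group_by(tibble(ld = log10(f$data$dose),
                                       y = f$data$response), .data$ld),
                       y = mean(.data$y), .groups = "drop")
    means <- arrange(means, .data$ld)
    interp_at_response(means$ld, means$y, target)
  }
  la <- interp_one(fit_a)
  lb <- interp_one(fit_b)
  ok <- !is.null(la) && !is.null(lb)
  if (!ok) warn("response ranges do not overlap at half-max; fit-free estimate unavailable")
  tibble(shift_fit = shift_fit,
         shift_interp = if (ok) 10^(lb - la) else NA_real_,
         interp_available = ok)
}
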