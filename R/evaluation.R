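## External-comparison analytics: catch-per-unit-effort, trend regression
## against the model trajectory, and credible-interval coverage of
## independent point estimates.

#' Catch per unit effort
#'
#' Annual harvest divided by annual hunting permits issued; a standard
#' relative abundance index.
#'
#' @param O_y annual harvest totals.
#' @param permits_y annual permit counts (> 0), same length.
#' @return per-year CPUE.
#' @export
cpue <- function(O_y, permits_y) {
  if (length(O_y) != length(permits_y))
    stop_domain("cpue: series lengths disagree")
  if (any(permits_y <= 0)) stop_domain("cpue: permits must be > 0")
  O_y / permits_y
}

#' Ordinary least-squares trend comparison
#'
#' Regresses `y` on `x` (e.g. the model's abundance trajectory on CPUE) and
#' reports the R-squared, the two-sided p-value of the slope, residual
#' degrees of freedom (`n - 2`) and the coefficients.
#'
#' @param x,y per-year numeric series, length >= 3, no missing values.
#' @return object of class `trend_comparison` with fields `r_squared`,
#'   `p_value`, `df`, `slope`, `intercept`, `n`.
#' @export
trend_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_domain("trend_regression: need >= 3 paired points")
  if (anyNA(x) || anyNA(y)) stop_domain("trend_regression: missing values")
  if (stats::var(x) == 0)
    stop_domain("trend_regression: regressor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(r_squared = sm$r.squared,
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 df = fit$df.residual,
                 slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 n = length(x)),
            class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat(sprintf("<trend_comparison> df = %d, R^2 = %.3f, p = %.4g, slope = %.4g\n",
              x$df, x$r_squared, x$p_value, x$slope))
  invisible(x)
}

#' Does the model's credible interval cover an external estimate?
#'
#' A numeric replacement for visual comparison against an independent
#' abundance estimate (e.g. a capture-recapture point estimate): `TRUE` iff
#' the external point lies inside the model's central 95% credible interval
#' for total abundance in that year. Interval endpoints are inclusive.
#'
#' @param samples a `posterior_samples` object, or a summary data frame from
#'   [posterior_summary()].
#' @param year calendar year to check.
#' @param external_estimate external point estimate of total abundance.
#' @return logical flag.
#' @export
interval_covers <- function(samples, year, external_estimate) {
  summ <- if (inherits(samples, "posterior_samples"))
    posterior_summary(samples) else samples
  row <- summ[summ$variable == paste0("N_total[", year, "]"), ]
  if (nrow(row) != 1)
    stop_domain("interval_covers: year ", year, " not present in summary")
  external_estimate >= row$q2.5 && external_estimate <= row$q97.5
}
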