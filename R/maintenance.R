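#' Fit the log-linear heat production vs intake regression
#'
#' Heat production rises log-linearly with metabolizable energy intake:
#' `ln(HP) = ln(a) + b * MEI`. Fitting this semi-log model by ordinary least
#' squares over a ladder of feeding levels and extrapolating to zero intake
#' gives fasting heat production `FHP = exp(ln a)` — a more realistic
#' estimate at zero MEI than a straight-line extrapolation, because HP falls
#' off exponentially as intake is withdrawn. FHP is equated with the net
#' energy requirement for maintenance (NEm).
#'
#' @param mei Metabolizable energy intake, MJ/kg BW^0.75/d. Alternatively a
#'   data frame with columns `mei` and `hp` (e.g. from [compute_balance()]),
#'   in which case `hp` is ignored.
#' @param hp Heat production, MJ/kg BW^0.75/d; all values must be positive.
#' @return An object of class `maintenance_fit`: `intercept` (ln a), `slope`
#'   (b, per MJ/kg BW^0.75/d), `r_squared`, `rsd` (residual SD of ln HP),
#'   `p_slope` (two-sided), `n`, `fhp` (MJ/kg BW^0.75/d) and `nem_kj`
#'   (kJ/kg BW^0.75/d).
#' @export
#' @examples
#' lv <- reference_feeding_levels()
#' fit <- fit_lnhp_regression(lv$mei_mean, lv$hp_mean)
#' fit
fit_lnhp_regression <- function(mei, hp = NULL) {
  if (is.data.frame(mei)) {
    if (!all(c("mei", "hp") %in% names(mei)))
      stop("data frame input must have columns `mei` and `hp`", call. = FALSE)
    hp <- mei$hp
    mei <- mei$mei
  }
  if (length(mei) != length(hp))
    stop("`mei` and `hp` must have the same length", call. = FALSE)
  if (length(mei) < 3)
    stop("need at least 3 points to fit the regression", call. = FALSE)
  bad <- which(hp <= 0)
  if (length(bad))
    stop("HP must be positive; offending point(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (stats::sd(mei) == 0)
    stop("MEI has zero variance: degenerate design", call. = FALSE)

  fit <- stats::lm(log(hp) ~ mei)
  # a noise-free trial fits perfectly; summary.lm warns, harmlessly
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  intercept <- co["(Intercept)", "Estimate"]
  slope <- co["mei", "Estimate"]
  sse <- sum(stats::residuals(fit)^2)
  n <- length(mei)
  out <- list(
    intercept = intercept,
    slope = slope,
    slope_se = co["mei", "Std. Error"],
    r_squared = sm$r.squared,
    rsd = sqrt(sse / (n - 2)),
    p_slope = co["mei", "Pr(>|t|)"],
    n = n,
    fhp = exp(intercept),
    nem_kj = 1000 * exp(intercept)
  )
  class(out) <- "maintenance_fit"
  out
}

#' Fasting heat production and maintenance requirement from a fit
#'
#' Extrapolates the fitted log-linear model to zero intake: at MEI = 0,
#' `HP = exp(intercept)`, the fasting heat production. The maintenance net
#' energy requirement NEm equals FHP, reported in kJ/kg BW^0.75/d
#' (1000 x FHP in MJ).
#'
#' @param fit A [fit_lnhp_regression()] result.
#' @return A list with `fhp` (MJ/kg BW^0.75/d) and `nem_kj` (kJ/kg BW^0.75/d).
#' @export
#' @examples
#' fhp_from_fit(fit_lnhp_regression(c(0, 0.5, 1), exp(c(0, 0.5, 1))))
fhp_from_fit <- function(fit) {
  if (!inherits(fit, "maintenance_fit"))
    stop("`fit` must be a maintenance_fit", call. = FALSE)
  list(fhp = exp(fit$intercept), nem_kj = 1000 * exp(fit$intercept))
}

#' @export
print.maintenance_fit <- function(x, digits = 4, ...) {
  cat("Log-linear heat production model: ln(HP) = ln(a) + b * MEI\n")
  cat(sprintf("  ln(a) = %.*f   b = %.*f (SE %.*f, p = %.3g)\n",
              digits, x$intercept, digits, x$slope, digits, x$slope_se,
              x$p_slope))
  cat(sprintf("  R-squared = %.*f   residual SD = %.*f   n = %d\n",
              digits, x$r_squared, digits, x$rsd, x$n))
  cat(sprintf("  FHP = %.*f MJ/kg BW^0.75/d  =>  NEm = %.0f kJ/kg BW^0.75/d\n",
              digits, x$fhp, x$nem_kj))
  invisible(x)
}
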