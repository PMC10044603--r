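#' Construct a prediction-equation object
#'
#' Low-level constructor for the linear NE prediction equation container used
#' throughout the prediction module.
#'
#' @param predictors Character vector of predictor names, in entry order.
#' @param coefficients Named numeric vector of slopes (same names).
#' @param intercept Numeric intercept.
#' @param r_squared,rsd,p_value,n Fit statistics: coefficient of
#'   determination, residual SD `sqrt(SSE / (n - p - 1))`, overall-F p-value
#'   and sample size.
#' @return An object of class `prediction_equation`.
#' @keywords internal
#' @export
new_prediction_equation <- function(predictors, coefficients, intercept,
                                    r_squared, rsd, p_value, n) {
  stopifnot(length(predictors) == length(coefficients))
  structure(
    list(predictors = predictors,
         coefficients = stats::setNames(as.numeric(coefficients), predictors),
         intercept = as.numeric(intercept),
         r_squared = r_squared, rsd = rsd, p_value = p_value,
         n = as.integer(n)),
    class = "prediction_equation"
  )
}

#' Pairwise Pearson correlation report
#'
#' Pearson correlations between every pair of the supplied traits, with
#' t-based two-sided p-values and the conventional significance stars
#' (`*` p < 0.05, `**` p < 0.01). Constant columns have no defined
#' correlation; their pairs are reported as missing with a warning.
#'
#' @param panel Data frame of per-source trait values.
#' @param vars Columns to correlate; default the panel's numeric columns.
#' @return An object of class `correlation_report`: matrices `r`, `p` and
#'   `stars`, plus `n`.
#' @export
#' @examples
#' panel <- generate_wheat_panel(generator_config(seed = 1))
#' pearson_matrix(panel, c("NE", "AME", "NDF", "ADF"))
pearson_matrix <- function(panel, vars = NULL) {
  if (is.null(vars))
    vars <- names(panel)[vapply(panel, is.numeric, logical(1))]
  x <- as.matrix(panel[, vars, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows", call. = FALSE)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(vars[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(x))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat("Pearson correlations (n = ", x$n, ")\n", sep = "")
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  disp[upper.tri(disp)] <- ""
  print(as.data.frame(disp), right = TRUE)
  cat("*, ** : p < 0.05, p < 0.01 (two-sided)\n")
  invisible(x)
}

#' Ordinary least-squares NE prediction fit
#'
#' Fits `response ~ predictors` by OLS and packages the result as a
#' [prediction_equation][new_prediction_equation]. The residual SD is
#' `sqrt(SSE / (n - p - 1))` and the p-value is the overall-F test of the
#' regression. A rank-deficient design is an error naming the collinear
#' columns rather than a silent coefficient drop.
#'
#' @param panel Data frame containing response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return A `prediction_equation`.
#' @export
#' @examples
#' panel <- generate_wheat_panel(generator_config(seed = 1, noise_sd = 0))
#' ols_fit(panel, "NE", c("AME", "NDF", "ADF"))
ols_fit <- function(panel, response, predictors) {
  miss <- setdiff(c(response, predictors), names(panel))
  if (length(miss))
    stop("columns not in panel: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(panel)
  if (n <= length(predictors) + 1)
    stop("need n > number of predictors + 1", call. = FALSE)

  X <- cbind(`(Intercept)` = 1,
             as.matrix(panel[, predictors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fm <- stats::as.formula(paste(response, "~",
                                paste(predictors, collapse = " + ")))
  fit <- stats::lm(fm, data = panel)
  sm <- suppressWarnings(summary(fit))  # zero-noise panels fit perfectly
  co <- stats::coef(fit)
  sse <- sum(stats::residuals(fit)^2)
  p <- length(predictors)
  pval <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  new_prediction_equation(
    predictors = predictors, coefficients = co[predictors],
    intercept = co[["(Intercept)"]],
    r_squared = sm$r.squared, rsd = sqrt(sse / (n - p - 1)),
    p_value = unname(pval), n = n
  )
}

# partial-F p-value for adding/removing one term between nested OLS fits
partial_f <- function(sse_small, sse_big, df_big) {
  f <- (sse_small - sse_big) / (sse_big / df_big)
  p <- stats::pf(f, 1, df_big, lower.tail = FALSE)
  c(F = f, p = p)
}

sse_of <- function(panel, response, predictors) {
  fm <- if (length(predictors))
    stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  else stats::as.formula(paste(response, "~ 1"))
  sum(stats::residuals(stats::lm(fm, data = panel))^2)
}

#' Classical stepwise selection of an NE prediction equation
#'
#' Stepwise multiple regression with partial-F entry and removal tests, the
#' procedure behind published feed-energy prediction tables: at each step the
#' candidate with the smallest p-to-enter joins the model if that p-value is
#' below `alpha_enter`, then any included predictor whose p-to-remove exceeds
#' `alpha_remove` is dropped. Ties on p-to-enter break by larger partial F,
#' then by name. The equation after every completed step is returned, giving
#' the cumulative sequence of models of increasing precision.
#'
#' @param panel Data frame containing response and candidates.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha_enter,alpha_remove Entry and removal thresholds on the
#'   partial-F p-value; `alpha_enter <= alpha_remove` (defaults 0.05/0.10).
#' @return A list of class `stepwise_path`: `steps`, a list of
#'   `prediction_equation`s (one per completed step), and `final`, the last
#'   one (or `NULL`, with a warning, if no candidate passes entry).
#' @export
#' @examples
#' panel <- generate_wheat_panel(generator_config(seed = 1))
#' stepwise_select(panel, "NE", c("CP", "CF", "NDF", "ADF", "EE", "Ash"))
stepwise_select <- function(panel, response, candidates,
                            alpha_enter = 0.05, alpha_remove = 0.10) {
  if (length(candidates) < 1)
    stop("need at least one candidate predictor", call. = FALSE)
  if (alpha_enter > alpha_remove)
    stop("`alpha_enter` must be <= `alpha_remove`", call. = FALSE)
  n <- nrow(panel)
  included <- character(0)
  steps <- list()
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    sse0 <- sse_of(panel, response, included)
    stats_in <- vapply(pool, function(cand) {
      preds <- c(included, cand)
      df_big <- n - length(preds) - 1L
      partial_f(sse0, sse_of(panel, response, preds), df_big)
    }, c(F = 0, p = 0))
    ord <- order(stats_in["p", ], -stats_in["F", ], pool)
    best <- ord[1]
    if (!(stats_in["p", best] < alpha_enter)) break
    included <- c(included, pool[best])

    # backward pass: drop anything whose p-to-remove exceeds alpha_remove
    repeat {
      if (length(included) < 2) break
      sse_full <- sse_of(panel, response, included)
      df_full <- n - length(included) - 1L
      stats_out <- vapply(included, function(v) {
        partial_f(sse_of(panel, response, setdiff(included, v)),
                  sse_full, df_full)
      }, c(F = 0, p = 0))
      worst <- which.max(stats_out["p", ])
      if (stats_out["p", worst] > alpha_remove)
        included <- setdiff(included, included[worst])
      else break
    }
    steps[[length(steps) + 1L]] <- ols_fit(panel, response, included)
  }
  if (!length(steps))
    warning("no candidate passed the entry threshold; empty selection")
  structure(list(steps = steps,
                 final = if (length(steps)) steps[[length(steps)]] else NULL,
                 alpha_enter = alpha_enter, alpha_remove = alpha_remove),
            class = "stepwise_path")
}

#' Predict NE for new samples from a prediction equation
#'
#' @param eq A [prediction_equation][new_prediction_equation] (fitted, from
#'   [ols_fit()]/[stepwise_select()], or published via
#'   [reference_ne_equations()]).
#' @param sample A named numeric vector, or a data frame with one column per
#'   predictor; every predictor in `eq` must be supplied.
#' @return Predicted NE, MJ/kg (vector of length `nrow(sample)` for data
#'   frames).
#' @export
#' @examples
#' eq <- reference_ne_equations()$eq1
#' predict_ne(eq, c(NDF = 9.56))
predict_ne <- function(eq, sample) {
  if (!inherits(eq, "prediction_equation"))
    stop("`eq` must be a prediction_equation", call. = FALSE)
  if (is.data.frame(sample)) {
    miss <- setdiff(eq$predictors, names(sample))
    if (length(miss))
      stop("sample lacks predictor(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    vals <- as.matrix(sample[, eq$predictors, drop = FALSE])
    return(drop(eq$intercept + vals %*% eq$coefficients[eq$predictors]))
  }
  miss <- setdiff(eq$predictors, names(sample))
  if (length(miss))
    stop("sample lacks predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  eq$intercept + sum(eq$coefficients[eq$predictors] * sample[eq$predictors])
}

#' @export
format.prediction_equation <- function(x, digits = 3, ...) {
  terms <- sprintf("%s %.*f %s",
                   ifelse(x$coefficients < 0, "-", "+"),
                   digits, abs(x$coefficients), x$predictors)
  rhs <- paste(terms, collapse = " ")
  rhs <- sub("^\\+ ", "", rhs)
  sprintf("NE = %s %s %.*f", rhs,
          ifelse(x$intercept < 0, "-", "+"), digits, abs(x$intercept))
}

#' @export
print.prediction_equation <- function(x, digits = 3, ...) {
  cat(format(x, digits = digits), "\n")
  cat(sprintf("  R-squared = %.3f   RSD = %.2f   n = %d", x$r_squared, x$rsd,
              x$n))
  if (is.finite(x$p_value %||% NA_real_))
    cat(sprintf("   p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
print.stepwise_path <- function(x, digits = 3, ...) {
  cat(sprintf("Stepwise selection (alpha enter %.2f / remove %.2f), %d step(s)\n",
              x$alpha_enter, x$alpha_remove, length(x$steps)))
  for (i in seq_along(x$steps)) {
    cat(sprintf("(%d) ", i))
    print(x$steps[[i]], digits = digits)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
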