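#' Repair a printed correlation matrix to the nearest positive-semidefinite one
#'
#' Pairwise correlation matrices transcribed from publications are frequently
#' indefinite, because each coefficient was computed pairwise (possibly on
#' slightly different samples) and then rounded. Sampling from such a matrix
#' is impossible, so the generator requires it to be repaired first. The
#' repair is Higham's alternating-projections algorithm (projection onto the
#' positive-semidefinite cone alternating with projection onto the
#' unit-diagonal set, with Dykstra's correction), as implemented by
#' [Matrix::nearPD()] with `corr = TRUE`.
#'
#' @param target Square symmetric numeric matrix with unit diagonal and
#'   entries in `[-1, 1]`.
#' @param tol Convergence tolerance of the alternating projections.
#' @return The repaired correlation matrix (same dimnames), with attributes
#'   `max_abs_change` (largest absolute elementwise change from the input)
#'   and `converged` (logical).
#' @seealso [wheat_correlation_target()] for the panel target this is
#'   typically applied to.
#' @export
#' @examples
#' r <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3, 3)
#' rep <- repair_correlation(r)
#' min(eigen(rep, symmetric = TRUE, only.values = TRUE)$values) # >= ~0
repair_correlation <- function(target, tol = 1e-8) {
  if (!is.matrix(target) || !is.numeric(target) || nrow(target) != ncol(target))
    stop("`target` must be a square numeric matrix", call. = FALSE)
  if (max(abs(target - t(target))) > 1e-12)
    stop("`target` must be symmetric", call. = FALSE)
  if (max(abs(diag(target) - 1)) > 1e-12)
    stop("`target` must have a unit diagonal", call. = FALSE)
  if (any(abs(target) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)

  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) {
    out <- target
    attr(out, "max_abs_change") <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  np <- Matrix::nearPD(target, corr = TRUE, conv.tol = tol,
                       maxit = 1000, do2eigen = TRUE)
  out <- as.matrix(np$mat)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(target)
  attr(out, "max_abs_change") <- max(abs(out - target))
  attr(out, "converged") <- np$converged
  out
}

# min eigenvalue check used by the generators
is_psd <- function(m, tol = 1e-8) {
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}
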