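# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: OLS by explicit normal equations, ANOVA via
# stats::anova(lm()), subset search by exhaustive enumeration.

# OLS by explicit normal-equations solve (small designs only)
ols_normal_equations <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slopes = beta[-1], sse = sse,
       r_squared = 1 - sse / sst)
}

# residual SD of every subset of candidate predictors
all_subsets_rsd <- function(panel, response, candidates) {
  subsets <- unlist(lapply(seq_along(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  n <- nrow(panel)
  data.frame(
    predictors = vapply(subsets, paste, "", collapse = "+"),
    rsd = vapply(subsets, function(s) {
      or <- ols_normal_equations(panel[[response]],
                                 panel[, s, drop = FALSE])
      sqrt(or$sse / (n - length(s) - 1))
    }, 0)
  )
}

# a tiny deterministic record for energy-balance unit tests; truth values
# chosen first, fields back-computed by the same arithmetic the module
# contract defines (intake from MEI, carcass energy from RE)
make_record <- function(mei, re, bw_i = 0.135, bw_f = 0.5, ame = 12.11,
                        ge = 15.8, period = 7, density = 6.0,
                        id = "r1", level = "L", diet = "basal") {
  w <- ((bw_i + bw_f) / 2)^0.75
  intake <- mei * period * w / ame
  data.frame(
    replicate_id = id, level = level, diet_id = diet, birds = 2L,
    period_d = period, feed_intake_kg = intake, diet_ge_mj_kg = ge,
    excreta_energy_mj = intake * (ge - ame), bw_initial_kg = bw_i,
    bw_final_kg = bw_f,
    carcass_energy_mj = density * bw_i + re * period * w,
    baseline_density_mj_kg = density, stringsAsFactors = FALSE
  )
}

# printed treatment-level feeding means used in several fits
level_means <- reference_feeding_levels()
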