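#' Moment targets for the 40-source wheat chemistry panel
#'
#' Per-variable means, coefficients of variation, standard deviations and
#' truncation bounds for the chemistry, physical and energy traits of the
#' wheat panel the synthetic generator emulates. Chemistry is expressed as %
#' of dry matter, bulk weight in g/L, gross energy (GE) in kJ/g, and apparent
#' metabolizable energy (AME) and net energy (NE) in MJ/kg air-dry grain.
#'
#' SDs are taken as printed where a table prints one (GE, AME, NE) and derived
#' as mean x CV/100 otherwise. Truncation bounds are the observed panel
#' minima/maxima; the ash range, which the source table prints identically to
#' the ether-extract range (an apparent duplication), is replaced by
#' mean +/- 3 SD.
#'
#' @return A data frame with columns `variable`, `mean`, `cv` (%), `sd`,
#'   `lower`, `upper`, `unit`.
#' @seealso [wheat_correlation_target()], [generate_wheat_panel()]
#' @export
#' @examples
#' wheat_chemistry_moments()
wheat_chemistry_moments <- function() {
  m <- data.frame(
    variable = c("Moisture", "EE", "CP", "CF", "Ash", "NDF", "ADF",
                 "BulkWeight", "GE", "AME", "NE"),
    mean  = c(12.02, 1.90, 14.46, 3.07, 1.76, 9.56, 2.58,
              775.30, 16.21, 13.15, 8.15),
    cv    = c(7.42, 12.90, 7.56, 8.77, 17.55, 11.54, 15.54,
              4.95, 1.16, 5.67, 6.40),
    sd    = NA_real_,
    lower = c(9.93, 1.31, 10.66, 2.65, NA, 6.80, 1.69,
              660.4, 15.71, 11.03, 6.81),
    upper = c(13.89, 3.29, 16.16, 3.73, NA, 12.15, 3.92,
              863, 16.54, 14.34, 9.12),
    unit  = c(rep("% DM", 7), "g/L", "kJ/g", "MJ/kg", "MJ/kg"),
    stringsAsFactors = FALSE
  )
  m$sd <- m$mean * m$cv / 100
  # printed SDs take precedence over CV-derived ones
  m$sd[m$variable == "GE"]  <- 0.19
  m$sd[m$variable == "AME"] <- 0.73
  m$sd[m$variable == "NE"]  <- 0.52
  ash <- m$variable == "Ash"
  m$lower[ash] <- m$mean[ash] - 3 * m$sd[ash]
  m$upper[ash] <- m$mean[ash] + 3 * m$sd[ash]
  m
}

#' Pearson correlation target for the wheat panel
#'
#' The pairwise Pearson correlation matrix over NE, AME and the conventional
#' composition traits of the wheat panel, used as the generative target of
#' [generate_wheat_panel()]. As printed, a pairwise correlation matrix need
#' not be positive semidefinite; pass it through [repair_correlation()]
#' before sampling from it.
#'
#' @return A 9 x 9 symmetric numeric matrix with unit diagonal and dimnames
#'   `NE, AME, CP, CF, NDF, ADF, EE, Ash, BulkWeight`.
#' @export
#' @examples
#' round(wheat_correlation_target()["NE", ], 3)
wheat_correlation_target <- function() {
  v <- c("NE", "AME", "CP", "CF", "NDF", "ADF", "EE", "Ash", "BulkWeight")
  r <- diag(1, 9)
  dimnames(r) <- list(v, v)
  vals <- list(
    NE  = c(AME = 0.883, CP = 0.097, CF = -0.398, NDF = -0.835, ADF = -0.676,
            EE = 0.432, Ash = -0.215, BulkWeight = 0.176),
    AME = c(CP = 0.090, CF = -0.467, NDF = -0.757, ADF = -0.540,
            EE = 0.530, Ash = -0.169, BulkWeight = 0.199),
    CP  = c(CF = -0.025, NDF = -0.044, ADF = -0.178, EE = 0.314,
            Ash = -0.411, BulkWeight = 0.142),
    CF  = c(NDF = 0.425, ADF = 0.403, EE = -0.184, Ash = 0.502,
            BulkWeight = -0.575),
    NDF = c(ADF = 0.569, EE = -0.349, Ash = 0.142, BulkWeight = -0.173),
    ADF = c(EE = 0.063, Ash = -0.218, BulkWeight = 0.063),
    EE  = c(Ash = -0.296, BulkWeight = 0.085),
    Ash = c(BulkWeight = -0.677)
  )
  for (a in names(vals)) {
    for (b in names(vals[[a]])) {
      r[a, b] <- vals[[a]][[b]]
      r[b, a] <- vals[[a]][[b]]
    }
  }
  r
}

#' Reference feeding-level energy balance (treatment means)
#'
#' Treatment-level means and SDs of metabolizable energy intake (MEI),
#' retained energy (RE) and heat production (HP), all in MJ/kg BW^0.75 per
#' day, for ducks fed ad libitum or restricted to 85%, 70%, 55% and 40% of
#' ad-libitum intake (i.e. feed restriction of 15-60%). These are the level
#' means the maintenance regression can be checked against, and the default
#' level targets of [generate_feeding_trial()].
#'
#' @return A data frame with one row per feeding level: `level` (label),
#'   `fraction` (of ad-libitum intake), `mei_mean`, `mei_sd`, `re_mean`,
#'   `re_sd`, `hp_mean`, `hp_sd`.
#' @export
#' @examples
#' reference_feeding_levels()
reference_feeding_levels <- function() {
  data.frame(
    level = c("ad_libitum", "restricted_15", "restricted_30",
              "restricted_45", "restricted_60"),
    fraction = c(1.00, 0.85, 0.70, 0.55, 0.40),
    mei_mean = c(2.10, 1.94, 1.67, 1.44, 1.17),
    mei_sd   = c(0.07, 0.03, 0.07, 0.09, 0.08),
    re_mean  = c(0.61, 0.51, 0.42, 0.33, 0.19),
    re_sd    = c(0.04, 0.03, 0.02, 0.01, 0.03),
    hp_mean  = c(1.51, 1.43, 1.25, 1.11, 0.98),
    hp_sd    = c(0.09, 0.05, 0.08, 0.09, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Reference NE prediction equations for wheat
#'
#' The five published stepwise prediction equations for wheat NE (MJ/kg):
#' the chemistry-only family built on NDF then ADF, and the AME family built
#' on AME then NDF then ADF. Each is returned as a [prediction_equation]
#' object carrying the published fit statistics, usable directly with
#' [predict_ne()].
#'
#' @return A named list of five `prediction_equation` objects, `eq1` ... `eq5`.
#' @export
#' @examples
#' predict_ne(reference_ne_equations()$eq5,
#'            c(AME = 13.15, NDF = 9.56, ADF = 2.58))
reference_ne_equations <- function() {
  eq <- function(coefs, intercept, r2, rsd) {
    new_prediction_equation(
      predictors = names(coefs), coefficients = coefs, intercept = intercept,
      r_squared = r2, rsd = rsd, p_value = NA_real_, n = 40L
    )
  }
  list(
    eq1 = eq(c(NDF = -0.394), 11.919, 0.698, 0.29),
    eq2 = eq(c(NDF = -0.315, ADF = -0.386), 12.151, 0.757, 0.26),
    eq3 = eq(c(AME = 0.629), -0.120, 0.780, 0.25),
    eq4 = eq(c(AME = 0.418, NDF = -0.184), 4.408, 0.845, 0.21),
    eq5 = eq(c(AME = 0.380, NDF = -0.147, ADF = -0.274), 5.262, 0.874, 0.19)
  )
}
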