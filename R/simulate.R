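#' Configuration for the synthetic wheat-panel generator
#'
#' @param n_samples Number of wheat sources to generate (>= 4).
#' @param seed Integer seed; every draw of the generator is reproducible
#'   given the seed.
#' @param ne_mode How NE is generated. `"structural"` (default) sets
#'   `NE = b_AME * AME + b_NDF * NDF + b_ADF * ADF + intercept + e` with
#'   `e ~ Normal(0, noise_sd^2)`, so that regression-recovery tests have a
#'   known truth; `"joint"` draws NE jointly with the other traits from the
#'   full correlation target.
#' @param noise_sd Residual SD of the structural NE equation, MJ/kg.
#' @param coefficients Named numeric vector of true structural slopes for
#'   `AME`, `NDF` and `ADF` (MJ/kg per unit predictor).
#' @param intercept True structural intercept, MJ/kg.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 40L, seed = 1L,
                             ne_mode = c("structural", "joint"),
                             noise_sd = 0.19,
                             coefficients = c(AME = 0.380, NDF = -0.147,
                                              ADF = -0.274),
                             intercept = 5.262) {
  ne_mode <- match.arg(ne_mode)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 4L)
    stop("`n_samples` must be at least 4", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(c("AME", "NDF", "ADF") %in% names(coefficients)))
    stop("`coefficients` must name AME, NDF and ADF", call. = FALSE)
  structure(
    list(n_samples = n_samples, seed = as.integer(seed), ne_mode = ne_mode,
         noise_sd = noise_sd,
         coefficients = coefficients[c("AME", "NDF", "ADF")],
         intercept = intercept),
    class = "generator_config"
  )
}

#' Design of the restricted-feeding maintenance trial
#'
#' Describes the multi-level feeding trial used to estimate fasting heat
#' production: birds are fed at a ladder of fractions of ad-libitum intake,
#' and heat production follows the log-linear model
#' `ln(HP) = ln_a + b * MEI` with multiplicative log-normal noise.
#'
#' @param levels Data frame with one row per feeding level: columns `level`
#'   (label), `fraction` (of ad-libitum intake, in (0, 1]), `mei_mean` and
#'   `mei_sd` (MJ/kg BW^0.75/d). Defaults to [reference_feeding_levels()].
#' @param replicates Replicate cages per level (>= 2).
#' @param birds Birds per replicate cage.
#' @param period_d Length of the formal balance period, days.
#' @param ln_a,b True log-linear heat-production parameters; `exp(ln_a)` is
#'   the fasting heat production in MJ/kg BW^0.75/d.
#' @param hp_sigma SD of the multiplicative (log-scale) heat-production
#'   noise; 0 gives a noise-free trial. The default 0.006 is calibrated to
#'   the ingredient arm of the workflow: the difference method at 20%
#'   inclusion amplifies diet-level noise fivefold, and this value keeps the
#'   per-source NE measurement error (~0.14 MJ/kg) below the residual SD of
#'   the published prediction equations (0.19 MJ/kg), which also absorbs
#'   lack of fit.
#' @param basal_ame,basal_ge AME and gross energy of the basal diet, MJ/kg
#'   air-dry feed.
#' @param bw_initial_mean,bw_initial_sd Initial body weight distribution, kg.
#' @param baseline_density Carcass energy density of the baseline slaughter
#'   group, MJ per kg live body weight; used to assign each bird's initial
#'   carcass energy.
#' @param re_floor Retained-energy floor (MJ/kg BW^0.75/d); generated records
#'   whose RE falls below it are flagged, not dropped.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(levels = reference_feeding_levels()[, c("level", "fraction",
                                                                 "mei_mean", "mei_sd")],
                         replicates = 5L, birds = 2L, period_d = 7L,
                         ln_a = -0.570, b = 0.4719, hp_sigma = 0.006,
                         basal_ame = 12.11, basal_ge = 15.8,
                         bw_initial_mean = 0.13486, bw_initial_sd = 0.00332,
                         baseline_density = 6.0, re_floor = -0.05) {
  stopifnot(is.data.frame(levels),
            all(c("level", "fraction", "mei_mean", "mei_sd") %in% names(levels)))
  if (any(levels$fraction <= 0 | levels$fraction > 1))
    stop("feeding-level fractions must lie in (0, 1]", call. = FALSE)
  if (replicates < 2L) stop("`replicates` must be >= 2", call. = FALSE)
  if (period_d < 1) stop("`period_d` must be >= 1 day", call. = FALSE)
  if (hp_sigma < 0) stop("`hp_sigma` must be >= 0", call. = FALSE)
  if (b <= 0)
    warning("slope `b` <= 0 is non-physiological: heat production should rise with intake")
  structure(
    list(levels = levels, replicates = as.integer(replicates),
         birds = as.integer(birds), period_d = period_d, ln_a = ln_a, b = b,
         hp_sigma = hp_sigma, basal_ame = basal_ame, basal_ge = basal_ge,
         bw_initial_mean = bw_initial_mean, bw_initial_sd = bw_initial_sd,
         baseline_density = baseline_density, re_floor = re_floor),
    class = "trial_design"
  )
}

# inverse-CDF draw from a truncated normal (exact, one uniform per value)
rtruncnorm_inv <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# correlated truncated normal draws via a Gaussian copula: a latent standard
# multivariate normal carries the target correlation, and each coordinate is
# mapped through the inverse CDF of its truncated-normal marginal. Marginals
# are exactly the prescribed truncated normals and the latent correlation
# survives the (monotone, near-linear) transform nearly unattenuated, unlike
# box rejection, which distorts the second moments badly.
rmvnorm_trunc <- function(n, mean, sd, corr, lower, upper) {
  p <- length(mean)
  es <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  fac <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p)
  z <- matrix(stats::rnorm(n * p), n, p) %*% t(fac)
  x <- vapply(seq_len(p), function(j) {
    plo <- stats::pnorm(lower[j], mean[j], sd[j])
    phi <- stats::pnorm(upper[j], mean[j], sd[j])
    stats::qnorm(plo + stats::pnorm(z[, j]) * (phi - plo), mean[j], sd[j])
  }, numeric(n))
  colnames(x) <- colnames(corr)
  x
}

#' Generate a synthetic wheat chemistry panel
#'
#' Draws `n_samples` wheat sources whose chemistry, bulk weight, gross energy
#' and AME follow a correlated truncated multivariate normal with the
#' prescribed first and second moments (a Gaussian copula carries the target
#' correlation across exact truncated-normal marginals), and whose NE is
#' either generated structurally from AME, NDF and ADF plus residual noise
#' (`ne_mode = "structural"`) or drawn jointly from the full correlation
#' target (`"joint"`). Moisture and GE carry no published correlations with
#' the other traits and are drawn as independent truncated normals.
#'
#' @param config A [generator_config()].
#' @param moments Moment table as returned by [wheat_chemistry_moments()].
#' @param target Correlation target over NE, AME and chemistry, already
#'   positive semidefinite (see [repair_correlation()]).
#' @return A data frame of one row per source with columns `source_id`,
#'   `Moisture`, `EE`, `CP`, `CF`, `Ash`, `NDF`, `ADF`, `BulkWeight`, `GE`,
#'   `AME`, `NE`, with the seed and NE mode in attributes `seed`/`ne_mode`.
#' @export
#' @examples
#' panel <- generate_wheat_panel(generator_config(n_samples = 40, seed = 7))
#' summary(panel$NE)
generate_wheat_panel <- function(config = generator_config(),
                                 moments = wheat_chemistry_moments(),
                                 target = repair_correlation(wheat_correlation_target())) {
  stopifnot(inherits(config, "generator_config"))
  need <- c("Moisture", "EE", "CP", "CF", "Ash", "NDF", "ADF",
            "BulkWeight", "GE", "AME")
  if (!all(need %in% moments$variable))
    stop("`moments` must cover: ", paste(need, collapse = ", "), call. = FALSE)
  if (!is_psd(target))
    stop("correlation target is not positive semidefinite; ",
         "run repair_correlation() on it first", call. = FALSE)
  bad <- with(moments, !(lower < mean & mean < upper))
  if (any(bad))
    stop("truncation bounds exclude the mean for: ",
         paste(moments$variable[bad], collapse = ", "), call. = FALSE)

  rownames(moments) <- moments$variable
  set.seed(config$seed)
  n <- config$n_samples

  corr_vars <- if (config$ne_mode == "joint")
    c("NE", "AME", "CP", "CF", "NDF", "ADF", "EE", "Ash", "BulkWeight")
  else c("AME", "CP", "CF", "NDF", "ADF", "EE", "Ash", "BulkWeight")
  if (!all(corr_vars %in% rownames(target)))
    stop("correlation target must have rows/cols: ",
         paste(corr_vars, collapse = ", "), call. = FALSE)
  sub <- target[corr_vars, corr_vars]
  mm <- moments[corr_vars, ]
  block <- rmvnorm_trunc(n, mm$mean, mm$sd, sub, mm$lower, mm$upper)

  indep <- lapply(c("Moisture", "GE"), function(v) {
    rtruncnorm_inv(n, moments[v, "mean"], moments[v, "sd"],
                   moments[v, "lower"], moments[v, "upper"])
  })
  names(indep) <- c("Moisture", "GE")

  panel <- data.frame(
    source_id = sprintf("W%02d", seq_len(n)),
    Moisture = indep$Moisture,
    EE = block[, "EE"], CP = block[, "CP"], CF = block[, "CF"],
    Ash = block[, "Ash"], NDF = block[, "NDF"], ADF = block[, "ADF"],
    BulkWeight = block[, "BulkWeight"], GE = indep$GE, AME = block[, "AME"],
    stringsAsFactors = FALSE
  )
  if (config$ne_mode == "structural") {
    co <- config$coefficients
    eps <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    panel$NE <- co[["AME"]] * panel$AME + co[["NDF"]] * panel$NDF +
      co[["ADF"]] * panel$ADF + config$intercept + eps
  } else {
    panel$NE <- block[, "NE"]
  }
  attr(panel, "seed") <- config$seed
  attr(panel, "ne_mode") <- config$ne_mode
  panel
}

# shared record back-computation: given per-replicate truth (mei, re, hp)
# and weights, emit a trial record that compute_balance() inverts exactly
build_records <- function(level, diet_id, rep_id, mei, re, hp, bw_i, bw_f,
                          diet_ame, diet_ge, design) {
  w <- ((bw_i + bw_f) / 2)^0.75
  period <- design$period_d
  intake <- mei * period * w / diet_ame
  excreta <- intake * (diet_ge - diet_ame)
  carcass <- design$baseline_density * bw_i + re * period * w
  data.frame(
    replicate_id = paste(diet_id, level, rep_id, sep = "_"),
    level = level, diet_id = diet_id, birds = design$birds,
    period_d = period, feed_intake_kg = intake, diet_ge_mj_kg = diet_ge,
    excreta_energy_mj = excreta, bw_initial_kg = bw_i, bw_final_kg = bw_f,
    carcass_energy_mj = carcass,
    baseline_density_mj_kg = design$baseline_density,
    flagged = re < design$re_floor,
    true_mei = mei, true_re = re, true_hp = hp,
    stringsAsFactors = FALSE
  )
}

#' Generate a restricted-feeding maintenance trial
#'
#' Simulates the multi-level feeding trial behind the fasting-heat-production
#' regression. Each replicate's MEI is drawn about its level mean, HP follows
#' `HP = exp(ln_a + b * MEI) * exp(eta)` with `eta ~ Normal(0, hp_sigma^2)`,
#' and RE is the balance `MEI - HP`. Feed intake, excreta energy and carcass
#' energies are then back-computed so that [compute_balance()] recovers
#' exactly these MEI/RE/HP values — the generated records are
#' self-consistent under the energy-balance arithmetic.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed.
#' @return A data frame of per-replicate trial records (one row per replicate
#'   cage) with the record fields consumed by [compute_balance()] plus
#'   `true_mei`, `true_re`, `true_hp` columns holding the generating values.
#' @export
#' @examples
#' trial <- generate_feeding_trial(trial_design(hp_sigma = 0), seed = 1)
#' head(trial)
generate_feeding_trial <- function(design = trial_design(), seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(seed)
  out <- lapply(seq_len(nrow(design$levels)), function(i) {
    lv <- design$levels[i, ]
    k <- design$replicates
    mei <- stats::rnorm(k, lv$mei_mean, lv$mei_sd)
    eta <- if (design$hp_sigma > 0) stats::rnorm(k, 0, design$hp_sigma) else rep(0, k)
    hp <- exp(design$ln_a + design$b * mei) * exp(eta)
    re <- mei - hp
    bw_i <- rtruncnorm_inv(k, design$bw_initial_mean, design$bw_initial_sd,
                           0.5 * design$bw_initial_mean,
                           1.5 * design$bw_initial_mean)
    bw_f <- bw_i * (1 + 2.5 * lv$fraction)
    build_records(lv$level, "basal", seq_len(k), mei, re, hp, bw_i, bw_f,
                  design$basal_ame, design$basal_ge, design)
  })
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  attr(rec, "seed") <- as.integer(seed)
  rec
}

#' Generate an ad-libitum substitution trial for a wheat panel
#'
#' Builds the test-diet arm of the study: a basal diet plus one diet per
#' wheat source in which the ingredient replaces a fixed fraction of the
#' basal diet. Each test diet's true energy values are the inclusion-weighted
#' mixtures `(1 - inclusion) * basal + inclusion * wheat` of AME, NE and GE.
#' Replicates are fed ad libitum; retained energy is set so the diet supplies
#' its true NE (`RE = NE_diet * intake - FHP`), heat production absorbs
#' multiplicative noise, and records are back-computed to be self-consistent
#' under [compute_balance()], so the downstream difference-method pipeline
#' recovers each wheat source's NE.
#'
#' @param panel Wheat panel from [generate_wheat_panel()] (columns
#'   `source_id`, `GE`, `AME`, `NE`).
#' @param design A [trial_design()]; its ad-libitum level sets the intake
#'   distribution and `exp(ln_a)` is the fasting heat production used for
#'   the maintenance share.
#' @param basal_ne True NE of the basal diet, MJ/kg.
#' @param inclusion Ingredient inclusion fraction, in (0, 1].
#' @param seed Integer seed.
#' @return A data frame of per-replicate trial records for the basal diet and
#'   every test diet, with truth columns `true_mei`, `true_re`, `true_hp`,
#'   `true_diet_ne`, `true_diet_ame`, `true_wheat_ne`.
#' @export
generate_substitution_trial <- function(panel, design = trial_design(),
                                        basal_ne = 7.0, inclusion = 0.2,
                                        seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.data.frame(panel) || nrow(panel) < 1L)
    stop("`panel` must be a nonempty data frame", call. = FALSE)
  if (!is.numeric(inclusion) || length(inclusion) != 1L ||
      inclusion <= 0 || inclusion > 1)
    stop("`inclusion` must lie in (0, 1]", call. = FALSE)
  set.seed(seed)

  adlib <- design$levels[design$levels$fraction == 1, ]
  if (nrow(adlib) != 1L)
    stop("`design$levels` must contain exactly one ad-libitum (fraction 1) level",
         call. = FALSE)
  intake_mean <- adlib$mei_mean / design$basal_ame   # kg feed / kg BW^0.75 / d
  intake_sd <- adlib$mei_sd / design$basal_ame
  fhp <- exp(design$ln_a)

  diets <- data.frame(
    diet_id = c("basal", panel$source_id),
    ame = c(design$basal_ame,
            (1 - inclusion) * design$basal_ame + inclusion * panel$AME),
    ne = c(basal_ne, (1 - inclusion) * basal_ne + inclusion * panel$NE),
    ge = c(design$basal_ge,
           (1 - inclusion) * design$basal_ge + inclusion * panel$GE),
    wheat_ne = c(NA_real_, panel$NE),
    stringsAsFactors = FALSE
  )

  out <- lapply(seq_len(nrow(diets)), function(i) {
    d <- diets[i, ]
    k <- design$replicates
    intake_met <- rtruncnorm_inv(k, intake_mean, max(intake_sd, 1e-12),
                                 0.5 * intake_mean, 1.5 * intake_mean)
    mei <- d$ame * intake_met
    re_target <- d$ne * intake_met - fhp
    hp_target <- mei - re_target
    eta <- if (design$hp_sigma > 0) stats::rnorm(k, 0, design$hp_sigma) else rep(0, k)
    hp <- hp_target * exp(eta)
    re <- mei - hp
    bw_i <- rtruncnorm_inv(k, design$bw_initial_mean, design$bw_initial_sd,
                           0.5 * design$bw_initial_mean,
                           1.5 * design$bw_initial_mean)
    bw_f <- bw_i * (1 + 2.5)
    rec <- build_records("ad_libitum", d$diet_id, seq_len(k), mei, re, hp,
                         bw_i, bw_f, d$ame, d$ge, design)
    rec$true_diet_ne <- d$ne
    rec$true_diet_ame <- d$ame
    rec$true_wheat_ne <- d$wheat_ne
    rec
  })
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  attr(rec, "seed") <- as.integer(seed)
  attr(rec, "inclusion") <- inclusion
  attr(rec, "basal_ne") <- basal_ne
  rec
}
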