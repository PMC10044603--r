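#' Metabolic body weight
#'
#' Metabolic weight is the scaling base for maintenance energy in birds and
#' mammals: live weight raised to the 0.75 power. Over a balance period the
#' arithmetic mean of initial and final live weight is used.
#'
#' @param bw_initial,bw_final Live body weights at the start and end of the
#'   balance period, kg. Vectorized.
#' @return Metabolic weight, kg^0.75.
#' @export
#' @examples
#' metabolic_weight(16, 16)   # 8
#' metabolic_weight(0.135, 0.5)
metabolic_weight <- function(bw_initial, bw_final) {
  if (any(bw_initial <= 0) || any(bw_final <= 0))
    stop("body weights must be positive", call. = FALSE)
  ((bw_initial + bw_final) / 2)^0.75
}

#' Apparent metabolizable energy of a diet by total excreta collection
#'
#' Classical apparent ME: gross energy consumed minus gross energy excreted,
#' per kg of air-dry feed, with no nitrogen correction.
#'
#' @param feed_intake Feed consumed over the period, kg air-dry.
#' @param diet_ge Gross energy of the diet, MJ/kg.
#' @param excreta_energy Total gross energy of excreta over the period, MJ.
#' @return AME, MJ/kg air-dry feed. Vectorized.
#' @export
#' @examples
#' compute_ame(0.70, 16.0, 2.24)  # 12.80
compute_ame <- function(feed_intake, diet_ge, excreta_energy) {
  if (any(feed_intake <= 0))
    stop("`feed_intake` must be positive", call. = FALSE)
  gross <- feed_intake * diet_ge
  if (any(excreta_energy > gross + 1e-9))
    stop("excreta energy exceeds gross energy intake (mass-balance violation)",
         call. = FALSE)
  (gross - excreta_energy) / feed_intake
}

#' Energy balance of trial records
#'
#' Converts per-replicate comparative-slaughter records into the three
#' energy-balance quantities, each expressed per kg metabolic body weight
#' per day:
#' \describe{
#'   \item{MEI}{metabolizable energy intake, `AME * intake / (period * W)`;}
#'   \item{RE}{retained energy, the gain in whole-carcass energy
#'     `(final - initial) / (period * W)`, where each bird's initial carcass
#'     energy is its initial weight times the baseline slaughter group's
#'     energy density;}
#'   \item{HP}{heat production, defined as `MEI - RE`.}
#' }
#' `W` is [metabolic_weight()]. Records with negative HP are physiologically
#' suspect and are flagged (`hp_negative`), never silently dropped.
#'
#' @param records Data frame of trial records with columns `feed_intake_kg`,
#'   `diet_ge_mj_kg`, `excreta_energy_mj`, `bw_initial_kg`, `bw_final_kg`,
#'   `carcass_energy_mj`, `baseline_density_mj_kg`, `period_d`, plus any id
#'   columns (carried through).
#' @return A data frame with one row per record: id columns (`replicate_id`,
#'   `level`, `diet_id` when present), `metabolic_wt` (kg^0.75), `intake_met`
#'   (kg feed per kg BW^0.75 per day), `ame` (MJ/kg), `mei`, `re`, `hp`
#'   (MJ/kg BW^0.75/d) and `hp_negative`.
#' @export
compute_balance <- function(records) {
  need <- c("feed_intake_kg", "diet_ge_mj_kg", "excreta_energy_mj",
            "bw_initial_kg", "bw_final_kg", "carcass_energy_mj",
            "baseline_density_mj_kg", "period_d")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(records$period_d < 1))
    stop("`period_d` must be >= 1", call. = FALSE)

  w <- metabolic_weight(records$bw_initial_kg, records$bw_final_kg)
  ame <- compute_ame(records$feed_intake_kg, records$diet_ge_mj_kg,
                     records$excreta_energy_mj)
  denom <- records$period_d * w
  mei <- ame * records$feed_intake_kg / denom
  e_init <- records$baseline_density_mj_kg * records$bw_initial_kg
  re <- (records$carcass_energy_mj - e_init) / denom
  hp <- mei - re

  ids <- intersect(c("replicate_id", "level", "diet_id"), names(records))
  out <- cbind(
    records[, ids, drop = FALSE],
    data.frame(metabolic_wt = w,
               intake_met = records$feed_intake_kg / denom,
               ame = ame, mei = mei, re = re, hp = hp,
               hp_negative = hp < 0)
  )
  rownames(out) <- NULL
  out
}

#' Ingredient AME by the difference (substitution) method
#'
#' Removes the basal diet's contribution from a test diet's AME:
#' `(ame_test - (1 - inclusion) * ame_basal) / inclusion`.
#'
#' @param ame_test,ame_basal AME of the test and basal diets, MJ/kg.
#' @param inclusion Ingredient inclusion fraction, in (0, 1].
#' @return Ingredient AME, MJ/kg. Vectorized over the diet values.
#' @export
#' @examples
#' ame_by_difference(12.90, 12.80, 0.2)  # 13.30
ame_by_difference <- function(ame_test, ame_basal, inclusion) {
  ingredient_by_difference(ame_test, ame_basal, inclusion)
}

#' Summarize energy balance by feeding level
#'
#' Per-level means and SDs of MEI, RE and HP, with a one-way ANOVA across
#' levels for each quantity. The ANOVA is computed from explicit between- and
#' within-level sums of squares; the degenerate case of zero between-level
#' variation is reported as F = 0, p = 1. Levels with a single replicate have
#' no SD and are excluded from the ANOVA with a warning.
#'
#' @param balances Output of [compute_balance()] with a `level` column; at
#'   least 2 levels with >= 2 replicates each.
#' @param quantities Character vector of balance columns to summarize.
#' @return A list of class `level_summary`: `summary` (data frame of per-level
#'   n/mean/sd per quantity) and `anova` (data frame per quantity with
#'   `df_between`, `df_within`, `F`, `p`).
#' @export
summarize_by_level <- function(balances, quantities = c("mei", "re", "hp")) {
  if (!"level" %in% names(balances))
    stop("`balances` must have a `level` column", call. = FALSE)
  counts <- table(balances$level)
  singles <- names(counts)[counts < 2]
  if (length(singles)) {
    warning("levels with a single replicate excluded from ANOVA: ",
            paste(singles, collapse = ", "))
  }
  keep_levels <- names(counts)[counts >= 2]
  if (length(keep_levels) < 2)
    stop("need at least 2 levels with >= 2 replicates each", call. = FALSE)

  summ <- do.call(rbind, lapply(quantities, function(q) {
    agg <- do.call(rbind, lapply(names(counts), function(lv) {
      x <- balances[[q]][balances$level == lv]
      data.frame(quantity = q, level = lv, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    agg
  }))
  rownames(summ) <- NULL

  anov <- do.call(rbind, lapply(quantities, function(q) {
    sub <- balances[balances$level %in% keep_levels, ]
    x <- sub[[q]]
    g <- factor(sub$level)
    grand <- mean(x)
    ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
    dfb <- nlevels(g) - 1L
    dfw <- length(x) - nlevels(g)
    if (ssb <= 0) {
      f <- 0; p <- 1
    } else if (ssw <= 0) {
      f <- Inf; p <- 0
    } else {
      f <- (ssb / dfb) / (ssw / dfw)
      p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
    }
    data.frame(quantity = q, df_between = dfb, df_within = dfw, F = f, p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(anov) <- NULL
  structure(list(summary = summ, anova = anov), class = "level_summary")
}

#' @export
print.level_summary <- function(x, digits = 3, ...) {
  cat("Energy balance by feeding level\n\n")
  print(x$summary, digits = digits, row.names = FALSE)
  cat("\nOne-way ANOVA across levels\n")
  print(x$anova, digits = digits, row.names = FALSE)
  invisible(x)
}
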