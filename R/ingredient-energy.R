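#' Diet NE concentration from the factorial NEm + NEp split
#'
#' A diet's net energy concentration is assembled from the two factorial
#' components, each divided by feed intake per kg metabolic weight per day:
#' the maintenance share (fasting heat production covered by the diet) and
#' the production share (retained energy).
#'
#' @param fhp Fasting heat production, MJ/kg BW^0.75/d.
#' @param re Retained energy, MJ/kg BW^0.75/d. Vectorized.
#' @param intake_met Feed intake per kg metabolic weight per day,
#'   kg/kg BW^0.75/d.
#' @return A data frame with columns `ne_m`, `ne_p` and `ne` (their sum),
#'   all MJ/kg feed.
#' @export
#' @examples
#' diet_ne_concentration(0.566, 0.51, 0.130)  # NE = 8.277 MJ/kg
diet_ne_concentration <- function(fhp, re, intake_met) {
  if (any(intake_met <= 0))
    stop("`intake_met` must be positive", call. = FALSE)
  ne_m <- fhp / intake_met
  ne_p <- re / intake_met
  data.frame(ne_m = ne_m, ne_p = ne_p, ne = ne_m + ne_p)
}

#' Ingredient energy value by the difference (substitution) method
#'
#' Removes the basal diet's contribution from a mixed test diet:
#' `(v_test - (1 - inclusion) * v_basal) / inclusion`. The same formula
#' applies to NE, NEm, NEp and AME, and is the exact inverse of the mixture
#' `v_test = (1 - inclusion) * v_basal + inclusion * v_ingredient`.
#'
#' @param v_test,v_basal Energy value of the test and basal diets, MJ/kg.
#' @param inclusion Ingredient inclusion fraction, in (0, 1].
#' @return Ingredient energy value, MJ/kg. Vectorized over diet values.
#' @export
#' @examples
#' ingredient_by_difference(8.30, 8.20, 0.2)  # 8.70
ingredient_by_difference <- function(v_test, v_basal, inclusion) {
  if (!is.numeric(inclusion) || length(inclusion) != 1L ||
      inclusion <= 0 || inclusion > 1)
    stop("`inclusion` must lie in (0, 1]", call. = FALSE)
  (v_test - (1 - inclusion) * v_basal) / inclusion
}

#' Conversion efficiency of AME to NE
#'
#' @param ne Net energy, MJ/kg.
#' @param ame Apparent metabolizable energy, MJ/kg; must be positive.
#' @return `100 * ne / ame`, percent. Vectorized.
#' @export
#' @examples
#' efficiency(8.15, 13.15)  # ~62
efficiency <- function(ne, ame) {
  if (any(ame <= 0)) stop("`ame` must be positive", call. = FALSE)
  100 * ne / ame
}

#' Evaluate ingredient energy values from a substitution trial
#'
#' The full difference-method pipeline: per-replicate energy balances are
#' turned into diet NE concentrations (maintenance share `FHP / intake` plus
#' production share `RE / intake`), replicates are averaged per diet, and the
#' basal diet's contribution is removed at the stated inclusion to give each
#' ingredient source's AME, NEm, NEp, NE and NE:AME efficiency per kg
#' air-dry ingredient.
#'
#' @param balances Output of [compute_balance()] on the substitution-trial
#'   records; must carry `diet_id` with one basal diet and one diet per
#'   source.
#' @param fit A [fit_lnhp_regression()] maintenance fit (source of FHP).
#' @param inclusion Ingredient inclusion fraction, in (0, 1].
#' @param basal_id `diet_id` value identifying the basal diet.
#' @param ge Optional named numeric vector of ingredient gross energies
#'   (kJ/g), names matching diet ids, carried into the output.
#' @return A data frame with one row per ingredient source: `source_id`,
#'   `GE` (if supplied), `AME`, `NEm`, `NEp`, `NE` (MJ/kg) and `NE_over_AME`
#'   (%), with the basal diet's values in attribute `basal`.
#' @export
evaluate_ingredients <- function(balances, fit, inclusion = 0.2,
                                 basal_id = "basal", ge = NULL) {
  if (!inherits(fit, "maintenance_fit"))
    stop("`fit` must be a maintenance_fit", call. = FALSE)
  if (!"diet_id" %in% names(balances))
    stop("`balances` must carry a `diet_id` column", call. = FALSE)
  if (!basal_id %in% balances$diet_id)
    stop("basal diet `", basal_id, "` not found in balances", call. = FALSE)

  fhp <- fit$fhp
  comp <- diet_ne_concentration(fhp, balances$re, balances$intake_met)
  per_rep <- cbind(balances[, c("diet_id", "ame")], comp)

  agg <- stats::aggregate(per_rep[, c("ame", "ne_m", "ne_p", "ne")],
                          by = list(diet_id = per_rep$diet_id), FUN = mean)
  basal <- agg[agg$diet_id == basal_id, ]
  tests <- agg[agg$diet_id != basal_id, ]

  out <- data.frame(
    source_id = tests$diet_id,
    AME = ingredient_by_difference(tests$ame, basal$ame, inclusion),
    NEm = ingredient_by_difference(tests$ne_m, basal$ne_m, inclusion),
    NEp = ingredient_by_difference(tests$ne_p, basal$ne_p, inclusion),
    NE  = ingredient_by_difference(tests$ne, basal$ne, inclusion),
    stringsAsFactors = FALSE
  )
  out$NE_over_AME <- efficiency(out$NE, out$AME)
  if (!is.null(ge)) {
    out <- cbind(out[, "source_id", drop = FALSE],
                 GE = unname(ge[out$source_id]),
                 out[, setdiff(names(out), "source_id")])
  }
  rownames(out) <- NULL
  attr(out, "basal") <- basal
  attr(out, "inclusion") <- inclusion
  out
}

#' Panel summary statistics
#'
#' Mean, sample SD, coefficient of variation and range of each energy or
#' chemistry quantity over an ingredient panel.
#'
#' @param results Data frame of per-source values (e.g. from
#'   [evaluate_ingredients()] or [generate_wheat_panel()]).
#' @param quantities Columns to summarize; default every numeric column.
#' @return Data frame with columns `quantity`, `mean`, `sd`, `cv` (%),
#'   `lowest`, `highest`.
#' @export
summarize_panel <- function(results, quantities = NULL) {
  if (is.null(quantities))
    quantities <- names(results)[vapply(results, is.numeric, logical(1))]
  if (nrow(results) < 2)
    stop("need at least 2 sources to summarize a panel", call. = FALSE)
  out <- do.call(rbind, lapply(quantities, function(q) {
    x <- results[[q]]
    data.frame(quantity = q, mean = mean(x), sd = stats::sd(x),
               cv = 100 * stats::sd(x) / mean(x),
               lowest = min(x), highest = max(x), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
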