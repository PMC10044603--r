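---
title: "Methods: the comparative-slaughter net-energy workflow in duckNE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the comparative-slaughter net-energy workflow in duckNE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckNE)
```

# The model

## Energy balance

For each replicate cage over a balance period of `period_d` days, with mean
metabolic weight $W = ((BW_i + BW_f)/2)^{0.75}$ (kg$^{0.75}$):

$$\mathrm{AME} = \frac{I \cdot GE_d - E_x}{I}, \qquad
  \mathrm{MEI} = \frac{\mathrm{AME} \cdot I}{t\,W}, \qquad
  \mathrm{RE} = \frac{C_f - \rho_0 BW_i}{t\,W}, \qquad
  \mathrm{HP} = \mathrm{MEI} - \mathrm{RE},$$

where $I$ is air-dry feed intake (kg), $GE_d$ the diet gross energy (MJ/kg),
$E_x$ the total excreta gross energy (MJ), $C_f$ the final carcass energy
(MJ), and $\rho_0$ the carcass energy density (MJ/kg live weight) of a
baseline group slaughtered at the start, which supplies each bird's initial
carcass energy. MEI, RE and HP are in MJ/kg BW$^{0.75}$/d. `HP = MEI - RE`
is an identity of the accounting, so it holds to machine precision on every
record (tested); negative HP is flagged, never dropped.

Assumptions worth naming:

* **AME, not AMEn.** Apparent ME by total excreta collection, per kg air-dry
  feed, with no nitrogen correction. The workflow reports AME throughout; a
  nitrogen-corrected variant is out of scope.
* **Metabolic weight** uses the arithmetic mean of initial and final live
  weight before the 0.75 power. For short balance periods the difference
  from other conventions (geometric mean, final weight) is well below the
  other error sources.
* **RE sign** is final minus initial carcass energy: restricted birds retain
  less, as the feeding-level ladder must show.

## Maintenance by extrapolation to zero intake

Across feeding levels (ad libitum and 85/70/55/40% of ad libitum), heat
production follows the semi-log model

$$\ln \mathrm{HP} = \ln a + b \cdot \mathrm{MEI},$$

fitted by OLS with `ln(HP)` linear in *untransformed* MEI (not log–log). The
exponential form matters: extrapolating a straight line in HP to zero intake
underestimates fasting heat production, because HP falls off exponentially as
intake is withdrawn. At MEI $= 0$, $\mathrm{FHP} = e^{\ln a}$
(MJ/kg BW$^{0.75}$/d), equated with the maintenance requirement NEm and
reported in kJ (`nem_kj = 1000 * fhp`). Published accounts of this quantity
sometimes print "MJ" for what is dimensionally kJ (HP itself is of order 1
MJ/kg BW$^{0.75}$/d, so FHP cannot be 566 MJ); the fit object carries both
fields explicitly so units are never guessed downstream.

The default fit uses replicate-level points (5 levels × 5 replicates = 25
records), which matches the degrees of freedom of a replicate-level
analysis; fitting the 5 treatment means instead is supported (it is just
`fit_lnhp_regression(lv$mei_mean, lv$hp_mean)`) and agrees with the
replicate-level parameters to about 1–2%, which is the agreement the
acceptance checks assert.

## Diet and ingredient NE

A diet's NE concentration is assembled factorially from a maintenance and a
production share, each divided by feed intake per kg metabolic weight per
day ($i = I/(t\,W)$, kg/kg BW$^{0.75}$/d):

$$\mathrm{NE}_{diet} = \underbrace{\mathrm{FHP}/i}_{\mathrm{NEm}} +
  \underbrace{\mathrm{RE}/i}_{\mathrm{NEp}},$$

so additivity `NE = NEm + NEp` is exact by construction. The maintenance
apportioning step (FHP divided by intake per metabolic kg) is the only
arithmetic consistent with reporting a per-kg-feed NEm column, even though
energy-balance papers rarely write it out.

The ingredient value comes from the **difference (substitution) method** at
inclusion $\pi$ (default 0.20):

$$v_{ingredient} = \frac{v_{test} - (1 - \pi)\,v_{basal}}{\pi},$$

applied identically to NE, NEm, NEp and AME. This is the exact inverse of
the mixture $v_{test} = (1-\pi) v_{basal} + \pi\, v_{ingredient}$ for every
$\pi \in (0, 1]$ (property-tested). Replicates are averaged per diet
*before* the difference step; since the basal diet is shared, the estimator
is identical in expectation to differencing per replicate, and it matches
how replicated diets are summarized in practice. Note the $1/\pi$
amplification: at 20% inclusion every error in a diet-level value is
multiplied by 5 in the ingredient value. This drives the noise calibration
below.

## Prediction equations

Correlation screening uses pairwise Pearson $r$ with t-based two-sided
p-values and the conventional stars (\*, \*\* at 0.05, 0.01). Equation
building is **classical stepwise OLS with partial-F tests**, the procedure
behind published feed-evaluation tables (and the default of the SPSS
workflow such tables typically come from): at each step the candidate with
the smallest p-to-enter joins if $p < \alpha_{enter}$, then any included
predictor with p-to-remove $> \alpha_{remove}$ is dropped. Defaults
$\alpha_{enter} = 0.05$, $\alpha_{remove} = 0.10$, both configurable. Ties
on p-to-enter break by larger partial F, then lexicographic name order, so
selection is deterministic. Entry-only ("forward") behavior is available by
setting $\alpha_{remove} = 1$; full stepwise is the default because removal
is the documented default of the procedure. The path returns the equation
after every completed step, mirroring how cumulative equation tables are
printed. Two candidate families reproduce the published table layout:
chemistry-only, and chemistry plus AME.

F-distribution p-values come from `stats::pf` (the regularized incomplete
beta function); no permutation alternative is offered. Rank-deficient
designs are an error naming the collinear columns. In tests, OLS is checked
against an explicit normal-equations solve to $10^{-10}$ and the stepwise
endpoint against an exhaustive all-subsets enumeration (the final model
attains the minimum RSD among the subsets on its path).

# The synthetic-data generator

## What it emulates

* A **40-source wheat chemistry panel**: moisture, EE, CP, CF, ash, NDF,
  ADF (% DM), bulk weight (g/L), GE (kJ/g) and AME (MJ/kg), with the
  published panel means, CVs/SDs, observed ranges, and the published 9×9
  Pearson correlation structure among {NE, AME, chemistry}.
* A **five-level restricted-feeding trial** (5 replicates × 2 birds, 7-day
  period) whose HP follows $\exp(\ln a + b\,\mathrm{MEI})$ with
  multiplicative log-normal noise, defaults $\ln a = -0.570$, $b = 0.4719$.
* A **substitution trial**: one basal diet plus one test diet per source,
  each test diet an exact inclusion-weighted mixture of basal and wheat for
  AME, NE and GE.

All generators emit *records*, not balances: intake, excreta energy, body
weights and carcass energies are back-computed so that `compute_balance()`
inverts them exactly. The constants this back-computation needs but the
energy accounting cancels out (basal diet GE 15.8 MJ/kg, baseline carcass
energy density 6.0 MJ/kg live BW, a level-proportional growth model for
final body weight) were chosen once as realistic for corn–soybean diets and
1–2-week-old ducklings; no downstream energy quantity depends on them.

## Correlated truncated sampling

The printed correlation matrix, like most transcribed pairwise tables, is
not positive semidefinite. `repair_correlation()` projects it to the nearest
PSD correlation matrix by Higham's alternating-projections algorithm
(`Matrix::nearPD`, tolerance $10^{-8}$), reporting the largest elementwise
change; the generators refuse an unrepaired target.

Sampling uses a **Gaussian copula**: a latent standard MVN carries the
(repaired) target correlation, and each coordinate is mapped through the
inverse CDF of its truncated-normal marginal (bounds = the observed panel
ranges). This was a deliberate choice over joint box-rejection: rejection
truncation distorts second moments badly (pairwise correlations attenuate
by up to ~0.05 at these bounds), while the copula keeps exact truncated
marginals and systematic correlation attenuation below ~0.006 on every
pair. Truncation does shrink marginal SDs relative to the nominal
parameters (e.g. AME's effective SD is ~0.65 against the nominal 0.73);
means stay within 2% of target. The moment-recovery property is asserted at
n = 40000, where the sampling SE of a correlation (~0.005) no longer masks
systematic error; at n = 4000 the max deviation over 28 pairs is dominated
by sampling noise for any correct sampler.

Two bounds required judgment: the published EE and ash ranges are printed
identically (an apparent duplication), so the printed range is assigned to
EE and ash uses mean ± 3 SD; and where a table prints both an SD and a CV
that disagree slightly (AME: SD 0.73 vs CV-implied 0.746), the printed SD
wins.

## NE modes

`ne_mode = "structural"` (default) sets
$\mathrm{NE} = 0.380\,\mathrm{AME} - 0.147\,\mathrm{NDF} -
0.274\,\mathrm{ADF} + 5.262 + \varepsilon$, $\varepsilon \sim N(0,
0.19^2)$ — the published best-fit equation as generating truth, with its
residual SD as noise. Only this mode makes regression-recovery tests
meaningful (the refit has a known answer). `"joint"` instead draws NE as a
ninth correlated trait, useful when only the correlation structure matters.

## Noise calibration (and an honest tension)

`hp_sigma`, the log-scale SD of HP noise, defaults to **0.006**. Two
published anchors pull in different directions:

* the replicate-level maintenance fit ($R^2 = 0.9951$ over 25 points)
  implies a residual SD of ln HP around 0.012;
* the ingredient arm requires much less: through
  $\mathrm{NE}_{diet} = (\mathrm{FHP} + \mathrm{RE})/i$ and the fivefold
  difference-method amplification, $\sigma = 0.012$ would give a per-source
  NE recovery error around 0.22 MJ/kg — larger than the published
  three-predictor equation residual (RSD 0.19 MJ/kg), which is itself an
  *upper* bound on measurement error since it also absorbs lack of fit.

No single multiplicative HP noise reproduces both arms; the default favors
the ingredient arm (per-source recovery error SD ≈ 0.14 MJ/kg, mean
absolute error ≈ 0.11, kept < 0.15 by a 200-repeat Monte-Carlo test), and
the maintenance arm then fits slightly cleaner ($R^2 \approx 0.999$) than
the printed 0.995. `hp_sigma` is a single user-visible parameter, so either
arm can be emphasized. Within-level MEI SDs default to the published level
SDs (0.07, 0.03, 0.07, 0.09, 0.08 MJ/kg BW$^{0.75}$/d).

## What the generator does not emulate

No growth dynamics, mortality, temperature effects or digestion kinetics —
only the energy-accounting quantities the analysis touches. Body-weight and
intake trajectories are placeholders that cancel out of every energy value.
Consequently, passing tests demonstrate that the *estimators* are correct
and well calibrated under the stated statistical structure; they say
nothing about biological sources of error in a real trial (incomplete
excreta collection, carcass sampling error, diet mixing heterogeneity,
bird-to-bird variation beyond the modeled noise).

# Numerical and interface choices

* One-way ANOVA in `summarize_by_level()` is computed from explicit
  between/within sums of squares (checked against `anova(lm())` in tests);
  the all-identical degenerate case is defined as F = 0, p = 1, where
  `anova()` returns NaN. Levels with one replicate are excluded from the
  ANOVA with a warning, their SD reported as `NA`.
* Seeds: every generator takes an explicit integer seed and is bitwise
  reproducible; the pipeline derives stage seeds as `seed`, `seed + 1`,
  `seed + 2`.
* Stage CSVs carry `# seed:` and `# config_hash:` comment lines; numeric
  output is never rounded in CSVs, only in the rendered `report.txt`
  (default 2 decimals, matching how such tables are printed).
* Problem sizes in the test suite were chosen to keep the default run
  around 15–20 s: 200 Monte-Carlo repeats for the two calibration
  properties, 100 seeds for the stochastic recovery check, n = 40000 for
  the moment-recovery property.

# Known limitations

* The published per-source wheat values are not available, so the 40-source
  level of the analysis is validated by parameter-recovery properties, not
  by matching individual published rows.
* The recovered per-kg NEm of the synthetic ingredient (~3.3 MJ/kg at the
  default intake) sits somewhat above the published panel mean (2.91),
  because the ad-libitum intake implied by the published MEI and basal AME
  fixes the maintenance share; the published internal quantities are not
  perfectly mutually consistent and NE itself is unaffected.
* AME is apparent and nitrogen-uncorrected; no TME/AMEn pathway.
* The stepwise procedure is the classical partial-F one by design; no
  information criteria, cross-validation or shrinkage.
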