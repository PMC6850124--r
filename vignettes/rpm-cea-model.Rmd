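---
title: "The rpmsim model: structure, inputs and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rpmsim model: structure, inputs and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Recipients of implantable cardioverter-defibrillators (ICDs) face high
long-term rates of all-cause rehospitalization and death. Remote patient
monitoring (RPM) of the implanted device has been associated with delayed
rehospitalization and longer survival in the large PREDICT RM cohort of
Medicare-aged recipients, but the health-economic consequences play out
over a lifetime, far beyond any registry's follow-up. `rpmsim` implements
an individual-patient discrete-event microsimulation that extrapolates the
published PREDICT RM regression equations over a 25-year horizon and
compares RPM with conventional follow-up on life-years (LYs),
quality-adjusted life-years (QALYs), rehospitalization burden, costs and
the incremental cost-effectiveness ratio (ICER).

The engine is a condition/event simulation: persistent *conditions*
(baseline covariates, treatment arm, hospitalization history, accumulated
comorbidities) modulate the hazards of point-in-time *events*
(first rehospitalization, subsequent rehospitalizations, death), and
accruals (life-time, utility, costs, outpatient claims) run continuously
between events until death or the horizon.

## Event-time model

Both first rehospitalization and death follow Weibull
accelerated-failure-time (AFT) equations on the log-day scale:

$$\log T = \mu + \sigma W, \qquad
  S(t \mid \mu) = \exp\!\left[-\left(t/e^{\mu}\right)^{1/\sigma}\right],$$

with $\mu$ = intercept + covariate coefficients, $W$ a standard minimum
extreme-value variate, and Weibull shape $k = 1/\sigma$. The packaged
coefficient tables are the published PREDICT RM equations: intercepts
7.5446 (rehospitalization) and 9.976 (death), AFT scales 1.2024 and
0.9875, RPM coefficients +0.0968 and +0.1666, and a hospitalization-history
coefficient of -1.5451 in the mortality equation. Because the AFT is
multiplicative in event time, a coefficient $\beta$ scales every sampled
time by $e^{\beta}$ for the same underlying draw: the RPM terms correspond
to a ~10% extension of time to first rehospitalization
($e^{0.0968} = 1.1016$) and ~18% extension of survival
($e^{0.1666} = 1.1813$).

Event times are sampled by inverse survival, interpreting the uniform draw
$u$ as a survival probability: $T = e^{\mu}(-\log u)^{\sigma}$. The printed
scale/shape pairs satisfy $k = 1/\sigma$ to four decimals for both
endpoints, which is the parameterization assumed throughout.

**Time unit.** The sources never state the unit of the intercepts; days
are assumed. $e^{7.5446} \approx 1891$ days puts the all-reference
patient's median time to first rehospitalization at ~3.3 years, which is
clinically plausible for this population, and a day grid is natural for
claims-style accrual. Any other unit would only rescale the intercepts.

**The hospitalization effect on mortality.** Mortality depends on the
history of the first rehospitalization. How the original engine applied
this time-varying condition is not described; `rpmsim` uses the standard
discrete-event mechanism: at the first rehospitalization the remaining
death time is re-drawn from the updated equation
($\mu' = \mu + \beta_{\text{hosp}}$) *conditional on survival to the
rehospitalization time* via the left-truncated inverse CDF

$$T = e^{\mu'}\left[\left(t_0/e^{\mu'}\right)^{1/\sigma}
      - \log u\right]^{\sigma} > t_0 .$$

This preserves continuity of the survival function at the switch and
reduces to the unconditional draw at $t_0 = 0$. A dedicated uniform from
the patient's stream is used, shared across arms.

**Subsequent rehospitalizations** are a homogeneous Poisson process at the
published constant rates (1.79 per patient-year without RPM, 1.65 with),
running from the first rehospitalization until death or the horizon. The
count is drawn through the Poisson quantile function from a shared
uniform (so both arms move together) and event times are placed uniformly
in the window.

**Outpatient claims** (hospital outpatient/ASC and physician) accrue
deterministically as rate x time by phase (before/after first
rehospitalization), arm and type. Expectations are identical to sampling
individual claims, the reported quantities are means, and the
deterministic form cuts runtime enormously; claim counts are therefore
expected counts.

**Tie-break and horizon rules.** Death ties with any other event resolve
in favor of death; patients alive at 25 years are censored with no forced
terminal event; no accrual of any kind occurs after `min(t_death, H)`.

## Cloning and common random numbers

Each sampled patient is cloned into both arms. All structural draws
(first-rehospitalization survival draw, pre-hospitalization death draw,
conditional re-draw, subsequent-event count draw, per-event placement and
comorbidity draws) come from a counter-based uniform generator keyed by
`(master_seed, patient id, draw counter)`. Consequences:

* arm differences are pure parameter effects — for clones whose events
  precede the horizon, `t_rpm = t_no_rpm * exp(beta_RPM)` exactly;
* scenario runs reuse the base draws, so scenario-vs-base deltas are not
  confounded by sampling noise;
* results are reproducible bit-for-bit across platforms and independent of
  R's global RNG, and growing the cohort never reshuffles the draws of
  earlier patients;
* with every arm-specific input equalized and both RPM coefficients
  zeroed, the two arms are *identical*, a property the test suite asserts.

## The synthetic population

Patient-level PREDICT RM data are not public. The generator consumes the
published categorical marginals (25 covariates: demographics, NYHA class,
admission reason, heart-failure history, comorbidities, labs, QRS/
conduction, device type, site characteristics) and samples each covariate
independently. What this emulates and what it does not:

* Marginal prevalences match the published cohort (exact level counts are
  used where printed; a remainder level carrying the unprinted mass is
  added, with zero regression coefficient — "no" for binary risk factors,
  "(unreported)" otherwise, e.g. hospital teaching status where the
  printed rows cover only 55.4%).
* The *joint* distribution is not reproduced: no published correlation
  structure exists to consume. A patient with dialysis-dependent renal
  failure is as likely to have normal BUN as anyone else, which is
  epidemiologically wrong in detail. Absolute life expectancy therefore
  carries structural uncertainty (the linear predictor's spread is
  understated relative to a correlated population), which is why the
  absolute no-RPM life expectancy is checked to a +-10% band while the
  CRN-paired increments are checked tightly. User-supplied patient tables
  with realistic correlations drop in directly.
* Share-only user tables with sub-rounding shortfalls (< 2%) are
  renormalized; larger shortfalls become an explicit remainder level.

Risk strata are within-cohort quartiles of the predicted median times to
rehospitalization and death (baseline equations), quartile 1 = shortest
predicted time, giving the 4 x 4 death-by-rehospitalization grid used for
subgroup scenarios. The original stratification cutpoints were never
published, so stratum-level outputs are labelled approximate and only the
qualitative gradient (higher-risk strata, smaller incremental QALYs) is
claimed.

## Economics

Costs and benefits are discounted at 3% per year using the
annual-effective convention applied continuously,
$d(t) = 1.03^{-t/365.25}$, with closed-form interval accrual
$\int_{t_0}^{t_1} d(t)\,dt$; the discount rate, like every economic
input, is configurable.

The supplementary DRG cost mix, claim-rate and utility-coefficient tables
behind the original model were never published. The packaged defaults are
therefore **calibrated placeholders**, back-solved from the published
per-arm lifetime aggregates so that the no-RPM arm lands in the right
magnitude, and flagged as placeholders in the configuration:

| input | default | derivation |
|---|---|---|
| cost per rehospitalization | $5,483 / $5,383 (no-RPM / RPM) | lifetime rehospitalization cost / lifetime events |
| per-claim cost | $163.33 / $149.89 | lifetime nonhospital cost / lifetime claims |
| claim rates (PPY) | outpatient 8.25 / 9.08; physician 23.50 / 24.99 | lifetime type totals / undiscounted person-years; phases share one rate |
| length of stay | 5 days, both arms | placeholder (arm-specific values unpublished) |
| baseline utility | 0.825 | lifetime QALY / LY ratio |
| comorbidity decrement / probability | 0.02 / 0.25 per rehospitalization | placeholders exercising the mechanism |
| death cost | $0 (scenario hook: $11,000 synthetic DRG-like value) | unpublished |

Utility is zero during each hospital stay (stays are clipped at the next
event, death or the horizon, so overlapping stays never double-count), and
each rehospitalization adds a permanent additive utility decrement with
the configured probability. Whether the original decrements were additive
or multiplicative is unknown; additive is assumed. Switching both
mechanisms off makes QALYs equal LYs, which is how the utility-toggle
scenarios are implemented. Dollar-denominated outputs (including the ICER)
inherit the placeholder calibration and are not claimed as reproductions;
the reproduction surface is LYs, rehospitalization burden, and the
dominance directions of the scenario grid.

Per-patient-year metrics divide lifetime totals by mean *undiscounted*
person-years — the published table is internally consistent only under
that convention (10.4 events at 1.26 PPY implies ~8.25 undiscounted years
against 6.85 discounted LYs). Rehospitalization counts are reported
undiscounted; the count includes the first rehospitalization plus
subsequent events.

## Scenario engine and sensitivity analysis

Scenarios are data: a named list of typed edits (coefficient zeroing,
horizon truncation, covariate forcing, arm equalization of any
cost/rate/LoS input, utility-rule toggles, risk-stratum restriction,
dotted-path set/scale of any numeric input) applied to a deep copy of the
base inputs. The packaged battery mirrors the published grid (34 rows: 13
reported risk strata, 5 comorbidity forcings, 3 coefficient-zeroing rows,
3 horizons, 7 cost/resource equalizations, 3 utility toggles). One-way
sensitivity re-runs the analysis at x0.8 / x1.2 of each chosen parameter
under the base draws and orders parameters by ICER spread (tornado
ordering, ties alphabetical).

```{r scenario-demo}
library(rpmsim)
spec <- load_population_spec()
models <- load_aft_models(population = spec)
patients <- sample_patients(spec, 20000, seed = 1) |>
  assign_risk_strata(models$rehosp, models$death)
base <- list(
  models = models, econ = econ_inputs(),
  cfg = sim_config(master_seed = 1), patients = patients
)
run_scenarios(base, scenario_battery())
```

## Validation

`validate_engine()` replays the raw first-rehospitalization and
pre-hospitalization death draws for a configured cohort and compares the
empirical survival of the sampled times against the analytic
population-average Weibull survival at interior deciles. Inverse-CDF
sampling is exact, so any deviation is Monte-Carlo noise; the report
claims PASS only when the maximum absolute deviation is below 0.01 at a
cohort of 100,000 or more. The test suite additionally carries a negative
control in which the AFT scale is deliberately misapplied and the
deviation must blow up.

## Problem sizes and numerical tolerances

* The headline reproduction runs (and `scripts/acceptance.R`) use
  n = 100,000 patients, the scale at which binomial noise on a survival
  probability is ~0.003 and the decile deviation bound of 0.01 is
  comfortably Monte-Carlo-dominated; the full run takes well under a
  minute on one core.
* Unit and property tests use cohorts of 300–30,000, chosen so that each
  asserted difference exceeds three Monte-Carlo standard errors.
* Exact identities (survival/sampling round trip, CRN scaling,
  clone symmetry, ledger additivity) are asserted at 1e-10 to 1e-12;
  means of stochastic quantities at 3 standard errors; structural
  reproductions at the bands stated above.
* Uniform draws are generated strictly inside (0, 1) (53-bit mantissa,
  half-ulp offset), so `log(u)` and `(-log u)^sigma` are always finite.

## Known limitations

* Independence of baseline covariates (above) — the dominant structural
  approximation.
* Economic defaults are calibrated placeholders; absolute dollar outputs
  are configuration-dependent.
* All-cause death only; no decomposition into cardiovascular death, no
  device battery/replacement events, no probabilistic sensitivity
  analysis (the reproduced analyses are deterministic/one-way only).
* The risk stratification approximates unpublished cutpoints with
  within-cohort quartiles.
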