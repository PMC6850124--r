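# Shared fixtures: packaged inputs are loaded once; tiny synthetic models
# and economic inputs are built in code.

pkg_spec <- load_population_spec()
pkg_models <- load_aft_models(population = pkg_spec)

# Economic inputs with every cost, claim and utility mechanism switched off
# (utility 1 everywhere): QALYs equal LYs and costs are zero.
zero_econ <- function(discount_rate = 0.03, ...) {
  econ_inputs(
    discount_rate = discount_rate,
    cost_per_rehosp = c(no_rpm = 0, rpm = 0),
    death_cost = c(no_rpm = 0, rpm = 0),
    claim_rates = dplyr::mutate(rpmsim:::default_claim_rates(), rate = 0),
    claim_costs = dplyr::mutate(rpmsim:::default_claim_costs(), cost = 0),
    los_days = c(no_rpm = 0, rpm = 0),
    baseline_utility = 1,
    comorbidity_decrement = 0,
    comorbidity_prob = 0,
    ...
  )
}

# Minimal AFT model with no covariate coefficients.
flat_model <- function(endpoint = "rehosp", intercept = 7, scale = 1.2,
                       rpm_coefficient = 0, hosp_coefficient = NULL) {
  new_aft_model(
    endpoint = endpoint, intercept = intercept,
    coefficients = tibble::tibble(
      covariate = character(0), level = character(0), coefficient = numeric(0)
    ),
    rpm_coefficient = rpm_coefficient, hosp_coefficient = hosp_coefficient,
    scale = scale
  )
}

# Model pair whose event times are pushed far beyond / far before the
# horizon, for forcing degenerate event flows.
forced_models <- function(rehosp_intercept, death_intercept) {
  list(
    rehosp = flat_model("rehosp", intercept = rehosp_intercept, scale = 0.5),
    death = flat_model("death",
      intercept = death_intercept, scale = 0.5,
      hosp_coefficient = 0
    )
  )
}

# Hand-built one-row trajectory (pre-accrual shape) for ledger tests.
make_traj <- function(end_time, t_first = NA_real_, death = TRUE, u0 = 1,
                      arm = "no_rpm", id = 1L) {
  tibble::tibble(
    id = id, arm = arm, t_first_rehosp = t_first,
    end_time = end_time, death_observed = death, u0 = u0
  )
}

no_events <- function() {
  tibble::tibble(
    id = integer(0), arm = character(0), time = numeric(0), comorbid = logical(0)
  )
}
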