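make_base <- function(n = 600, seed = 19, strata = FALSE) {
  pts <- sample_patients(pkg_spec, n, seed = seed)
  if (strata) pts <- assign_risk_strata(pts, pkg_models$rehosp, pkg_models$death)
  list(
    models = pkg_models, econ = econ_inputs(),
    cfg = sim_config(master_seed = seed), patients = pts
  )
}

test_that("modifications edit a deep copy of the base inputs", {
  base <- make_base(n = 50)
  ref <- reference_patient(pkg_spec)

  mod <- apply_scenario(base, scenario("z", zero_coefficient("death", "rpm")))
  # RPM term removed from mortality only: rpm clone predicts the intercept
  expect_equal(linear_predictor(ref, mod$models$death, rpm = TRUE), 9.976)
  expect_equal(linear_predictor(ref, mod$models$rehosp, rpm = TRUE), 7.5446 + 0.0968)
  # base untouched
  expect_equal(base$models$death$rpm_coefficient, 0.1666)

  mod <- apply_scenario(base, scenario("h", set_horizon(2)))
  expect_equal(years_to_days(mod$cfg$horizon_years), 730.5)

  mod <- apply_scenario(base, scenario("f", force_covariate("af_flutter", "yes")))
  expect_true(all(mod$patients$af_flutter == "yes"))

  mod <- apply_scenario(base, scenario("e", equalize("subsequent_rehosp_rate")))
  expect_equal(unname(mod$cfg$subsequent_rehosp_rate[["rpm"]]), 1.79)

  mod <- apply_scenario(
    base,
    scenario("c", equalize("claim_costs", type = "outpatient"))
  )
  cc <- mod$econ$claim_costs
  expect_equal(
    cc$cost[cc$type == "outpatient" & cc$arm == "rpm"],
    cc$cost[cc$type == "outpatient" & cc$arm == "no_rpm"]
  )
  # other type untouched
  expect_equal(
    sort(unique(cc$cost[cc$type == "physician"])),
    sort(unique(econ_inputs()$claim_costs$cost[econ_inputs()$claim_costs$type == "physician"]))
  )

  mod <- apply_scenario(base, scenario("u", toggle_utility("no_zero_utility_in_hospital")))
  expect_false(mod$econ$utility_zero_in_hospital)

  mod <- apply_scenario(base, scenario("p", set_param("econ.death_cost", 11000)))
  expect_equal(unname(mod$econ$death_cost), c(11000, 11000))
  mod <- apply_scenario(base, scenario("s", scale_param("econ.cost_per_rehosp.rpm", 1.2)))
  expect_equal(
    unname(mod$econ$cost_per_rehosp[["rpm"]]),
    unname(base$econ$cost_per_rehosp[["rpm"]]) * 1.2
  )
  expect_error(
    apply_scenario(base, scenario("x", set_param("econ.warp_drive", 1))),
    "unknown parameter path"
  )
  expect_error(
    apply_scenario(base, scenario("x", zero_coefficient("death", "shoe_size"))),
    "no coefficient matches"
  )
})

test_that("an empty scenario reproduces the base case bit-for-bit", {
  base <- make_base(n = 300)
  direct <- run_cea(base$patients, base$models, base$econ, base$cfg)
  via <- run_scenarios(base, list(scenario("identity")))
  expect_identical(via$delta_qalys, direct$delta_qalys)
  expect_identical(via$delta_costs, direct$delta_costs)
  expect_identical(via$icer_per_qaly, direct$icer_per_qaly)
})

test_that("scenario batches survive per-row failures and honor strata", {
  base <- make_base(n = 400, strata = TRUE)
  tab <- run_scenarios(base, list(
    scenario("ok", set_horizon(5)),
    scenario("broken", set_param("econ.nonexistent", 1)),
    scenario("stratum", restrict_stratum(1, 1))
  ))
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$delta_qalys[tab$scenario == "broken"]))
  expect_match(tab$error[tab$scenario == "broken"], "unknown parameter path")
  expect_true(all(is.na(tab$error[tab$scenario != "broken"])))
  expect_lt(tab$n[tab$scenario == "stratum"], 400)

  expect_error(run_scenarios(base, list()), "no scenarios")
  expect_error(
    run_scenarios(base, list(scenario("a"), scenario("a"))),
    "unique"
  )
})

test_that("removing every arm difference nulls the increments", {
  base <- make_base(n = 1500)
  null_scen <- scenario(
    "null",
    zero_coefficient("rehosp", "rpm"), zero_coefficient("death", "rpm"),
    equalize("subsequent_rehosp_rate"), equalize("cost_per_rehosp"),
    equalize("claim_rates"), equalize("claim_costs"), equalize("los_days")
  )
  tab <- run_scenarios(base, list(null_scen))
  expect_equal(tab$delta_lys, 0, tolerance = 1e-12)
  expect_equal(tab$delta_costs, 0, tolerance = 1e-9)
  expect_lt(abs(tab$delta_qalys), 0.02) # comorbidity draws differ by event set
})

test_that("the packaged battery covers the published scenario grid", {
  batt <- scenario_battery()
  expect_gte(length(batt), 25)
  nms <- vapply(batt, function(s) s$name, character(1))
  expect_true(any(grepl("RPM coeff = 0, death", nms)))
  expect_true(any(grepl("Time horizon = 2", nms)))
  expect_true(any(grepl("stratum D4-R4", nms)))
  expect_false(anyDuplicated(nms) > 0)
})

test_that("one-way sweeps order parameters by ICER spread", {
  base <- make_base(n = 500)
  sweep <- one_way_sensitivity(
    base,
    parameters = c(
      "econ.cost_per_rehosp", "econ.discount_rate", "econ.death_cost"
    )
  )
  expect_equal(nrow(sweep), 3)
  expect_true(all(diff(sweep$spread) <= 0))
  # death_cost is zero: scaling it is a no-op on the ICER
  dc <- dplyr::filter(sweep, parameter == "econ.death_cost")
  expect_equal(dc$icer_low, dc$icer_high)
  # a costlier rehospitalization raises the incremental cost
  cp <- dplyr::filter(sweep, parameter == "econ.cost_per_rehosp")
  expect_gt(cp$delta_costs_high, cp$delta_costs_low)
})

test_that("discounted life-years move inversely to the discount rate", {
  base <- make_base(n = 400)
  runs <- lapply(c(0.8, 1.2), function(m) {
    mod <- apply_scenario(base, scenario("d", scale_param("econ.discount_rate", m)))
    r <- run_cea(mod$patients, mod$models, mod$econ, mod$cfg)
    r$arm_summaries$mean_lys[r$arm_summaries$arm == "no_rpm"]
  })
  expect_gt(runs[[1]], runs[[2]])
})
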