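test_that("a patient whose draws outlive the horizon is censored event-free", {
  pts <- sample_patients(pkg_spec, 20, seed = 1)
  # both event-time equations pushed far beyond the horizon
  models <- forced_models(rehosp_intercept = 20, death_intercept = 20)
  traj <- simulate_cohort(pts, models, econ = zero_econ())
  H <- years_to_days(25)
  expect_true(all(traj$life_days == H))
  expect_true(all(!traj$death_observed))
  expect_true(all(is.na(traj$t_death)))
  expect_true(all(traj$n_rehosp == 0))
  expect_equal(traj$cost_disc, rep(0, nrow(traj)))
})

test_that("common random numbers couple the arms exactly", {
  pts <- sample_patients(pkg_spec, 2000, seed = 8)
  traj <- simulate_cohort(pts, pkg_models)
  wide <- tidyr::pivot_wider(
    dplyr::select(traj, id, arm, t_first_rehosp),
    names_from = arm, values_from = t_first_rehosp
  )
  both <- dplyr::filter(wide, !is.na(no_rpm), !is.na(rpm))
  expect_gt(nrow(both), 1000)
  expect_equal(both$rpm, both$no_rpm * exp(0.0968), tolerance = 1e-12)
})

test_that("subsequent rehospitalizations are Poisson at the arm rate", {
  # immediate first rehospitalization, death far beyond a 10-year horizon:
  # the post-rehospitalization window is (almost) exactly 10 years
  models <- forced_models(rehosp_intercept = -10, death_intercept = 20)
  cfg <- sim_config(horizon_years = 10, master_seed = 77)
  pts <- sample_patients(pkg_spec, 10000, seed = 77)
  traj <- simulate_cohort(pts, models, econ = zero_econ(), cfg = cfg)

  for (a in c("no_rpm", "rpm")) {
    lam <- cfg$subsequent_rehosp_rate[[a]] * 10
    cnt <- traj$n_rehosp[traj$arm == a] - 1 # drop the first event
    expect_equal(mean(cnt), lam, tolerance = 3 * sqrt(lam / 10000) / lam)
    expect_equal(var(cnt), lam, tolerance = 0.1)
  }

  # doubling the rate doubles the expected count
  cfg2 <- sim_config(
    horizon_years = 10,
    subsequent_rehosp_rate = c(no_rpm = 2 * 1.79, rpm = 2 * 1.65),
    master_seed = 77
  )
  traj2 <- simulate_cohort(pts, models, econ = zero_econ(), cfg = cfg2)
  m1 <- mean(traj$n_rehosp[traj$arm == "no_rpm"] - 1)
  m2 <- mean(traj2$n_rehosp[traj2$arm == "no_rpm"] - 1)
  expect_equal(m2 / m1, 2, tolerance = 0.03)
})

test_that("event ordering and death dominance hold on the real model", {
  pts <- sample_patients(pkg_spec, 1500, seed = 31)
  traj <- simulate_cohort(pts, pkg_models, keep_events = TRUE)
  events <- attr(traj, "events")
  H <- years_to_days(25)

  joined <- dplyr::inner_join(
    events,
    dplyr::select(traj, id, arm, t_first_rehosp, end_time),
    by = c("id", "arm")
  )
  expect_true(all(joined$time >= joined$t_first_rehosp))
  expect_true(all(joined$time <= joined$end_time))
  expect_true(all(traj$end_time <= H))
  expect_true(all(traj$life_days <= H))
  # death times only within follow-up
  expect_true(all(is.na(traj$t_death) | traj$t_death <= H))
  # rehospitalization count = first event + subsequent events
  n_ev <- dplyr::count(joined, id, arm)
  chk <- dplyr::inner_join(n_ev, traj, by = c("id", "arm"))
  expect_equal(chk$n, chk$n_rehosp)
})

test_that("simulation is deterministic under the master seed", {
  pts <- sample_patients(pkg_spec, 400, seed = 5)
  t1 <- simulate_cohort(pts, pkg_models, cfg = sim_config(master_seed = 123))
  t2 <- simulate_cohort(pts, pkg_models, cfg = sim_config(master_seed = 123))
  expect_identical(t1, t2)
  t3 <- simulate_cohort(pts, pkg_models, cfg = sim_config(master_seed = 124))
  expect_false(identical(t1, t3))
})

test_that("with all arm differences removed the clones are symmetric", {
  pts <- sample_patients(pkg_spec, 800, seed = 13)
  models <- pkg_models
  models$rehosp$rpm_coefficient <- 0
  models$death$rpm_coefficient <- 0
  cfg <- sim_config(subsequent_rehosp_rate = c(no_rpm = 1.79, rpm = 1.79))
  econ <- econ_inputs(
    cost_per_rehosp = c(no_rpm = 5000, rpm = 5000),
    claim_rates = dplyr::mutate(rpmsim:::default_claim_rates(), rate = 10),
    claim_costs = dplyr::mutate(rpmsim:::default_claim_costs(), cost = 100),
    los_days = c(no_rpm = 5, rpm = 5)
  )
  traj <- simulate_cohort(pts, models, econ = econ, cfg = cfg)
  s <- summarize_arms(traj)
  num <- dplyr::select(s, -arm)
  expect_equal(as.numeric(num[1, ]), as.numeric(num[2, ]), tolerance = 1e-12)
})

test_that("raising a harmful covariate to 100% prevalence shortens life", {
  pts <- sample_patients(pkg_spec, 3000, seed = 21)
  traj <- simulate_cohort(pts, pkg_models, econ = zero_econ())
  forced <- dplyr::mutate(pts, lung_disease = "yes")
  traj_f <- simulate_cohort(forced, pkg_models, econ = zero_econ())
  expect_lt(mean(traj_f$ly_disc), mean(traj$ly_disc))
})

test_that("simulate_patient wraps the cohort engine for one clone", {
  pt <- sample_patients(pkg_spec, 1, seed = 3)
  one <- simulate_patient(pt, "rpm", pkg_models)
  expect_equal(nrow(one), 1)
  expect_equal(one$arm, "rpm")
  expect_error(simulate_cohort(pt[0, ], pkg_models), "empty cohort")
})
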