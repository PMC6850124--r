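test_that("linear predictor reproduces the published equation structure", {
  ref <- reference_patient(pkg_spec)
  expect_equal(linear_predictor(ref, pkg_models$rehosp), 7.5446)
  expect_equal(linear_predictor(ref, pkg_models$rehosp, rpm = TRUE), 7.5446 + 0.0968)
  expect_equal(linear_predictor(ref, pkg_models$death), 9.976)
  expect_equal(
    linear_predictor(ref, pkg_models$death, hospitalized = TRUE),
    9.976 - 1.5451
  )
  # hospitalization history is a mortality-only condition
  expect_error(
    linear_predictor(ref, pkg_models$rehosp, hospitalized = TRUE),
    "death endpoint"
  )
  # a non-reference level moves mu by its coefficient
  old <- dplyr::mutate(ref, age = ">=75")
  expect_equal(
    linear_predictor(old, pkg_models$rehosp),
    7.5446 - 0.1822
  )
})

test_that("packaged models satisfy the shape = 1/scale reciprocity", {
  for (m in pkg_models) {
    expect_lt(abs(m$shape - 1 / m$scale) / m$shape, 0.001)
  }
  expect_error(
    new_aft_model("rehosp",
      intercept = 7, scale = 1.2, shape = 2,
      coefficients = tibble::tibble(
        covariate = character(0), level = character(0), coefficient = numeric(0)
      ),
      rpm_coefficient = 0
    ),
    "inconsistent"
  )
})

test_that("survival function behaves as a Weibull survival", {
  m <- pkg_models$rehosp
  mu <- 7.5446
  expect_equal(aft_survival(m, mu, 0), 1)
  expect_equal(aft_survival(m, mu, exp(mu)), exp(-1))
  expect_error(aft_survival(m, mu, -1), "nonnegative")
  t <- seq(0, 9000, by = 500)
  s <- aft_survival(m, mu, t)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("median time matches an independent numeric inversion of S(t)", {
  m <- pkg_models$rehosp
  mu <- 7.5446
  # oracle: solve S(t) = 0.5 by root finding, no closed form used
  oracle <- uniroot(
    function(t) aft_survival(m, mu, t) - 0.5,
    c(1, 1e6),
    tol = 1e-10
  )$root
  expect_equal(median_event_time(m, mu), oracle, tolerance = 1e-8)
  expect_equal(oracle, 1216.6, tolerance = 1e-4)
  # exponential special case and monotonicity
  m1 <- flat_model(scale = 1)
  expect_equal(median_event_time(m1, 5), exp(5) * log(2))
  expect_true(all(diff(median_event_time(m, seq(5, 9, 0.5))) > 0))
})

test_that("sampling inverts survival exactly and obeys the scaling law", {
  u <- c(1e-9, 1e-4, seq(0.05, 0.95, by = 0.05), 1 - 1e-9)
  for (m in pkg_models) {
    mu <- if (m$endpoint == "rehosp") 7.5446 else 9.976
    t <- sample_event_time(m, mu, u)
    expect_equal(aft_survival(m, mu, t), u, tolerance = 1e-12)
    # u = exp(-1) maps to the characteristic life exp(mu)
    expect_equal(sample_event_time(m, mu, exp(-1)), exp(mu))
    # adding beta to mu multiplies times by exp(beta) for the same u
    beta <- 0.0968
    expect_equal(
      sample_event_time(m, mu + beta, u),
      exp(beta) * sample_event_time(m, mu, u),
      tolerance = 1e-12
    )
  }
  # u -> 1 gives vanishing times
  expect_lt(sample_event_time(pkg_models$rehosp, 7.5446, 1 - 1e-12), 1e-3)
  expect_error(sample_event_time(pkg_models$rehosp, 7, 0), "strictly inside")
  expect_error(sample_event_time(pkg_models$rehosp, 7, 1), "strictly inside")
})

test_that("the published RPM coefficients imply ~10% and ~18% extensions", {
  expect_equal(exp(0.0968), 1.1016, tolerance = 1e-4)
  expect_equal(exp(0.1666), 1.1813, tolerance = 1e-4)
})

test_that("conditional sampling is left-truncated resampling", {
  m <- pkg_models$death
  mu <- 8.5
  u <- seq(0.05, 0.95, by = 0.05)
  # no truncation: identical to the unconditional draw
  expect_equal(
    conditional_event_time(m, mu, 0, u),
    sample_event_time(m, mu, u),
    tolerance = 1e-12
  )
  # truncation contract: strictly beyond t0
  for (t0 in c(10, 500, 5000)) {
    expect_true(all(conditional_event_time(m, mu, t0, u) > t0))
  }
  expect_error(conditional_event_time(m, mu, -1, 0.5), "nonnegative")
  expect_error(conditional_event_time(m, mu, 10, 0), "strictly inside")

  # distributional check against a rejection-sampling oracle at t0 = median
  t0 <- median_event_time(m, mu)
  n <- 20000
  u_cond <- rpmsim:::counter_uniforms(99, seq_len(n), 1)
  draws <- conditional_event_time(m, mu, t0, u_cond)
  u_rej <- rpmsim:::counter_uniforms(42, seq_len(20 * n), 2)
  raw <- sample_event_time(m, mu, u_rej)
  oracle <- raw[raw > t0][seq_len(n)]
  ks <- suppressWarnings(stats::ks.test(draws, oracle))
  expect_gt(ks$p.value, 0.001)
})

test_that("coefficient loading validates against the population", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c(
      "endpoint,covariate,level,coefficient,se,p",
      "rehosp,(scale),,1.2,,", "rehosp,(intercept),,7.5,,",
      "rehosp,rpm,yes,0.1,,",
      "rehosp,age,ancient,-0.2,,",
      "death,(scale),,1.0,,", "death,(intercept),,9.9,,",
      "death,rpm,yes,0.1,,", "death,hospitalization,yes,-1.5,,"
    ),
    f
  )
  expect_error(
    load_aft_models(f, population = pkg_spec),
    "no matching population level"
  )
  # without a population to check against, the table loads
  expect_silent(models <- load_aft_models(f))
  expect_equal(models$rehosp$shape, 1 / 1.2)
})
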