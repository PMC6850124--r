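#' Construct a Weibull accelerated-failure-time model
#'
#' Log-time AFT parameterization: `log T = mu + sigma * W` with `W`
#' standard minimum extreme value, so survival is
#' `S(t) = exp(-(t / exp(mu))^(1/sigma))` and the Weibull shape is
#' `k = 1/sigma`. Positive coefficients lengthen time to event. Times are
#' in days; `mu` is on the log-day scale.
#'
#' @param endpoint `"rehosp"` (time to first rehospitalization) or
#'   `"death"`.
#' @param intercept log-days intercept.
#' @param coefficients tibble with columns `covariate`, `level`,
#'   `coefficient` (non-reference levels only; optional `se`, `p` carried
#'   along for reporting).
#' @param rpm_coefficient log-time coefficient of the remote-monitoring
#'   condition.
#' @param hosp_coefficient log-time coefficient applied to mortality after
#'   the first rehospitalization (death endpoint only; `NULL` otherwise).
#' @param scale AFT scale `sigma` (> 0).
#' @param shape Weibull shape; defaults to `1/scale`. If supplied it must
#'   agree with `1/scale` to 0.1% relative tolerance.
#' @return An `aft_model` object.
#' @export
new_aft_model <- function(endpoint, intercept, coefficients, rpm_coefficient,
                          hosp_coefficient = NULL, scale, shape = NULL) {
  endpoint <- match.arg(endpoint, c("rehosp", "death"))
  if (scale <= 0) abort("scale must be positive")
  if (!is.null(shape) && abs(shape - 1 / scale) / shape >= 0.001) {
    abort(sprintf(
      "shape (%.4f) inconsistent with 1/scale (%.4f) beyond 0.1%% tolerance",
      shape, 1 / scale
    ))
  }
  if (endpoint == "rehosp" && !is.null(hosp_coefficient)) {
    abort("the rehospitalization model takes no hospitalization-history coefficient")
  }
  coefficients <- as_tibble(coefficients)
  stopifnot(all(c("covariate", "level", "coefficient") %in% names(coefficients)))
  structure(
    list(
      endpoint = endpoint,
      intercept = intercept,
      coefficients = coefficients,
      rpm_coefficient = rpm_coefficient,
      hosp_coefficient = hosp_coefficient,
      scale = scale,
      shape = shape %||% (1 / scale)
    ),
    class = "aft_model"
  )
}

#' @export
print.aft_model <- function(x, ...) {
  cat(sprintf(
    "<aft_model: %s>  intercept %.4f (log-days), scale %.4f, shape %.4f\n",
    x$endpoint, x$intercept, x$scale, x$shape
  ))
  cat(sprintf(
    "  RPM coefficient %.4f%s; %d covariate coefficients\n",
    x$rpm_coefficient,
    if (!is.null(x$hosp_coefficient)) {
      sprintf("; hospitalization coefficient %.4f", x$hosp_coefficient)
    } else {
      ""
    },
    nrow(x$coefficients)
  ))
  invisible(x)
}

#' Load the packaged time-to-event regression equations
#'
#' Reads the published Weibull AFT coefficient table (time to first
#' rehospitalization and time to death for the PREDICT RM cohort) or a
#' user-supplied CSV in the same layout (`endpoint`, `covariate`, `level`,
#' `coefficient`, `se`, `p`, with special covariate rows `(intercept)`,
#' `(scale)`, `(shape)`, `rpm`, and `hospitalization`). When a population
#' specification is supplied, every coefficient's (covariate, level) pair is
#' validated against it.
#'
#' @param path CSV path; `NULL` uses the packaged table.
#' @param population optional `population_spec` to validate against.
#' @return Named list with elements `rehosp` and `death`, each an
#'   [new_aft_model()] object.
#' @examples
#' models <- load_aft_models()
#' models$death
#' @export
load_aft_models <- function(path = NULL, population = NULL) {
  path <- path %||% system.file("extdata", "aft_coefficients.csv", package = "rpmsim")
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      endpoint = readr::col_character(), covariate = readr::col_character(),
      level = readr::col_character(), coefficient = readr::col_double(),
      se = readr::col_double(), p = readr::col_character()
    ),
    progress = FALSE
  )
  build <- function(ep) {
    d <- filter(raw, .data$endpoint == ep)
    grab <- function(term) {
      v <- d$coefficient[d$covariate == term]
      if (length(v) == 1) v else NULL
    }
    covs <- filter(
      d,
      !.data$covariate %in% c("(intercept)", "(scale)", "(shape)", "rpm", "hospitalization")
    )
    if (!is.null(population)) {
      for (i in seq_len(nrow(covs))) {
        hit <- population$covariate == covs$covariate[i] & population$level == covs$level[i]
        if (!any(hit)) {
          abort(sprintf(
            "coefficient (%s, %s) has no matching population level",
            covs$covariate[i], covs$level[i]
          ))
        }
      }
    }
    new_aft_model(
      endpoint = ep,
      intercept = grab("(intercept)"),
      coefficients = select(covs, "covariate", "level", "coefficient", "se", "p"),
      rpm_coefficient = grab("rpm") %||% 0,
      hosp_coefficient = if (ep == "death") grab("hospitalization") else NULL,
      scale = grab("(scale)"),
      shape = grab("(shape)")
    )
  }
  list(rehosp = build("rehosp"), death = build("death"))
}

#' Linear predictor of an AFT equation
#'
#' `mu = intercept + sum(beta[level]) + rpm * beta_RPM +
#' hospitalized * beta_hosp` on the log-day scale. Reference levels (and any
#' unreported remainder level) contribute zero.
#'
#' @param patients patient tibble (one column per covariate).
#' @param model an `aft_model`.
#' @param rpm logical scalar or vector: remote-monitoring condition on?
#' @param hospitalized logical scalar or vector: after first
#'   rehospitalization? Only meaningful for the death endpoint.
#' @return Numeric vector of log-day linear predictors, one per patient.
#' @examples
#' models <- load_aft_models()
#' ref <- reference_patient(load_population_spec())
#' linear_predictor(ref, models$rehosp) # the rehospitalization intercept
#' @export
linear_predictor <- function(patients, model, rpm = FALSE, hospitalized = FALSE) {
  stopifnot(inherits(model, "aft_model"))
  n <- nrow(patients)
  mu <- rep(model$intercept, n)
  cf <- model$coefficients
  for (i in seq_len(nrow(cf))) {
    col <- patients[[cf$covariate[i]]]
    if (is.null(col)) abort(sprintf("patient table lacks covariate '%s'", cf$covariate[i]))
    mu <- mu + cf$coefficient[i] * (col == cf$level[i])
  }
  mu <- mu + as.numeric(rpm) * model$rpm_coefficient
  if (!is.null(model$hosp_coefficient)) {
    mu <- mu + as.numeric(hospitalized) * model$hosp_coefficient
  } else if (any(as.logical(hospitalized))) {
    abort("hospitalization history applies only to the death endpoint")
  }
  mu
}

#' All-reference patient profile
#'
#' Convenience one-row patient tibble with every covariate at its reference
#' level, for which every linear predictor equals the model intercept.
#'
#' @param spec a `population_spec`.
#' @return One-row patient tibble.
#' @export
reference_patient <- function(spec) {
  ref <- attr(spec, "reference_levels")
  out <- as_tibble(as.list(ref))
  mutate(out, id = 1L, .before = 1)
}

#' Weibull AFT survival function
#'
#' `S(t) = exp(-(t / exp(mu))^(1/sigma))`.
#'
#' @param model an `aft_model` (supplies `sigma`).
#' @param mu linear predictor(s), log-days.
#' @param t time(s) in days, >= 0.
#' @return Survival probabilities in `[0, 1]`.
#' @export
aft_survival <- function(model, mu, t) {
  if (any(t < 0)) abort("t must be nonnegative")
  exp(-(t / exp(mu))^(1 / model$scale))
}

#' Sample an event time by inverse survival
#'
#' Interprets `u` as a survival-probability draw (`u = S(T)`), giving
#' `T = exp(mu) * (-log(u))^sigma`. Shared `u` values across arms or
#' scenarios implement common random numbers: adding `beta` to `mu`
#' multiplies the sampled time by `exp(beta)` exactly.
#'
#' @inheritParams aft_survival
#' @param u uniform draw(s) strictly inside (0, 1).
#' @return Event time(s) in days.
#' @export
sample_event_time <- function(model, mu, u) {
  if (any(u <= 0 | u >= 1)) abort("u must lie strictly inside (0, 1)")
  exp(mu) * (-log(u))^model$scale
}

#' Sample an event time conditional on survival to t0
#'
#' Inverse-CDF draw from the Weibull distribution with updated linear
#' predictor `mu`, left-truncated at `t0`:
#' `T = exp(mu) * ((t0/exp(mu))^(1/sigma) - log(u))^sigma > t0`.
#' This is the mechanism by which the mortality equation's
#' hospitalization-history coefficient takes effect at the first
#' rehospitalization: the remaining death time is re-drawn from the updated
#' equation conditioned on having survived to the rehospitalization.
#'
#' @inheritParams sample_event_time
#' @param t0 left-truncation time(s) in days, >= 0. At `t0 = 0` the draw
#'   equals [sample_event_time()].
#' @return Event time(s) in days, strictly greater than `t0`.
#' @export
conditional_event_time <- function(model, mu, t0, u) {
  if (any(u <= 0 | u >= 1)) abort("u must lie strictly inside (0, 1)")
  if (any(t0 < 0)) abort("t0 must be nonnegative")
  a <- exp(mu)
  a * ((t0 / a)^(1 / model$scale) - log(u))^model$scale
}

#' Median event time
#'
#' `median(T) = exp(mu) * log(2)^sigma`; used for risk stratification and
#' reporting.
#'
#' @inheritParams aft_survival
#' @return Median time(s) in days.
#' @export
median_event_time <- function(model, mu) {
  exp(mu) * log(2)^model$scale
}
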