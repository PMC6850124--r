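log_msg <- function(...) message(sprintf(...))

#' Run the base case and write report files
#'
#' Simulates the configured cohort, writes per-arm summaries and
#' incremental results as CSV plus a machine-readable JSON block embedding
#' the seed, cohort size, configuration hash and package version. Logs go
#' to stderr; results never go to stdout.
#'
#' @param config a `run_config` (see [load_run_config()]).
#' @param out_dir output directory (created if absent); defaults to the
#'   config's `output_dir`.
#' @return The [icer()] result, invisibly; side effect: files
#'   `arm_summaries.csv`, `incrementals.csv`, `result.json`.
#' @export
run_base_case <- function(config = default_run_config(), out_dir = NULL) {
  t0 <- Sys.time()
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- resolve_config(config)
  log_msg(
    "base case: n = %d, seed = %d, horizon = %g y",
    nrow(parts$patients), config$master_seed, parts$cfg$horizon_years
  )
  res <- run_cea(parts$patients, parts$models, parts$econ, parts$cfg)
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  stamp <- function(d) {
    mutate(d, master_seed = config$master_seed, config_hash = config_hash(config))
  }
  readr::write_csv(stamp(res$arm_summaries), file.path(out_dir, "arm_summaries.csv"))
  readr::write_csv(stamp(tidy(res)), file.path(out_dir, "incrementals.csv"))
  payload <- list(
    meta = list(
      master_seed = config$master_seed, n = nrow(parts$patients),
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("rpmsim"))
    ),
    arms = res$arm_summaries,
    incrementals = as.list(setNames(tidy(res)$estimate, tidy(res)$term)),
    dominance = res$dominance
  )
  jsonlite::write_json(payload, file.path(out_dir, "result.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  log_msg("base case done in %.1f s", runtime)
  invisible(res)
}

#' Validate the event-time engine against its analytic equations
#'
#' Simulates the raw first-rehospitalization and pre-hospitalization death
#' draws for a cohort and compares the empirical survival of the sampled
#' times with the analytic population-average Weibull survival at interior
#' deciles. Inverse-CDF sampling is exact, so the deviation is pure
#' Monte-Carlo noise; the check PASSes when the maximum absolute deviation
#' is below 0.01 at a cohort of at least 100,000.
#'
#' @param config a `run_config`; `cohort_size` patients are simulated.
#' @param arm which arm's equations to validate.
#' @return A `validation_report`: list with the decile table (`table`),
#'   `max_deviation`, `n` and `pass`.
#' @export
validate_engine <- function(config = default_run_config(), arm = "no_rpm") {
  parts <- resolve_config(config)
  n <- nrow(parts$patients)
  rpm <- arm == "rpm"
  rows <- map(c("rehosp", "death"), function(ep) {
    model <- parts$models[[ep]]
    mu <- linear_predictor(parts$patients, model, rpm = rpm)
    u <- counter_uniforms(
      parts$cfg$master_seed, parts$patients$id,
      if (ep == "rehosp") CTR_FIRST_REHOSP else CTR_DEATH
    )
    times <- sample_event_time(model, mu, u)
    survival_deviation(times, mu, model) |> mutate(endpoint = ep, .before = 1)
  })
  tab <- list_rbind(rows)
  max_dev <- max(abs(tab$deviation))
  structure(
    list(table = tab, max_deviation = max_dev, n = n, pass = max_dev < 0.01 && n >= 1e5),
    class = "validation_report"
  )
}

#' Empirical-vs-analytic survival deviation table
#'
#' Shared helper of [validate_engine()]: at the empirical deciles of the
#' sampled times, compares the empirical survival (0.9, 0.8, ..., 0.1 by
#' construction) with the analytic population-average survival
#' `mean_i S_i(t)`.
#'
#' @param times sampled event times (days).
#' @param mu per-patient linear predictors used to sample them.
#' @param model the `aft_model`.
#' @return Tibble: `time`, `empirical`, `analytic`, `deviation`.
#' @export
survival_deviation <- function(times, mu, model) {
  probs <- seq(0.1, 0.9, by = 0.1)
  grid <- quantile(times, probs, names = FALSE, type = 7)
  emp <- vapply(grid, function(t) mean(times > t), numeric(1))
  ana <- vapply(grid, function(t) mean(aft_survival(model, mu, t)), numeric(1))
  tibble(time = grid, empirical = emp, analytic = ana, deviation = emp - ana)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n = %d, max |empirical - analytic| = %.4f -> %s\n",
    x$n, x$max_deviation,
    if (x$pass) "PASS" else "no PASS claim (needs max dev < 0.01 at n >= 100,000)"
  ))
  invisible(x)
}

#' Survival-overlay plot for a validation report
#'
#' @param report a `validation_report` from [validate_engine()].
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  d <- report$table |>
    tidyr::pivot_longer(c("empirical", "analytic"),
      names_to = "curve", values_to = "survival"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time / DAYS_PER_YEAR, y = .data$survival,
    colour = .data$curve, linetype = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~endpoint, scales = "free_x") +
    ggplot2::labs(
      x = "Years", y = "Survival",
      title = "Sampled vs analytic survival at deciles"
    ) +
    ggplot2::theme_minimal()
}

#' Run the packaged scenario battery and write the report
#'
#' @param config a `run_config`.
#' @param scenarios list of [scenario()]s; default [scenario_battery()].
#' @param out_file CSV path, or `NULL` to skip writing.
#' @return Scenario tibble from [run_scenarios()].
#' @export
run_scenario_report <- function(config = default_run_config(),
                                scenarios = scenario_battery(),
                                out_file = NULL) {
  parts <- resolve_config(config)
  parts$patients <- assign_risk_strata(
    parts$patients, parts$models$rehosp, parts$models$death
  )
  base <- list(
    models = parts$models, econ = parts$econ,
    cfg = parts$cfg, patients = parts$patients
  )
  log_msg("running %d scenarios at n = %d", length(scenarios), nrow(parts$patients))
  tab <- run_scenarios(base, scenarios)
  if (!is.null(out_file)) readr::write_csv(tab, out_file)
  tab
}

#' Run a one-way sensitivity sweep and write the report
#'
#' @param config a `run_config`.
#' @param parameters dotted parameter paths (default: the main cost, rate,
#'   utility and discount inputs).
#' @param multipliers length-2 multipliers (default x0.8 / x1.2).
#' @param out_file CSV path, or `NULL` to skip writing.
#' @return Sweep tibble from [one_way_sensitivity()].
#' @export
run_sensitivity_report <- function(config = default_run_config(),
                                   parameters = c(
                                     "econ.discount_rate",
                                     "econ.cost_per_rehosp",
                                     "econ.baseline_utility",
                                     "econ.comorbidity_decrement",
                                     "econ.los_days",
                                     "econ.claim_rates",
                                     "econ.claim_costs",
                                     "cfg.subsequent_rehosp_rate"
                                   ),
                                   multipliers = c(0.8, 1.2),
                                   out_file = NULL) {
  parts <- resolve_config(config)
  base <- list(
    models = parts$models, econ = parts$econ,
    cfg = parts$cfg, patients = parts$patients
  )
  tab <- one_way_sensitivity(base, parameters, multipliers)
  if (!is.null(out_file)) readr::write_csv(tab, out_file)
  tab
}
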