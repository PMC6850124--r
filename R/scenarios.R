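#' Scenario definitions
#'
#' A scenario is a named list of typed modifications applied to a base
#' analysis (models, economic inputs, simulation config, patient cohort)
#' before re-running the cost-effectiveness analysis under the base
#' cohort's common random numbers.
#'
#' @param name unique scenario label.
#' @param ... modification objects created by [zero_coefficient()],
#'   [set_horizon()], [force_covariate()], [equalize()], [toggle_utility()],
#'   [restrict_stratum()], [set_param()] or [scale_param()].
#' @param note optional free-text annotation carried into outputs (e.g.
#'   "approximate" for quartile-based strata).
#' @return A `scenario` object.
#' @export
scenario <- function(name, ..., note = NA_character_) {
  mods <- list(...)
  ok <- vapply(mods, function(m) inherits(m, "scenario_mod"), logical(1))
  if (!all(ok)) abort("all modifications must be scenario_mod objects")
  structure(list(name = name, modifications = mods, note = note), class = "scenario")
}

new_mod <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "scenario_mod")
}

#' Scenario modifications
#'
#' Constructors for the typed edits a [scenario()] can apply.
#'
#' * `zero_coefficient(endpoint, term, level)` sets a regression
#'   coefficient to zero; `term` may be `"rpm"`, `"hospitalization"`, or a
#'   covariate name (all its levels, or one `level`).
#' * `set_horizon(years)` truncates follow-up.
#' * `force_covariate(covariate, level)` sets the level for every patient.
#' * `equalize(field, type, to)` copies an arm-specific value from arm `to`
#'   onto the other arm; `field` is one of `"subsequent_rehosp_rate"`,
#'   `"cost_per_rehosp"`, `"death_cost"`, `"los_days"`, `"claim_rates"`,
#'   `"claim_costs"` (the last two optionally restricted to a claim
#'   `type`).
#' * `toggle_utility(rule)` switches off a utility rule:
#'   `"no_zero_utility_in_hospital"` or `"no_comorbidity_disutility"`.
#' * `restrict_stratum(death_quartile, rehosp_quartile)` keeps only
#'   patients in one predicted-risk stratum.
#' * `set_param(path, value)` / `scale_param(path, factor)` address any
#'   numeric input by dotted path, e.g. `"econ.discount_rate"`,
#'   `"econ.cost_per_rehosp.rpm"`, `"cfg.subsequent_rehosp_rate.no_rpm"`,
#'   `"econ.claim_rates.outpatient.rpm.pre"`.
#'
#' @param endpoint,term,level,years,covariate,field,type,to,rule
#'   see descriptions above.
#' @param death_quartile,rehosp_quartile stratum indices in 1..4.
#' @param path,value,factor dotted parameter path and its new value or
#'   multiplier.
#' @return A `scenario_mod` object.
#' @name scenario_mods
NULL

#' @rdname scenario_mods
#' @export
zero_coefficient <- function(endpoint, term, level = NULL) {
  new_mod("zero_coefficient",
    endpoint = match.arg(endpoint, c("rehosp", "death")),
    term = term, level = level
  )
}

#' @rdname scenario_mods
#' @export
set_horizon <- function(years) new_mod("set_horizon", years = years)

#' @rdname scenario_mods
#' @export
force_covariate <- function(covariate, level) {
  new_mod("force_covariate", covariate = covariate, level = level)
}

#' @rdname scenario_mods
#' @export
equalize <- function(field, type = NULL, to = "no_rpm") {
  new_mod("equalize", field = field, type = type, to = to)
}

#' @rdname scenario_mods
#' @export
toggle_utility <- function(rule) {
  new_mod("toggle_utility",
    rule = match.arg(rule, c("no_zero_utility_in_hospital", "no_comorbidity_disutility"))
  )
}

#' @rdname scenario_mods
#' @export
restrict_stratum <- function(death_quartile, rehosp_quartile) {
  stopifnot(death_quartile %in% 1:4, rehosp_quartile %in% 1:4)
  new_mod("restrict_stratum", death_quartile = death_quartile, rehosp_quartile = rehosp_quartile)
}

#' @rdname scenario_mods
#' @export
set_param <- function(path, value) new_mod("set_param", path = path, value = value)

#' @rdname scenario_mods
#' @export
scale_param <- function(path, factor) {
  if (factor <= 0) abort("multiplier must be positive")
  new_mod("scale_param", path = path, factor = factor)
}

#' Apply a scenario to a base analysis
#'
#' Returns a deep-modified copy of the base inputs; the base is untouched.
#'
#' @param base list with elements `models`, `econ`, `cfg`, `patients`
#'   (patients optionally carrying `death_quartile` / `rehosp_quartile`
#'   columns from [assign_risk_strata()]).
#' @param scen a [scenario()].
#' @return A modified copy of `base`.
#' @export
apply_scenario <- function(base, scen) {
  stopifnot(inherits(scen, "scenario"))
  for (m in scen$modifications) base <- apply_mod(base, m)
  base
}

apply_mod <- function(base, m) {
  switch(m$kind,
    zero_coefficient = {
      mod <- base$models[[m$endpoint]]
      if (identical(m$term, "rpm")) {
        mod$rpm_coefficient <- 0
      } else if (identical(m$term, "hospitalization")) {
        if (is.null(mod$hosp_coefficient)) abort("no hospitalization coefficient on this endpoint")
        mod$hosp_coefficient <- 0
      } else {
        hit <- mod$coefficients$covariate == m$term
        if (!is.null(m$level)) hit <- hit & mod$coefficients$level == m$level
        if (!any(hit)) abort(sprintf("no coefficient matches term '%s'", m$term))
        mod$coefficients$coefficient[hit] <- 0
      }
      base$models[[m$endpoint]] <- mod
      base
    },
    set_horizon = {
      base$cfg$horizon_years <- m$years
      base
    },
    force_covariate = {
      if (!m$covariate %in% names(base$patients)) {
        abort(sprintf("unknown covariate '%s'", m$covariate))
      }
      base$patients[[m$covariate]] <- m$level
      base
    },
    equalize = {
      f <- m$field
      if (f == "subsequent_rehosp_rate") {
        base$cfg$subsequent_rehosp_rate[] <- base$cfg$subsequent_rehosp_rate[[m$to]]
      } else if (f %in% c("cost_per_rehosp", "death_cost", "los_days")) {
        base$econ[[f]][] <- base$econ[[f]][[m$to]]
      } else if (f %in% c("claim_rates", "claim_costs")) {
        tab <- base$econ[[f]]
        valcol <- if (f == "claim_rates") "rate" else "cost"
        sel <- if (is.null(m$type)) rep(TRUE, nrow(tab)) else tab$type == m$type
        src <- tab[sel & tab$arm == m$to, c("type", "phase", valcol)]
        for (i in which(sel)) {
          v <- src[[valcol]][src$type == tab$type[i] & src$phase == tab$phase[i]]
          tab[[valcol]][i] <- v
        }
        base$econ[[f]] <- tab
      } else {
        abort(sprintf("unknown equalize field '%s'", f))
      }
      base
    },
    toggle_utility = {
      if (m$rule == "no_zero_utility_in_hospital") {
        base$econ$utility_zero_in_hospital <- FALSE
      } else {
        base$econ$comorbidity_decrement <- 0
      }
      base
    },
    restrict_stratum = {
      p <- base$patients
      if (!all(c("death_quartile", "rehosp_quartile") %in% names(p))) {
        abort("patients carry no risk strata; run assign_risk_strata() on the base cohort")
      }
      base$patients <- filter(
        p,
        .data$death_quartile == m$death_quartile,
        .data$rehosp_quartile == m$rehosp_quartile
      )
      if (nrow(base$patients) == 0) abort("stratum is empty")
      base
    },
    set_param = modify_param(base, m$path, function(x) m$value),
    scale_param = modify_param(base, m$path, function(x) x * m$factor),
    abort(sprintf("unknown modification kind '%s'", m$kind))
  )
}

# dotted-path resolver over cfg/econ scalars, arm-named vectors and the
# claim rate/cost tables ("econ.claim_rates[.type][.arm][.phase]")
modify_param <- function(base, path, f) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !parts[1] %in% c("econ", "cfg")) {
    abort(sprintf("unknown parameter path '%s'", path))
  }
  root <- parts[1]
  field <- parts[2]
  obj <- base[[root]]
  if (!field %in% names(obj)) abort(sprintf("unknown parameter path '%s'", path))
  target <- obj[[field]]
  rest <- parts[-(1:2)]
  if (is.data.frame(target)) {
    valcol <- if ("rate" %in% names(target)) "rate" else "cost"
    sel <- rep(TRUE, nrow(target))
    for (p in rest) {
      sel <- sel & (target$type == p | target$arm == p | target$phase == p)
    }
    if (!any(sel)) abort(sprintf("path '%s' matches no rows", path))
    target[[valcol]][sel] <- f(target[[valcol]][sel])
  } else if (length(rest) == 1) {
    if (!rest %in% names(target)) abort(sprintf("unknown parameter path '%s'", path))
    target[[rest]] <- f(target[[rest]])
  } else if (length(rest) == 0) {
    target[] <- f(target)
  } else {
    abort(sprintf("unknown parameter path '%s'", path))
  }
  obj[[field]] <- target
  base[[root]] <- obj
  base
}

#' Run a batch of scenarios
#'
#' Each scenario re-runs the cost-effectiveness analysis against the base
#' cohort under the base master seed (common random numbers), so scenario
#' deltas are pure parameter effects. Per-scenario failures are reported in
#' the `error` column without aborting the batch.
#'
#' @param base list with `models`, `econ`, `cfg`, `patients` (run
#'   [assign_risk_strata()] on the patients first if stratum scenarios are
#'   included).
#' @param scenarios list of [scenario()] objects.
#' @return Tibble: one row per scenario with `delta_qalys`, `delta_costs`,
#'   `delta_lys`, `icer_per_qaly`, `dominance`, `n`, `note`, `error`.
#' @export
run_scenarios <- function(base, scenarios) {
  if (length(scenarios) == 0) abort("no scenarios supplied")
  nms <- map_chr(scenarios, "name")
  if (anyDuplicated(nms)) abort("scenario names must be unique within a batch")
  rows <- map(scenarios, function(sc) {
    res <- tryCatch(
      {
        mod <- apply_scenario(base, sc)
        r <- run_cea(mod$patients, mod$models, mod$econ, mod$cfg)
        tibble(
          scenario = sc$name, n = r$arm_summaries$n[1],
          delta_lys = r$delta_lys, delta_qalys = r$delta_qalys,
          delta_costs = r$delta_costs, icer_per_qaly = r$icer_per_qaly,
          dominance = r$dominance, note = sc$note, error = NA_character_
        )
      },
      error = function(e) {
        tibble(
          scenario = sc$name, n = NA_integer_, delta_lys = NA_real_,
          delta_qalys = NA_real_, delta_costs = NA_real_,
          icer_per_qaly = NA_real_, dominance = NA_character_,
          note = sc$note, error = conditionMessage(e)
        )
      }
    )
    res
  })
  list_rbind(rows)
}

#' The packaged scenario battery
#'
#' The published scenario grid: each reported predicted-risk stratum
#' (quartile approximation, labelled as such), 100% forcings of key
#' comorbidities, removal of the RPM coefficients from either or both
#' equations, truncated horizons, equalized arm-specific costs/rates/LoS
#' (no-RPM values), a DRG-like death cost (explicitly synthetic placeholder
#' value), and the utility-rule toggles.
#'
#' @param death_cost_placeholder USD used for the death-cost scenario
#'   (synthetic placeholder; the published value is not public).
#' @return List of [scenario()] objects (length >= 25).
#' @export
scenario_battery <- function(death_cost_placeholder = 11000) {
  strata <- list(
    c(1, 1), c(2, 1), c(3, 1), c(1, 2), c(2, 2), c(3, 2), c(4, 2),
    c(2, 3), c(3, 3), c(4, 3), c(2, 4), c(3, 4), c(4, 4)
  )
  stratum_scens <- map(strata, function(s) {
    scenario(sprintf("stratum D%d-R%d", s[1], s[2]),
      restrict_stratum(s[1], s[2]),
      note = "approximate (within-cohort quartile strata)"
    )
  })
  c(
    stratum_scens,
    list(
      scenario("AF = 100%", force_covariate("af_flutter", "yes")),
      scenario("Cerebrovascular disease = 100%", force_covariate("cerebrovascular", "yes")),
      scenario("Chronic lung disease = 100%", force_covariate("lung_disease", "yes")),
      scenario("Diabetes = 100%", force_covariate("diabetes", "yes")),
      scenario("Hypertension = 100%", force_covariate("hypertension", "yes")),
      scenario("RPM coeff = 0, rehospitalization", zero_coefficient("rehosp", "rpm")),
      scenario("RPM coeff = 0, death", zero_coefficient("death", "rpm")),
      scenario(
        "RPM coeff = 0, rehospitalization and death",
        zero_coefficient("rehosp", "rpm"), zero_coefficient("death", "rpm")
      ),
      scenario("Time horizon = 2", set_horizon(2)),
      scenario("Time horizon = 5", set_horizon(5)),
      scenario("Time horizon = 10", set_horizon(10)),
      scenario("Death cost = DRG-like MI death cost",
        set_param("econ.death_cost", death_cost_placeholder),
        note = "synthetic placeholder death cost"
      ),
      scenario("LoS equivalent (no RPM value)", equalize("los_days")),
      scenario(
        "Equal hospital outpatient/ASC costs (no RPM value)",
        equalize("claim_costs", type = "outpatient")
      ),
      scenario(
        "Equal physician visit costs (no RPM value)",
        equalize("claim_costs", type = "physician")
      ),
      scenario(
        "Equal hospital outpatient/ASC rates (no RPM value)",
        equalize("claim_rates", type = "outpatient")
      ),
      scenario(
        "Equal physician visit rates (no RPM value)",
        equalize("claim_rates", type = "physician")
      ),
      scenario(
        "Equal subsequent rehospitalization rates (no RPM value)",
        equalize("subsequent_rehosp_rate")
      ),
      scenario(
        "No utility of zero during hospitalization",
        toggle_utility("no_zero_utility_in_hospital")
      ),
      scenario(
        "No disutility following hospitalization",
        toggle_utility("no_comorbidity_disutility")
      ),
      scenario(
        "No hospitalization utility rules",
        toggle_utility("no_zero_utility_in_hospital"),
        toggle_utility("no_comorbidity_disutility")
      )
    )
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the analysis with each parameter scaled down and up (default
#' x0.8 / x1.2) under common random numbers, and orders parameters by the
#' resulting ICER spread (tornado ordering; ties broken alphabetically).
#'
#' @inheritParams run_scenarios
#' @param parameters character vector of dotted parameter paths (see
#'   [set_param()]).
#' @param multipliers length-2 positive multipliers (low, high).
#' @return Tibble: `parameter`, `icer_low`, `icer_high`,
#'   `delta_costs_low/high`, `delta_qalys_low/high`, `spread`, sorted by
#'   decreasing spread.
#' @export
one_way_sensitivity <- function(base, parameters,
                                multipliers = c(0.8, 1.2)) {
  stopifnot(length(multipliers) == 2, all(multipliers > 0))
  rows <- map(parameters, function(p) {
    run_at <- function(mult) {
      mod <- apply_scenario(base, scenario("sweep", scale_param(p, mult)))
      run_cea(mod$patients, mod$models, mod$econ, mod$cfg)
    }
    lo <- run_at(multipliers[1])
    hi <- run_at(multipliers[2])
    tibble(
      parameter = p,
      icer_low = lo$icer_per_qaly, icer_high = hi$icer_per_qaly,
      delta_costs_low = lo$delta_costs, delta_costs_high = hi$delta_costs,
      delta_qalys_low = lo$delta_qalys, delta_qalys_high = hi$delta_qalys
    )
  })
  list_rbind(rows) |>
    mutate(spread = abs(.data$icer_high - .data$icer_low)) |>
    arrange(desc(.data$spread), .data$parameter)
}

#' Tornado plot of a sensitivity sweep
#'
#' @param sweep tibble from [one_way_sensitivity()].
#' @param base_icer optional base-case ICER to draw as a reference line.
#' @return A ggplot object.
#' @export
plot_tornado <- function(sweep, base_icer = NULL) {
  d <- sweep |>
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  p <- ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high, yend = .data$parameter),
      linewidth = 4, colour = "#4393C3"
    ) +
    ggplot2::labs(
      x = "ICER (USD per QALY)", y = NULL,
      title = "One-way sensitivity (tornado ordering)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  p
}
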