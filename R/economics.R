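#' Economic inputs
#'
#' Costs, outpatient claim rates, lengths of stay and utility parameters.
#' The supplementary cost/utility tables behind the published model (DRG
#' cost mix, claim-rate and utility-coefficient tables) were never made
#' public, so the defaults here are calibrated placeholders back-solved from
#' the published per-arm lifetime aggregates (see the methods vignette);
#' every value is overridable. Arm-keyed values are named vectors
#' `c(no_rpm = ..., rpm = ...)`.
#'
#' @param discount_rate annual effective discount rate (default 0.03).
#' @param cost_per_rehosp USD per rehospitalization event, per arm.
#' @param death_cost USD terminal event cost, per arm (default 0; a
#'   DRG-like death cost is exercised via scenarios).
#' @param claim_rates tibble `type` ("outpatient" = hospital
#'   outpatient/ASC, "physician"), `arm`, `phase` ("pre"/"post" first
#'   rehospitalization), `rate` in claims per patient-year.
#' @param claim_costs tibble in the same shape, `cost` in USD per claim.
#' @param los_days mean hospital length of stay per rehospitalization,
#'   per arm.
#' @param baseline_utility scalar in `[0, 1]`, or a function of the patient
#'   tibble returning one utility per patient.
#' @param comorbidity_decrement permanent utility decrement per acquired
#'   comorbidity.
#' @param comorbidity_prob probability that a rehospitalization adds a
#'   permanent comorbidity.
#' @param utility_zero_in_hospital logical; patients accrue zero utility
#'   during each hospital stay (default TRUE).
#' @return An `econ_inputs` object (list).
#' @export
econ_inputs <- function(discount_rate = 0.03,
                        cost_per_rehosp = c(no_rpm = 57023 / 10.4, rpm = 59214 / 11.0),
                        death_cost = c(no_rpm = 0, rpm = 0),
                        claim_rates = default_claim_rates(),
                        claim_costs = default_claim_costs(),
                        los_days = c(no_rpm = 5, rpm = 5),
                        baseline_utility = 0.825,
                        comorbidity_decrement = 0.02,
                        comorbidity_prob = 0.25,
                        utility_zero_in_hospital = TRUE) {
  if (discount_rate < 0 || discount_rate >= 1) abort("discount_rate must be in [0, 1)")
  check_arm_vec <- function(x, nm) {
    if (!all(c("no_rpm", "rpm") %in% names(x))) {
      abort(sprintf("%s must be named with 'no_rpm' and 'rpm'", nm))
    }
    if (any(x < 0)) abort(sprintf("%s must be nonnegative", nm))
  }
  check_arm_vec(cost_per_rehosp, "cost_per_rehosp")
  check_arm_vec(death_cost, "death_cost")
  check_arm_vec(los_days, "los_days")
  if (is.numeric(baseline_utility) &&
    (baseline_utility < 0 || baseline_utility > 1)) {
    abort("baseline_utility must be in [0, 1]")
  }
  if (any(claim_rates$rate < 0) || any(claim_costs$cost < 0)) {
    abort("claim rates and costs must be nonnegative")
  }
  structure(
    list(
      discount_rate = discount_rate,
      cost_per_rehosp = cost_per_rehosp,
      death_cost = death_cost,
      claim_rates = as_tibble(claim_rates),
      claim_costs = as_tibble(claim_costs),
      los_days = los_days,
      baseline_utility = baseline_utility,
      comorbidity_decrement = comorbidity_decrement,
      comorbidity_prob = comorbidity_prob,
      utility_zero_in_hospital = utility_zero_in_hospital
    ),
    class = "econ_inputs"
  )
}

# Claim rates (claims per patient-year) back-solved from published lifetime
# claim totals divided by undiscounted person-years per arm; the pre/post
# first-rehospitalization split is unpublished, so phases share one rate.
default_claim_rates <- function() {
  py <- c(no_rpm = 10.4 / 1.26, rpm = 11.0 / 1.18) # undiscounted person-years
  tidyr::expand_grid(
    type = c("outpatient", "physician"),
    arm = c("no_rpm", "rpm"),
    phase = c("pre", "post")
  ) |>
    mutate(rate = dplyr::case_when(
      .data$type == "outpatient" & .data$arm == "no_rpm" ~ 68.1 / py[["no_rpm"]],
      .data$type == "outpatient" & .data$arm == "rpm" ~ 84.6 / py[["rpm"]],
      .data$type == "physician" & .data$arm == "no_rpm" ~ 194 / py[["no_rpm"]],
      .data$type == "physician" & .data$arm == "rpm" ~ 233 / py[["rpm"]]
    ))
}

# Per-claim costs: published discounted lifetime nonhospital cost divided by
# lifetime claim count, per arm; the type/phase breakdown is unpublished.
default_claim_costs <- function() {
  tidyr::expand_grid(
    type = c("outpatient", "physician"),
    arm = c("no_rpm", "rpm"),
    phase = c("pre", "post")
  ) |>
    mutate(cost = ifelse(.data$arm == "no_rpm", 42792 / 262, 47515 / 317))
}

#' Present-value discount factor
#'
#' Annual-effective convention applied continuously:
#' `(1 + r)^(-t / 365.25)` for `t` in days.
#'
#' @param t time in days (>= 0).
#' @param rate annual effective discount rate.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) abort("t must be nonnegative")
  (1 + rate)^(-t / DAYS_PER_YEAR)
}

#' Discounted accrual over an interval
#'
#' Closed-form integral of the discount factor over `[t0, t1]` (days),
#' returned in years: `((1+r)^(-tau0) - (1+r)^(-tau1)) / log(1+r)` with
#' `tau = t / 365.25`; the zero-rate limit is `tau1 - tau0`. The QALY part is
#' the utility times the life-year part.
#'
#' @param u utility in `[0, 1]` applying over the interval.
#' @param t0,t1 interval bounds in days, `0 <= t0 <= t1`.
#' @param rate annual effective discount rate.
#' @return Tibble with columns `lys` and `qalys` (discounted years).
#' @export
accrue_interval <- function(u, t0, t1, rate) {
  if (any(t1 < t0)) abort("t1 must be >= t0")
  tibble(lys = discounted_years(t0, t1, rate), qalys = u * discounted_years(t0, t1, rate))
}

# vectorized core of accrue_interval (days in, years out)
discounted_years <- function(t0, t1, rate) {
  tau0 <- t0 / DAYS_PER_YEAR
  tau1 <- t1 / DAYS_PER_YEAR
  if (rate == 0) {
    tau1 - tau0
  } else {
    ((1 + rate)^(-tau0) - (1 + rate)^(-tau1)) / log(1 + rate)
  }
}

#' Accrue discounted outcomes and costs along trajectories
#'
#' Vectorized ledger builder. Life is partitioned at each rehospitalization;
#' utility is zero during each hospital stay (clipped at the next event,
#' death or the horizon); each rehospitalization may add a permanent utility
#' decrement; event costs are discounted at their event times; outpatient
#' claims accrue deterministically as rate x time with costs discounted
#' continuously over each phase; the terminal death cost is discounted at
#' the death time.
#'
#' @param traj tibble with one row per patient-arm: `id`, `arm`,
#'   `t_first_rehosp` (days, `NA` if none), `end_time` (days,
#'   `min(t_death, H)`), `death_observed` (logical), `u0` (baseline
#'   utility).
#' @param events tibble of rehospitalization events: `id`, `arm`, `time`
#'   (days), `comorbid` (logical: event adds a permanent comorbidity).
#'   Includes the first rehospitalization.
#' @param econ an [econ_inputs()] object.
#' @return `traj` with added ledger columns (`ly_disc`, `ly_undisc`,
#'   `qaly_disc`, cost components, claim counts, `n_rehosp`).
#' @export
accrue_trajectories <- function(traj, events, econ) {
  r <- econ$discount_rate
  key <- function(id, arm) paste(arm, id)

  # --- life-years ---------------------------------------------------------
  out <- traj |>
    mutate(
      ly_disc = discounted_years(0, .data$end_time, r),
      ly_undisc = .data$end_time / DAYS_PER_YEAR
    )

  # --- QALYs and event costs ---------------------------------------------
  ev <- events |>
    inner_join(
      select(out, "id", "arm", "end_time", "u0"),
      by = c("id", "arm")
    ) |>
    arrange(.data$arm, .data$id, .data$time)

  if (nrow(ev) > 0) {
    k <- key(ev$id, ev$arm)
    new_grp <- c(TRUE, k[-1] != k[-length(k)])
    grp_sizes <- diff(c(which(new_grp), length(k) + 1))
    # per-group cumulative comorbidity count after each event
    cs <- cumsum(ev$comorbid)
    base <- rep(cs[new_grp] - ev$comorbid[new_grp], grp_sizes)
    n_comorb <- cs - base
    u_after <- pmin(1, pmax(0, ev$u0 - econ$comorbidity_decrement * n_comorb))
    # interval from this event to the next event (or end of follow-up)
    nxt <- c(ev$time[-1], NA_real_)
    nxt[c(new_grp[-1], TRUE)] <- NA_real_ # last event of each group
    seg_end <- ifelse(is.na(nxt), ev$end_time, nxt)
    seg_end <- pmax(seg_end, ev$time) # events at end_time contribute nothing
    qaly_seg <- u_after * discounted_years(ev$time, seg_end, r)
    # zero utility during each stay, clipped at next event / end of follow-up
    if (econ$utility_zero_in_hospital) {
      los <- unname(econ$los_days[ev$arm])
      stay_end <- pmin(ev$time + los, seg_end)
      qaly_seg <- qaly_seg - u_after * discounted_years(ev$time, stay_end, r)
    }
    ev$qaly_seg <- qaly_seg
    ev$cost_disc <- unname(econ$cost_per_rehosp[ev$arm]) * discount_factor(ev$time, r)
    ev$cost_undisc <- unname(econ$cost_per_rehosp[ev$arm])
    ev$first_time <- rep(ev$time[new_grp], grp_sizes)

    ev_sum <- ev |>
      group_by(.data$id, .data$arm) |>
      summarise(
        qaly_after_first = sum(.data$qaly_seg),
        rehosp_cost_disc = sum(.data$cost_disc),
        rehosp_cost_undisc = sum(.data$cost_undisc),
        n_rehosp = dplyr::n(),
        .groups = "drop"
      )
  } else {
    ev_sum <- tibble(
      id = integer(0), arm = character(0), qaly_after_first = numeric(0),
      rehosp_cost_disc = numeric(0), rehosp_cost_undisc = numeric(0),
      n_rehosp = integer(0)
    )
  }

  out <- out |>
    left_join(ev_sum, by = c("id", "arm")) |>
    mutate(
      qaly_after_first = tidyr::replace_na(.data$qaly_after_first, 0),
      rehosp_cost_disc = tidyr::replace_na(.data$rehosp_cost_disc, 0),
      rehosp_cost_undisc = tidyr::replace_na(.data$rehosp_cost_undisc, 0),
      n_rehosp = tidyr::replace_na(.data$n_rehosp, 0L),
      pre_end = pmin(dplyr::coalesce(.data$t_first_rehosp, Inf), .data$end_time),
      qaly_disc = .data$u0 * discounted_years(0, .data$pre_end, r) + .data$qaly_after_first
    ) |>
    select(-"qaly_after_first")

  # --- outpatient claims (deterministic rate x time) ----------------------
  phase_disc <- function(arm, phase) {
    t0 <- if (phase == "pre") 0 else dplyr::coalesce(out$t_first_rehosp, out$end_time)
    t1 <- if (phase == "pre") out$pre_end else out$end_time
    sel <- out$arm == arm
    list(
      years = (t1 - t0)[sel] / DAYS_PER_YEAR,
      disc_years = discounted_years(t0, t1, r)[sel],
      sel = sel
    )
  }
  out$claims_outpatient <- 0
  out$claims_physician <- 0
  out$claim_cost_disc <- 0
  out$claim_cost_undisc <- 0
  for (armv in unique(out$arm)) {
    for (ph in c("pre", "post")) {
      pd <- phase_disc(armv, ph)
      for (ty in c("outpatient", "physician")) {
        rate <- econ$claim_rates$rate[econ$claim_rates$type == ty &
          econ$claim_rates$arm == armv & econ$claim_rates$phase == ph]
        cost <- econ$claim_costs$cost[econ$claim_costs$type == ty &
          econ$claim_costs$arm == armv & econ$claim_costs$phase == ph]
        col <- paste0("claims_", ty)
        out[[col]][pd$sel] <- out[[col]][pd$sel] + rate * pd$years
        out$claim_cost_disc[pd$sel] <- out$claim_cost_disc[pd$sel] +
          rate * cost * pd$disc_years
        out$claim_cost_undisc[pd$sel] <- out$claim_cost_undisc[pd$sel] +
          rate * cost * pd$years
      }
    }
  }

  # --- terminal death cost ------------------------------------------------
  dc <- unname(econ$death_cost[out$arm])
  out |>
    mutate(
      death_cost_disc = ifelse(.data$death_observed,
        dc * discount_factor(.data$end_time, r), 0
      ),
      death_cost_undisc = ifelse(.data$death_observed, dc, 0),
      cost_disc = .data$rehosp_cost_disc + .data$claim_cost_disc + .data$death_cost_disc,
      cost_undisc = .data$rehosp_cost_undisc + .data$claim_cost_undisc +
        .data$death_cost_undisc
    ) |>
    select(-"pre_end")
}

# baseline utility per patient: scalar or function hook
baseline_utilities <- function(econ, patients) {
  if (is.function(econ$baseline_utility)) {
    u <- econ$baseline_utility(patients)
  } else {
    u <- rep(econ$baseline_utility, nrow(patients))
  }
  pmin(1, pmax(0, u))
}
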