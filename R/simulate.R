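#' Simulation configuration
#'
#' @param horizon_years maximum follow-up (default 25 years; patients alive
#'   at the horizon are censored, no terminal event is forced).
#' @param subsequent_rehosp_rate events per patient-year after the first
#'   rehospitalization, per arm (published constant rates: no-RPM 1.79,
#'   RPM 1.65).
#' @param master_seed integer master seed; all randomness derives from it
#'   through per-patient counter streams.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(horizon_years = 25,
                       subsequent_rehosp_rate = c(no_rpm = 1.79, rpm = 1.65),
                       master_seed = 20060101) {
  if (horizon_years <= 0) abort("horizon must be positive")
  if (any(subsequent_rehosp_rate < 0)) abort("rates must be nonnegative")
  if (!all(c("no_rpm", "rpm") %in% names(subsequent_rehosp_rate))) {
    abort("subsequent_rehosp_rate must be named with 'no_rpm' and 'rpm'")
  }
  structure(
    list(
      horizon_years = horizon_years,
      subsequent_rehosp_rate = subsequent_rehosp_rate,
      master_seed = as.integer(master_seed)
    ),
    class = "sim_config"
  )
}

# draw-counter layout within each patient stream (see methods vignette):
#   1 first-rehospitalization survival draw (shared across arms)
#   2 pre-hospitalization death survival draw (shared across arms)
#   3 post-hospitalization conditional death re-draw (shared across arms)
#   4 subsequent-rehospitalization count quantile draw (shared across arms)
#   101..  subsequent event placement within the post-rehosp window
#   1001.. comorbidity acquisition per rehospitalization event
#   2001.. baseline covariate sampling (population module)
CTR_FIRST_REHOSP <- 1
CTR_DEATH <- 2
CTR_DEATH_REDRAW <- 3
CTR_SUBSEQ_COUNT <- 4
CTR_EVENT_TIMES <- 100
CTR_COMORBID <- 1000

#' Simulate a cloned cohort through the discrete-event model
#'
#' Each patient is cloned into the no-RPM and RPM arms with common random
#' numbers: the same survival-probability draws feed the first
#' rehospitalization, the pre-hospitalization death time, the conditional
#' death re-draw and the subsequent-rehospitalization count in both arms,
#' so arm differences are pure parameter effects. Event flow per clone:
#'
#' 1. draw time to first rehospitalization (arm-specific RPM coefficient)
#'    and time to death (hospitalization history off);
#' 2. if death comes first (ties resolve in favor of death), the patient
#'    dies without rehospitalization;
#' 3. otherwise the first rehospitalization fires and the death time is
#'    re-drawn from the mortality equation with the hospitalization
#'    coefficient applied, left-truncated at the rehospitalization time;
#' 4. subsequent rehospitalizations arrive as a homogeneous Poisson process
#'    at the arm's constant rate from the first rehospitalization until
#'    death or the horizon;
#' 5. outpatient claims accrue deterministically as rate x time by phase;
#'    all accrual stops at `min(t_death, H)`.
#'
#' @param patients patient tibble from [sample_patients()] (or a validated
#'   user table with an `id` column).
#' @param models named list with `rehosp` and `death` [new_aft_model()]s.
#' @param econ an [econ_inputs()] object.
#' @param cfg a [sim_config()] object.
#' @param arms character vector of arms to simulate.
#' @param keep_events if `TRUE`, attach the per-event table as attribute
#'   `"events"` (for audit dumps).
#' @return Trajectory tibble, one row per patient-arm, with event times,
#'   counts and the discounted/undiscounted ledger columns of
#'   [accrue_trajectories()].
#' @examples
#' spec <- load_population_spec()
#' models <- load_aft_models(population = spec)
#' pts <- sample_patients(spec, 200, seed = 7)
#' traj <- simulate_cohort(pts, models)
#' dplyr::count(traj, arm)
#' @export
simulate_cohort <- function(patients, models, econ = econ_inputs(),
                            cfg = sim_config(), arms = c("no_rpm", "rpm"),
                            keep_events = FALSE) {
  if (nrow(patients) == 0) abort("empty cohort")
  if (!"id" %in% names(patients)) abort("patient table needs an 'id' column")
  seed <- cfg$master_seed
  H <- years_to_days(cfg$horizon_years)
  ids <- patients$id

  u_rehosp <- counter_uniforms(seed, ids, CTR_FIRST_REHOSP)
  u_death <- counter_uniforms(seed, ids, CTR_DEATH)
  u_redraw <- counter_uniforms(seed, ids, CTR_DEATH_REDRAW)
  u_count <- counter_uniforms(seed, ids, CTR_SUBSEQ_COUNT)

  mu_r0 <- linear_predictor(patients, models$rehosp)
  mu_d0 <- linear_predictor(patients, models$death)
  u0 <- baseline_utilities(econ, patients)

  one_arm <- function(arm) {
    rpm <- arm == "rpm"
    mu_r <- mu_r0 + rpm * models$rehosp$rpm_coefficient
    mu_d <- mu_d0 + rpm * models$death$rpm_coefficient
    t_rehosp <- sample_event_time(models$rehosp, mu_r, u_rehosp)
    t_death0 <- sample_event_time(models$death, mu_d, u_death)

    first_fires <- t_rehosp < pmin(t_death0, H) # death ties beat rehospitalization
    mu_d_post <- mu_d + (models$death$hosp_coefficient %||% 0)
    t_death <- ifelse(
      first_fires,
      conditional_event_time(models$death, mu_d_post, t_rehosp, u_redraw),
      t_death0
    )
    end_time <- pmin(t_death, H)
    t_first <- ifelse(first_fires, t_rehosp, NA_real_)

    # subsequent rehospitalizations: Poisson count via shared quantile draw,
    # event times iid uniform over the post-rehospitalization window
    window_days <- ifelse(first_fires, end_time - t_first, 0)
    lambda <- cfg$subsequent_rehosp_rate[[arm]] * days_to_years(window_days)
    n_sub <- qpois(u_count, lambda)

    sub_id <- rep(ids, n_sub)
    sub_ctr <- CTR_EVENT_TIMES + sequence(n_sub)
    sub_u <- counter_uniforms(seed, sub_id, sub_ctr)
    sub_time <- rep(t_first, n_sub) + sub_u * rep(window_days, n_sub)

    first_ev <- tibble(
      id = ids[first_fires], time = t_first[first_fires],
      ctr = CTR_COMORBID
    )
    sub_ev <- tibble(id = sub_id, time = sub_time, ctr = CTR_COMORBID + sub_ctr - CTR_EVENT_TIMES)
    events <- bind_rows(first_ev, sub_ev)
    events$comorbid <- counter_uniforms(seed, events$id, events$ctr) < econ$comorbidity_prob
    events$arm <- arm
    events <- select(events, "id", "arm", "time", "comorbid")

    death_observed <- t_death <= H
    traj <- tibble(
      id = ids, arm = arm,
      t_first_rehosp = t_first,
      t_death = ifelse(death_observed, t_death, NA_real_),
      death_observed = death_observed,
      end_time = end_time,
      u0 = u0
    )
    list(traj = traj, events = events)
  }

  parts <- map(arms, one_arm)
  traj <- list_rbind(map(parts, "traj"))
  events <- list_rbind(map(parts, "events"))
  out <- accrue_trajectories(traj, events, econ) |>
    mutate(life_days = .data$end_time) |>
    arrange(.data$id, .data$arm)
  if (keep_events) attr(out, "events") <- arrange(events, .data$id, .data$arm, .data$time)
  out
}

#' Simulate a single patient in one arm
#'
#' Thin wrapper over [simulate_cohort()] for a one-row patient table.
#'
#' @param patient one-row patient tibble.
#' @param arm `"no_rpm"` or `"rpm"`.
#' @inheritParams simulate_cohort
#' @return One-row trajectory tibble.
#' @export
simulate_patient <- function(patient, arm, models, econ = econ_inputs(),
                             cfg = sim_config()) {
  stopifnot(nrow(patient) == 1)
  simulate_cohort(patient, models, econ, cfg, arms = arm)
}

#' Write a per-event audit dump
#'
#' @param traj trajectory tibble produced with `keep_events = TRUE`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_event_dump <- function(traj, path) {
  events <- attr(traj, "events")
  if (is.null(events)) abort("run simulate_cohort(..., keep_events = TRUE) first")
  readr::write_csv(mutate(events, event = "rehospitalization"), path)
  invisible(path)
}
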