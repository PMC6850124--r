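#' Per-arm summary of simulated trajectories
#'
#' Arithmetic means over patients with Monte-Carlo standard errors.
#' Per-patient-year (PPY) metrics divide lifetime totals by mean
#' *undiscounted* person-years; life-years, QALYs and costs are discounted.
#'
#' @param traj trajectory tibble from [simulate_cohort()].
#' @return Tibble with one row per arm (class `arm_summary`).
#' @export
summarize_arms <- function(traj) {
  if (nrow(traj) == 0) abort("no trajectories to summarize")
  out <- traj |>
    group_by(.data$arm) |>
    summarise(
      n = dplyr::n(),
      mean_lys = mean(.data$ly_disc),
      se_lys = sd(.data$ly_disc) / sqrt(dplyr::n()),
      mean_undiscounted_lys = mean(.data$ly_undisc),
      mean_qalys = mean(.data$qaly_disc),
      se_qalys = sd(.data$qaly_disc) / sqrt(dplyr::n()),
      mean_rehosp = mean(.data$n_rehosp),
      se_rehosp = sd(.data$n_rehosp) / sqrt(dplyr::n()),
      claims_outpatient = mean(.data$claims_outpatient),
      claims_physician = mean(.data$claims_physician),
      rehosp_cost = mean(.data$rehosp_cost_disc),
      nonhospital_cost = mean(.data$claim_cost_disc + .data$death_cost_disc),
      total_cost = mean(.data$cost_disc),
      se_total_cost = sd(.data$cost_disc) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    mutate(
      claims_total = .data$claims_outpatient + .data$claims_physician,
      rehosp_ppy = .data$mean_rehosp / .data$mean_undiscounted_lys,
      claims_ppy = .data$claims_total / .data$mean_undiscounted_lys,
      rehosp_cost_ppy = .data$rehosp_cost / .data$mean_undiscounted_lys,
      nonhospital_cost_ppy = .data$nonhospital_cost / .data$mean_undiscounted_lys,
      total_cost_ppy = .data$total_cost / .data$mean_undiscounted_lys
    )
  class(out) <- c("arm_summary", class(out))
  out
}

#' Incremental cost-effectiveness result
#'
#' Differences are intervention minus reference. Dominance classification:
#' cheaper and more effective (in QALYs) is `intervention_dominant`;
#' costlier and less effective is `intervention_dominated`; otherwise the
#' ICER is the cost difference per QALY (and per life-year) gained. With no
#' QALY difference the ICER is undefined and flagged.
#'
#' @param summaries an `arm_summary` tibble from [summarize_arms()].
#' @param reference,intervention arm labels.
#' @return A `cea_result` object with `tidy()`, `glance()`, `print()` and
#'   `autoplot()` methods.
#' @examples
#' spec <- load_population_spec()
#' models <- load_aft_models(population = spec)
#' pts <- sample_patients(spec, 500, seed = 42)
#' res <- icer(summarize_arms(simulate_cohort(pts, models)))
#' res
#' @export
icer <- function(summaries, reference = "no_rpm", intervention = "rpm") {
  ref <- filter(summaries, .data$arm == reference)
  int <- filter(summaries, .data$arm == intervention)
  if (nrow(ref) != 1 || nrow(int) != 1) abort("need exactly one summary row per arm")
  d_ly <- int$mean_lys - ref$mean_lys
  d_qaly <- int$mean_qalys - ref$mean_qalys
  d_cost <- int$total_cost - ref$total_cost
  d_rehosp <- int$mean_rehosp - ref$mean_rehosp
  d_ppy <- int$rehosp_ppy - ref$rehosp_ppy

  dominance <- if (d_cost < 0 && d_qaly > 0) {
    "intervention_dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    "intervention_dominated"
  } else {
    "none"
  }
  undefined_icer <- dominance == "none" && d_qaly == 0
  structure(
    list(
      arm_summaries = summaries,
      reference = reference,
      intervention = intervention,
      delta_lys = d_ly,
      delta_qalys = d_qaly,
      delta_costs = d_cost,
      delta_rehosp = d_rehosp,
      delta_rehosp_ppy = d_ppy,
      dominance = dominance,
      icer_undefined = undefined_icer,
      icer_per_ly = if (dominance == "none" && d_ly != 0) d_cost / d_ly else NA_real_,
      icer_per_qaly = if (dominance == "none" && !undefined_icer) d_cost / d_qaly else NA_real_
    ),
    class = "cea_result"
  )
}

#' Run the full base-case cost-effectiveness analysis
#'
#' Simulates the cloned cohort and aggregates it into a [icer()] result.
#'
#' @inheritParams simulate_cohort
#' @return A `cea_result`.
#' @export
run_cea <- function(patients, models, econ = econ_inputs(), cfg = sim_config()) {
  icer(summarize_arms(simulate_cohort(patients, models, econ, cfg)))
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf(
    "<cea_result> %s vs %s (n = %d per arm)\n",
    x$intervention, x$reference, x$arm_summaries$n[1]
  ))
  cat(sprintf(
    "  delta LYs %.3f | delta QALYs %.3f | delta costs $%.0f\n",
    x$delta_lys, x$delta_qalys, x$delta_costs
  ))
  if (x$dominance != "none") {
    cat(sprintf("  dominance: %s\n", x$dominance))
  } else if (x$icer_undefined) {
    cat("  ICER undefined (no QALY difference)\n")
  } else {
    cat(sprintf(
      "  ICER $%.0f per QALY ($%.0f per LY); $50,000/QALY threshold: %s\n",
      x$icer_per_qaly, x$icer_per_ly,
      if (x$icer_per_qaly < 50000) "below" else "above"
    ))
  }
  invisible(x)
}

#' @export
tidy.cea_result <- function(x, ...) {
  tibble(
    term = c(
      "delta_lys", "delta_qalys", "delta_rehosp", "delta_rehosp_ppy",
      "delta_costs", "icer_per_ly", "icer_per_qaly"
    ),
    estimate = c(
      x$delta_lys, x$delta_qalys, x$delta_rehosp, x$delta_rehosp_ppy,
      x$delta_costs, x$icer_per_ly, x$icer_per_qaly
    )
  )
}

#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    n = x$arm_summaries$n[1],
    delta_lys = x$delta_lys,
    delta_qalys = x$delta_qalys,
    delta_costs = x$delta_costs,
    icer_per_qaly = x$icer_per_qaly,
    dominance = x$dominance
  )
}

#' Cost-effectiveness plane
#'
#' Incremental cost vs incremental QALYs with the conventional
#' $50,000/QALY willingness-to-pay line.
#'
#' @param object a `cea_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cea_result <- function(object, ...) {
  d <- tibble(dq = object$delta_qalys, dc = object$delta_costs)
  lim_q <- max(abs(d$dq), 0.1) * 1.3
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dq, y = .data$dc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 50000, intercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 3, colour = "#2166AC") +
    ggplot2::xlim(-lim_q, lim_q) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (USD)",
      title = "Cost-effectiveness plane",
      subtitle = "Dashed line: $50,000 per QALY"
    ) +
    ggplot2::theme_minimal()
}
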