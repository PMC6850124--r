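#' Registry of baseline covariates
#'
#' One row per categorical baseline covariate of the simulated ICD cohort:
#' its reference level (the category carrying no regression coefficient) and
#' the label used for any unprinted remainder mass. Binary risk factors
#' (e.g. diabetes) are tabulated only as a "yes" share; their remainder is
#' the "no" reference. Covariates whose printed shares fall short of 100%
#' (e.g. hospital teaching status) get an explicit "(unreported)" level with
#' zero coefficient so each covariate remains a proper distribution.
#'
#' @return A tibble with columns `covariate`, `reference_level`,
#'   `remainder_level`.
#' @export
covariate_registry <- function() {
  tribble_reg <- list(
    c("age", "65-74"),
    c("nyha", "I/II"),
    c("sex", "male"),
    c("race", "white"),
    c("admission_reason", "procedure"),
    c("chf_duration", "none"),
    c("chf_hospitalization", "none"),
    c("af_flutter", "no"),
    c("nidcm", "none"),
    c("cabg_pci", "no"),
    c("pacemaker", "no"),
    c("cerebrovascular", "no"),
    c("lung_disease", "no"),
    c("diabetes", "no"),
    c("hypertension", "no"),
    c("dialysis", "no"),
    c("qrs", "<=120"),
    c("ivc", "normal"),
    c("creatinine", "<=1.5"),
    c("bun", "<=20"),
    c("sodium", "135-145"),
    c("sbp", "<=100"),
    c("icd_type", "single"),
    c("teaching", "coth"),
    c("pop_density", "<=3000")
  )
  binary <- c(
    "af_flutter", "cabg_pci", "pacemaker", "cerebrovascular", "lung_disease",
    "diabetes", "hypertension", "dialysis"
  )
  tibble(
    covariate = map_chr(tribble_reg, 1),
    reference_level = map_chr(tribble_reg, 2),
    remainder_level = ifelse(map_chr(tribble_reg, 1) %in% binary, "no", "(unreported)")
  )
}

#' Load a population specification
#'
#' Reads a table of categorical covariate frequencies (by default the
#' PREDICT RM population characteristics packaged with rpmsim) and returns a
#' normalized per-level probability table. Exact level counts are preferred
#' over printed percentage shares when both are present. Mass missing from a
#' covariate (its counts summing to less than the column denominator) is
#' assigned to an implicit remainder level that carries no regression
#' coefficient.
#'
#' @param source which frequency column to use: `"total"` (default; the
#'   base case uses the pooled cohort for both arms, since patients are
#'   cloned into arms), `"control"` or `"rpm"`.
#' @param path CSV with columns `covariate`, `level`, and `count` and/or
#'   `share` (percent); optional `source` and `denominator` columns.
#'   `NULL` uses the packaged table.
#' @return A `population_spec`: tibble with columns `covariate`, `level`,
#'   `prob`, `is_reference`, plus attributes `source` and `reference_levels`.
#' @examples
#' spec <- load_population_spec()
#' dplyr::filter(spec, covariate == "age")
#' @export
load_population_spec <- function(source = c("total", "control", "rpm"), path = NULL) {
  source <- match.arg(source)
  path <- path %||% system.file("extdata", "population_margins.csv", package = "rpmsim")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("covariate", "level") %in% names(raw))) {
    abort("population table must have 'covariate' and 'level' columns")
  }
  if ("source" %in% names(raw)) raw <- filter(raw, .data$source == !!source)
  if (nrow(raw) == 0) abort(sprintf("no rows for source '%s'", source))

  reg <- covariate_registry()
  unknown <- setdiff(unique(raw$covariate), reg$covariate)
  if (length(unknown) > 0) {
    abort(paste0("unknown covariate(s): ", paste(unknown, collapse = ", ")))
  }

  weight_col <- if ("count" %in% names(raw) && !all(is.na(raw$count))) "count" else "share"
  raw$w <- as.numeric(raw[[weight_col]])
  if (any(is.na(raw$w))) abort("missing frequency values in population table")
  if (any(raw$w < 0)) abort("negative frequencies in population table")

  denom <- if ("denominator" %in% names(raw) && weight_col == "count") {
    unique(raw$denominator)
  } else {
    NULL
  }
  if (!is.null(denom) && length(denom) != 1) abort("denominator must be constant within a source")

  spec <- raw |>
    group_by(.data$covariate) |>
    group_modify(function(d, key) {
      total <- sum(d$w)
      if (total <= 0) abort(sprintf("covariate '%s' has zero total mass", key$covariate))
      full <- if (!is.null(denom)) denom else if (weight_col == "share") 100 else total
      rem <- max(0, full - total)
      # share-only tables: a sub-rounding shortfall (< 2%) is renormalized
      # away rather than promoted to an explicit remainder level
      if (is.null(denom) && rem / full < 0.02) rem <- 0
      out <- tibble(level = d$level, prob = d$w)
      if (rem > full * 1e-9) {
        rem_label <- reg$remainder_level[reg$covariate == key$covariate]
        if (rem_label %in% out$level) {
          out$prob[out$level == rem_label] <- out$prob[out$level == rem_label] + rem
        } else {
          out <- bind_rows(out, tibble(level = rem_label, prob = rem))
        }
      }
      out$prob <- out$prob / sum(out$prob)
      out
    }) |>
    ungroup()

  ref <- setNames(reg$reference_level, reg$covariate)
  spec <- spec |>
    mutate(is_reference = .data$level == unname(ref[.data$covariate])) |>
    arrange(factor(.data$covariate, levels = reg$covariate))

  structure(
    spec,
    class = c("population_spec", class(spec)),
    source = source,
    reference_levels = ref[unique(spec$covariate)]
  )
}

#' Sample synthetic patient profiles
#'
#' Draws `n` patients by independent sampling of each categorical covariate
#' from its marginal distribution. Covariate marginals only are published,
#' so levels are sampled independently; see the methods vignette for what
#' this does and does not emulate. Draws come from per-patient counter
#' streams, so the first `k` patients of a cohort of `n > k` are identical
#' to a cohort of `k` sampled with the same seed.
#'
#' @param spec a `population_spec` from [load_population_spec()].
#' @param n number of patients (>= 0).
#' @param seed master seed (integer).
#' @return Tibble with one row per patient: `id` plus one column per
#'   covariate holding level labels.
#' @examples
#' spec <- load_population_spec()
#' pts <- sample_patients(spec, 5, seed = 1)
#' @export
sample_patients <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(n) != 1 || is.na(n) || n < 0) abort("n must be a single nonnegative count")
  n <- as.integer(n)
  covs <- unique(spec$covariate)
  out <- tibble(id = seq_len(n))
  if (n == 0) {
    for (cv in covs) out[[cv]] <- character(0)
    return(out)
  }
  for (k in seq_along(covs)) {
    d <- spec[spec$covariate == covs[k], ]
    u <- counter_uniforms(seed, out$id, 2000 + k)
    idx <- findInterval(u, cumsum(d$prob)) + 1L
    idx[idx > nrow(d)] <- nrow(d) # guard against cumulative rounding
    out[[covs[k]]] <- d$level[idx]
  }
  out
}

#' Validate a user-supplied patient table
#'
#' Checks that every covariate column is present and every value is a known
#' level of the population specification.
#'
#' @param patients tibble, one row per patient, level labels as values.
#' @param spec a `population_spec`.
#' @return `patients`, invisibly, with an `id` column added if missing.
#' @export
validate_patients <- function(patients, spec) {
  covs <- unique(spec$covariate)
  missing_cols <- setdiff(covs, names(patients))
  if (length(missing_cols) > 0) {
    abort(paste0("patient table missing covariate(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (cv in covs) {
    ok <- patients[[cv]] %in% spec$level[spec$covariate == cv]
    if (!all(ok)) {
      bad <- unique(patients[[cv]][!ok])
      abort(sprintf("unknown level(s) for '%s': %s", cv, paste(bad, collapse = ", ")))
    }
  }
  if (!"id" %in% names(patients)) patients <- mutate(patients, id = row_number(), .before = 1)
  invisible(patients)
}

#' Assign risk strata by predicted event times
#'
#' Tags each patient with the within-cohort quartile of its predicted median
#' time to first rehospitalization and to death (baseline equations: no RPM
#' effect, no hospitalization history). Quartile 1 holds the shortest
#' predicted times (highest risk), quartile 4 the longest, yielding the
#' 4 x 4 grid of death-by-rehospitalization strata used for subgroup
#' scenarios. Published stratum cutpoints are not available, so these
#' quartiles are an approximation.
#'
#' @param patients patient tibble from [sample_patients()].
#' @param rehosp_model,death_model `aft_model` objects (see
#'   [load_aft_models()]).
#' @return `patients` with added integer columns `rehosp_quartile` and
#'   `death_quartile`.
#' @export
assign_risk_strata <- function(patients, rehosp_model, death_model) {
  if (nrow(patients) < 4) abort("need at least 4 patients to form quartiles")
  med_r <- median_event_time(rehosp_model, linear_predictor(patients, rehosp_model))
  med_d <- median_event_time(death_model, linear_predictor(patients, death_model))
  patients |>
    mutate(
      rehosp_quartile = quartile_bin(med_r),
      death_quartile = quartile_bin(med_d)
    )
}

# quartile index with ties kept together (identical values share a bin)
quartile_bin <- function(x) {
  breaks <- unique(quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7))
  findInterval(x, breaks, left.open = TRUE) + 1L
}
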