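#' Day population build-up takes off
#'
#' First day on which adult density reaches a stated fraction of the carrying
#' capacity (default 5%), marking the start of exponential build-up.
#'
#' @param trajectory Trajectory data frame with `day` and an adult-density
#'   column.
#' @param K Carrying capacity, adults per leaf.
#' @param threshold_fraction Take-off threshold as a fraction of `K`, in (0, 1).
#' @param adults_col Name of the adult-density column.
#' @return Day index, or `NA_integer_` if the threshold is never reached.
#' @export
takeoff_day <- function(trajectory, K, threshold_fraction = 0.05,
                        adults_col = "adults") {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("`threshold_fraction` must lie in (0, 1)", call. = FALSE)
  }
  hit <- which(trajectory[[adults_col]] >= threshold_fraction * K)
  if (length(hit) == 0L) NA_integer_ else as.integer(trajectory$day[hit[1L]])
}

#' Steady-state adult density of a trajectory
#'
#' Mean adult density over the final `window_days` days of the run.
#'
#' @inheritParams takeoff_day
#' @param window_days Averaging window, days (shorter than the trajectory).
#' @return Mean adult density, adults per leaf.
#' @export
steady_state_adults <- function(trajectory, window_days = 60L,
                                adults_col = "adults") {
  n <- nrow(trajectory)
  if (n <= window_days) {
    stop("trajectory shorter than the steady-state window", call. = FALSE)
  }
  mean(trajectory[[adults_col]][(n - window_days + 1L):n])
}

#' Percent reduction of a treated value relative to wild type
#'
#' @param wt_value Wild-type (baseline) value (> 0).
#' @param treated_value Treated value.
#' @return `100 * (1 - treated_value / wt_value)`.
#' @export
percent_reduction <- function(wt_value, treated_value) {
  if (wt_value <= 0) stop("wild-type baseline must be positive", call. = FALSE)
  100 * (1 - treated_value / wt_value)
}

.scenario_metrics <- function(traj, K, wt_ss, wt_take, g,
                              threshold_fraction, window_days,
                              adults_col = "adults") {
  ss <- steady_state_adults(traj, window_days, adults_col)
  take <- takeoff_day(traj, K, threshold_fraction, adults_col)
  data.frame(
    steady_state_adults = ss,
    takeoff_day = take,
    generations_delayed = if (is.na(take) || is.na(wt_take)) NA_real_ else (take - wt_take) / g,
    percent_reduction = percent_reduction(wt_ss, ss)
  )
}

#' Run the treatment-intensity x stage-targeting scenario grid
#'
#' Simulates one wild-type baseline plus one run per (intensity, mode), where
#' the per-generation kill fractions are set from the intensity according to
#' the mode: `both` sets adult and nymph fractions equal to the intensity,
#' `nymph_only` and `adult_only` set one and leave the other at zero. Reports
#' steady-state adult density, take-off day, generations of delay relative to
#' wild type, and percent steady-state reduction.
#'
#' @param rates_list Named list of field-adjusted [daily_rates()].
#' @param temps Daily temperatures.
#' @param gamma Density-dependence coefficient.
#' @param K Carrying capacity (take-off threshold reference).
#' @param intensities Per-generation kill percentages (0-100).
#' @param modes Subset of `c("both", "nymph_only", "adult_only")`.
#' @param reference_temp Temperature at which the generation length `g` is
#'   computed.
#' @param threshold_fraction,window_days Metric parameters (see
#'   [takeoff_day()], [steady_state_adults()]).
#' @param init Initial abundances.
#' @return Data frame, one row per scenario (wild type first).
#' @export
run_treatment_grid <- function(rates_list, temps, gamma, K,
                               intensities = c(30, 40, 50, 60, 70, 80),
                               modes = c("both", "nymph_only", "adult_only"),
                               reference_temp = 28,
                               threshold_fraction = 0.05,
                               window_days = 60L,
                               init = c(0, 0, 0, 1)) {
  if (any(intensities < 0 | intensities > 100)) {
    stop("intensities are percentages in [0, 100]", call. = FALSE)
  }
  modes <- match.arg(modes, several.ok = TRUE)
  g <- generation_time(reference_rates(rates_list, reference_temp))
  wt <- simulate_population(rates_list, temps, gamma, init = init)
  wt_ss <- steady_state_adults(wt, window_days)
  wt_take <- takeoff_day(wt, K, threshold_fraction)
  rows <- list(cbind(
    data.frame(scenario = "wild_type", mode = "wild_type", intensity = 0),
    .scenario_metrics(wt, K, wt_ss, wt_take, g, threshold_fraction, window_days)
  ))
  for (mode in modes) {
    for (p in intensities) {
      tr <- switch(mode,
        both = treatment_spec(P_A = p / 100, P_L = p / 100, g = g),
        nymph_only = treatment_spec(P_A = 0, P_L = p / 100, g = g),
        adult_only = treatment_spec(P_A = p / 100, P_L = 0, g = g)
      )
      sim <- simulate_population(rates_list, temps, gamma, init = init, treatment = tr)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = sprintf("%s_%d", mode, p), mode = mode, intensity = p),
        .scenario_metrics(sim, K, wt_ss, wt_take, g, threshold_fraction, window_days)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the coverage x migration scenario grid
#'
#' For each combination of transgenic landscape coverage and maximum daily
#' migration rate, simulates the two-patch model (wild-type plot feeding adult
#' migrants into the transgenic plot) and reports transgenic-patch metrics.
#' The default treatment is a constant 60% per-generation reduction of both
#' nymph development and adult survival.
#'
#' @inheritParams run_treatment_grid
#' @param coverages Transgenic landscape coverage fractions.
#' @param m_max_values Maximum daily migration fractions.
#' @param treatment A [treatment_spec()] for the transgenic patch; by default
#'   60% on both stages with `g` from `reference_temp`.
#' @return Data frame, one row per (coverage, m_max) plus a wild-type baseline
#'   row.
#' @export
run_coverage_grid <- function(rates_list, temps, gamma, K,
                              coverages = c(0.2, 0.4, 0.6, 0.8),
                              m_max_values = c(0.01, 0.10),
                              treatment = NULL,
                              reference_temp = 28,
                              threshold_fraction = 0.05,
                              window_days = 60L,
                              init = c(0, 0, 0, 1)) {
  g <- generation_time(reference_rates(rates_list, reference_temp))
  if (is.null(treatment)) treatment <- treatment_spec(P_A = 0.6, P_L = 0.6, g = g)
  wt <- simulate_population(rates_list, temps, gamma, init = init)
  wt_ss <- steady_state_adults(wt, window_days)
  wt_take <- takeoff_day(wt, K, threshold_fraction)
  rows <- list(cbind(
    data.frame(scenario = "wild_type", coverage = NA_real_, m_max = NA_real_),
    .scenario_metrics(wt, K, wt_ss, wt_take, g, threshold_fraction, window_days)
  ))
  for (mm in m_max_values) {
    for (cv in coverages) {
      sim <- simulate_two_patch(
        rates_list, temps, gamma, treatment,
        migration_spec(m_max = mm, coverage = cv),
        init_wt = init, init_tg = init
      )
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = sprintf("cov%.2f_m%.2f", cv, mm), coverage = cv, m_max = mm),
        .scenario_metrics(sim, K, wt_ss, wt_take, g, threshold_fraction,
                          window_days, adults_col = "tg_adults")
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
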