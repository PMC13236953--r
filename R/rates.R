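IMMATURE_STAGES <- c("egg", "nymph", "pupa")

#' Daily per-stage transition rates
#'
#' The model's per-day probabilities for each immature stage (egg, nymph,
#' pupa): advance to the next stage with probability `r`, die with probability
#' `d`, or stay with probability `s = 1 - r - d`. Adults die with daily
#' probability `d_adult` and lay `fecundity` eggs per day.
#'
#' @param r,d Length-3 numeric vectors (egg, nymph, pupa) of daily development
#'   and mortality probabilities; `r + d <= 1` per stage.
#' @param d_adult Daily adult mortality probability.
#' @param fecundity Eggs per adult per day.
#' @param temperature Temperature (degrees C) these rates correspond to.
#' @return An object of class `daily_rates`.
#' @export
daily_rates <- function(r, d, d_adult, fecundity, temperature = NA_real_) {
  stopifnot(length(r) == 3L, length(d) == 3L)
  if (any(r < 0 | r > 1) || any(d < 0 | d > 1)) {
    stop("daily probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(r + d > 1 + 1e-12)) {
    stop("r + d exceeds 1 for an immature stage", call. = FALSE)
  }
  if (d_adult < 0 || d_adult > 1) stop("`d_adult` must lie in [0, 1]", call. = FALSE)
  if (fecundity < 0) stop("`fecundity` must be non-negative", call. = FALSE)
  r <- stats::setNames(as.numeric(r), IMMATURE_STAGES)
  d <- stats::setNames(as.numeric(d), IMMATURE_STAGES)
  structure(
    list(r = r, d = d, s = stats::setNames(pmax(0, 1 - r - d), IMMATURE_STAGES),
         d_adult = d_adult,
         fecundity = fecundity, temperature = temperature),
    class = "daily_rates"
  )
}

#' Daily development probability from a median development time
#'
#' @param m Median development time in days (>= 1).
#' @return `1 / m`.
#' @export
daily_development_rate <- function(m) {
  if (any(m < 1)) stop("median development time must be at least 1 day", call. = FALSE)
  1 / m
}

#' Daily mortality probability from a stage survival fraction
#'
#' @param stage_survival Fraction of the cohort surviving the stage, in (0, 1].
#' @return `1 - stage_survival`.
#' @export
daily_mortality_rate <- function(stage_survival) {
  if (any(stage_survival <= 0 | stage_survival > 1)) {
    stop("stage survival must lie in (0, 1]", call. = FALSE)
  }
  1 - stage_survival
}

#' Aggregate four nymphal instars into one model stage
#'
#' Combines the instar-level median development times `T1..T4` and mortality
#' fractions `N1..N4` into single nymph-stage daily rates: the development rate
#' is the reciprocal of the total development time, and the mortality rate is
#' the duration-weighted mean of the instar mortalities.
#'
#' @param T_dev Numeric length-4: instar median development times, days (>= 1).
#' @param N_mort Numeric length-4: instar mortality fractions in [0, 1).
#' @return List with `r`, `d`, `s` for the aggregated nymph stage.
#' @export
aggregate_nymph <- function(T_dev, N_mort) {
  stopifnot(length(T_dev) == 4L, length(N_mort) == 4L)
  if (any(T_dev < 1)) stop("instar development times must be >= 1 day", call. = FALSE)
  if (any(N_mort < 0 | N_mort >= 1)) stop("instar mortalities must lie in [0, 1)", call. = FALSE)
  total <- sum(T_dev)
  r <- 1 / total
  d <- sum(T_dev * N_mort) / total
  if (r + d > 1) {
    stop("inconsistent life table: aggregated nymph r + d exceeds 1", call. = FALSE)
  }
  list(r = r, d = d, s = 1 - r - d)
}

#' Convert life tables to daily rates
#'
#' Applies the reciprocal-duration development rule, the survival-complement
#' mortality rule and nymphal aggregation to each row of a life table (one row
#' per anchor temperature, schema of [generate_life_tables()]).
#'
#' @param life_tables Data frame as produced by [generate_life_tables()].
#' @return Named list of [daily_rates()], keyed by temperature.
#' @export
life_table_to_rates <- function(life_tables) {
  out <- lapply(seq_len(nrow(life_tables)), function(i) {
    row <- life_tables[i, ]
    ny <- aggregate_nymph(
      c(row$T1, row$T2, row$T3, row$T4),
      1 - c(row$s_n1, row$s_n2, row$s_n3, row$s_n4)
    )
    daily_rates(
      r = c(daily_development_rate(row$m_egg), ny$r, daily_development_rate(row$m_pupa)),
      d = c(daily_mortality_rate(row$s_egg), ny$d, daily_mortality_rate(row$s_pupa)),
      d_adult = 1 - row$s_adult,
      fecundity = row$fecundity,
      temperature = row$temperature
    )
  })
  stats::setNames(out, as.character(life_tables$temperature))
}

#' Pick the rates at (or nearest to) a reference temperature
#'
#' @param rates_list Named list of [daily_rates()] keyed by temperature.
#' @param temperature Reference temperature, degrees C.
#' @return The element of `rates_list` with the nearest temperature.
#' @export
reference_rates <- function(rates_list, temperature = 28) {
  temps <- vapply(rates_list, function(x) x$temperature, numeric(1))
  rates_list[[which.min(abs(temps - temperature))]]
}

#' Probability an egg eventually emerges as an adult
#'
#' Under the daily stay/advance/die chain, the probability of eventually
#' leaving an immature stage alive is `r / (r + d)`, so egg-to-adult emergence
#' is the product of that ratio over egg, nymph and pupa stages.
#'
#' @param rates A [daily_rates()] object.
#' @return Emergence probability in [0, 1].
#' @export
emergence_probability <- function(rates) {
  if (any(rates$r + rates$d == 0)) {
    stop("degenerate rates: r + d = 0 for an immature stage", call. = FALSE)
  }
  prod(rates$r / (rates$r + rates$d))
}

#' Add a uniform daily field mortality to the immature stages
#'
#' @param rates A [daily_rates()] object.
#' @param q Additional daily mortality probability applied to egg, nymph and
#'   pupa stages (adults untouched).
#' @return Adjusted [daily_rates()].
#' @export
add_field_mortality <- function(rates, q) {
  if (q < 0) stop("`q` must be non-negative", call. = FALSE)
  d_new <- rates$d + q
  if (any(rates$r + d_new > 1 + 1e-12)) {
    stop("field adjustment `q` pushes r + d above 1", call. = FALSE)
  }
  daily_rates(rates$r, pmin(d_new, 1 - rates$r), rates$d_adult,
              rates$fecundity, rates$temperature)
}

#' Calibrate the field-mortality adjustment q
#'
#' Solves by bisection for the single additive daily mortality `q`, applied
#' uniformly to egg, nymph and pupa stages, under which the analytic
#' egg-to-adult emergence probability equals the target field emergence rate
#' (default 10%, the level reported for whitefly field populations).
#'
#' @param rates Laboratory [daily_rates()].
#' @param target_emergence Target emergence probability in
#'   (0, `emergence_probability(rates)`].
#' @param tol Absolute tolerance on the emergence probability at the solution.
#' @return The calibrated `q` (>= 0).
#' @export
calibrate_field_adjustment <- function(rates, target_emergence = 0.10, tol = 1e-10) {
  base <- emergence_probability(rates)
  if (target_emergence <= 0 || target_emergence > base) {
    stop("infeasible target: must lie in (0, baseline emergence = ",
         signif(base, 4), "]", call. = FALSE)
  }
  if (target_emergence == base) return(0)
  # s = 1 - r - d is the available slack; beyond it probabilities break
  q_hi <- min(rates$s)
  f <- function(q) emergence_probability(add_field_mortality(rates, q)) - target_emergence
  if (f(q_hi) > 0) {
    stop("infeasible target: unreachable within valid daily probabilities", call. = FALSE)
  }
  lo <- 0
  hi <- q_hi
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-generation transgenic kill fractions
#'
#' A treatment removes a fraction `P_A` of adults and `P_L` of nymphs per
#' generation of `g` days; [apply_treatment()] converts these to daily
#' mortality increments `1 - (1 - P)^(1/g)` that compound back to `P` over a
#' generation.
#'
#' @param P_A,P_L Per-generation adult and nymph kill fractions in [0, 1].
#' @param g Generation length in days (>= 1).
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(P_A = 0, P_L = 0, g = 20) {
  if (P_A < 0 || P_A > 1 || P_L < 0 || P_L > 1) {
    stop("kill fractions must lie in [0, 1]", call. = FALSE)
  }
  if (g < 1) stop("generation length must be at least 1 day", call. = FALSE)
  structure(list(P_A = P_A, P_L = P_L, g = g), class = "treatment_spec")
}

#' Apply a transgenic treatment to daily rates
#'
#' Adds the daily mortality increment `1 - (1 - P_A)^(1/g)` to adults and
#' `1 - (1 - P_L)^(1/g)` to nymphs, on top of the baseline daily mortality.
#' Probabilities are capped at 1; if the boosted nymph mortality would leave
#' no room for development (`r + d > 1`) the advance probability is reduced so
#' probabilities stay valid (stay probability floored at 0).
#'
#' @param rates A [daily_rates()] object.
#' @param treatment A [treatment_spec()].
#' @return Treated [daily_rates()].
#' @export
apply_treatment <- function(rates, treatment) {
  stopifnot(inherits(treatment, "treatment_spec"))
  extra_a <- 1 - (1 - treatment$P_A)^(1 / treatment$g)
  extra_l <- 1 - (1 - treatment$P_L)^(1 / treatment$g)
  d <- rates$d
  r <- rates$r
  d["nymph"] <- min(1, d["nymph"] + extra_l)
  if (r["nymph"] + d["nymph"] > 1) r["nymph"] <- 1 - d["nymph"]
  daily_rates(r, d, min(1, rates$d_adult + extra_a),
              rates$fecundity, rates$temperature)
}

#' Expected egg-to-adult generation time
#'
#' Sum of expected stage durations `1 / r` over the immature stages, rounded
#' to the nearest day. Used to convert per-generation kill fractions into
#' daily increments.
#'
#' @param rates A [daily_rates()] object with all development rates positive.
#' @return Generation length in whole days.
#' @export
generation_time <- function(rates) {
  if (any(rates$r == 0)) {
    stop("degenerate rates: zero development rate for an immature stage", call. = FALSE)
  }
  round(sum(1 / rates$r))
}
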