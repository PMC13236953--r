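STAGES <- c("eggs", "nymphs", "pupae", "adults")

#' Build the 4x4 daily stage-transition (Leslie) matrix
#'
#' Stage order (eggs, nymphs, pupae, adults). Diagonal entries are the daily
#' stay probabilities (adults: daily survival `1 - d_adult`), the subdiagonal
#' carries the daily advance probabilities, and the top-right entry is daily
#' fecundity (eggs laid per adult per day).
#'
#' @param rates A [daily_rates()] object.
#' @return A 4x4 matrix with a `temperature` attribute.
#' @export
build_matrix <- function(rates) {
  M <- matrix(0, 4, 4, dimnames = list(STAGES, STAGES))
  M[1, 1] <- rates$s[["egg"]]
  M[2, 1] <- rates$r[["egg"]]
  M[2, 2] <- rates$s[["nymph"]]
  M[3, 2] <- rates$r[["nymph"]]
  M[3, 3] <- rates$s[["pupa"]]
  M[4, 3] <- rates$r[["pupa"]]
  M[4, 4] <- 1 - rates$d_adult
  M[1, 4] <- rates$fecundity
  attr(M, "temperature") <- rates$temperature
  M
}

#' Assemble anchor matrices from per-temperature rates
#'
#' @param rates_list Named list of [daily_rates()] (one per anchor
#'   temperature).
#' @return List with sorted `temps` and the corresponding `mats`.
#' @export
anchor_matrices <- function(rates_list) {
  temps <- vapply(rates_list, function(x) x$temperature, numeric(1))
  ord <- order(temps)
  list(temps = unname(temps[ord]), mats = unname(lapply(rates_list[ord], build_matrix)))
}

#' Interpolate the transition matrix at an arbitrary temperature
#'
#' Element-wise linear interpolation between the two bracketing anchor
#' matrices, weighted by the fractional distance of `temperature` between the
#' anchors. Temperatures at an anchor return that anchor's matrix exactly;
#' temperatures outside the anchor range are clamped to the nearest anchor.
#'
#' @param anchors Output of [anchor_matrices()].
#' @param temperature Temperature, degrees C.
#' @return A 4x4 transition matrix.
#' @export
interpolate_matrix <- function(anchors, temperature) {
  tt <- anchors$temps
  n <- length(tt)
  temp <- min(max(temperature, tt[1]), tt[n])
  i <- findInterval(temp, tt, rightmost.closed = TRUE)
  if (tt[i] == temp) return(anchors$mats[[i]])
  w <- (temp - tt[i]) / (tt[i + 1] - tt[i])
  (1 - w) * anchors$mats[[i]] + w * anchors$mats[[i + 1]]
}

#' Advance the population by one day
#'
#' Multiplies the abundance vector by the daily transition matrix, then
#' applies density-dependent adult mortality: `gamma * adults^2` is subtracted
#' from the adult class (clamped at zero). All abundances are clamped at zero.
#'
#' @param state Length-4 numeric abundance vector (eggs, nymphs, pupae,
#'   adults), individuals per leaf.
#' @param M 4x4 transition matrix.
#' @param gamma Density-dependence coefficient (>= 0), per (individuals per
#'   leaf) per day.
#' @return Updated length-4 abundance vector.
#' @export
step_population <- function(state, M, gamma = 0) {
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  x <- as.vector(M %*% state)
  x[4] <- x[4] - gamma * x[4]^2
  x[x < 0] <- 0
  x
}

#' Simulate single-population dynamics over a temperature series
#'
#' Each day the transition matrix is interpolated at that day's temperature
#' and the population is advanced with [step_population()]. If a treatment is
#' supplied, the anchor rates are first passed through [apply_treatment()], so
#' the whole run uses transgenic matrices.
#'
#' @param rates_list Named list of [daily_rates()] at the anchor temperatures.
#' @param temps Numeric vector of daily mean temperatures (degrees C), or a
#'   data frame with a `temperature` column.
#' @param gamma Density-dependence coefficient.
#' @param init Initial abundances (eggs, nymphs, pupae, adults) per leaf.
#' @param horizon Number of days to simulate (<= `length(temps)`).
#' @param treatment Optional [treatment_spec()].
#' @return Data frame with columns `day` (0..horizon), `temperature` (NA on
#'   day 0) and the four stage abundances.
#' @export
simulate_population <- function(rates_list, temps, gamma,
                                init = c(0, 0, 0, 1),
                                horizon = NULL,
                                treatment = NULL) {
  if (is.data.frame(temps)) temps <- temps$temperature
  if (is.null(horizon)) horizon <- length(temps)
  if (horizon > length(temps)) {
    stop("`horizon` exceeds the length of the temperature series", call. = FALSE)
  }
  if (!is.null(treatment)) {
    rates_list <- lapply(rates_list, apply_treatment, treatment = treatment)
  }
  anchors <- anchor_matrices(rates_list)
  out <- matrix(0, nrow = horizon + 1L, ncol = 4L,
                dimnames = list(NULL, STAGES))
  state <- as.numeric(init)
  out[1L, ] <- state
  for (d in seq_len(horizon)) {
    M <- interpolate_matrix(anchors, temps[d])
    state <- step_population(state, M, gamma)
    out[d + 1L, ] <- state
  }
  data.frame(
    day = 0:horizon,
    temperature = c(NA_real_, temps[seq_len(horizon)]),
    out
  )
}

#' Calibrate the density-dependence coefficient gamma
#'
#' Finds, by bisection on `log10(gamma)`, the coefficient under which the
#' wild-type steady-state adult density at a constant reference temperature
#' equals the target carrying capacity `K`. Steady state is measured as the
#' mean adult density over the final `window_days` of a `days`-long run
#' started from one adult per leaf.
#'
#' @param rates_list Named list of [daily_rates()] at the anchor temperatures
#'   (field-adjusted wild-type rates).
#' @param K Target carrying capacity, adults per leaf (default 500).
#' @param ref_temp Constant calibration temperature, degrees C.
#' @param days,window_days Run length and steady-state averaging window, days.
#' @return Calibrated `gamma` (> 0).
#' @export
calibrate_density_dependence <- function(rates_list, K = 500, ref_temp = 28,
                                         days = 730L, window_days = 60L) {
  anchors <- anchor_matrices(rates_list)
  M <- interpolate_matrix(anchors, ref_temp)
  lambda <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (lambda <= 1) {
    stop("infeasible calibration: population does not grow at ", ref_temp,
         " degrees C (dominant eigenvalue ", signif(lambda, 4), ")", call. = FALSE)
  }
  ss_at <- function(gamma) {
    state <- c(0, 0, 0, 1)
    acc <- 0
    for (d in seq_len(days)) {
      state <- step_population(state, M, gamma)
      if (d > days - window_days) acc <- acc + state[4]
    }
    acc / window_days
  }
  lo <- -10   # log10(gamma): 1e-10 leaves the population far above any K
  hi <- 0
  if (ss_at(10^lo) < K) stop("carrying-capacity target above the undamped steady state", call. = FALSE)
  if (ss_at(10^hi) > K) stop("carrying-capacity target below the gamma = 1 steady state", call. = FALSE)
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (ss_at(10^mid) > K) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}
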