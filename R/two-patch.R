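#' Migration specification for a mixed transgenic landscape
#'
#' `m_max` is the maximum daily fraction of wild-type-patch adults that move
#' into the transgenic patch; immigration pressure on a transgenic plot scales
#' with the surrounding wild-type area, so the effective daily fraction is
#' `m_max * (1 - coverage)`.
#'
#' @param m_max Maximum daily adult migration fraction in [0, 1].
#' @param coverage Fraction of the landscape planted transgenic, in [0, 1].
#' @return An object of class `migration_spec`.
#' @export
migration_spec <- function(m_max, coverage) {
  if (m_max < 0 || m_max > 1 || coverage < 0 || coverage > 1) {
    stop("`m_max` and `coverage` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(m_max = m_max, coverage = coverage), class = "migration_spec")
}

#' Effective daily wild-type-to-transgenic migration fraction
#'
#' @param spec A [migration_spec()].
#' @return `m_max * (1 - coverage)`.
#' @export
effective_migration <- function(spec) {
  spec$m_max * (1 - spec$coverage)
}

#' Build the 8x8 two-patch transition matrix
#'
#' Block-diagonal placement of the wild-type (upper-left) and transgenic
#' (lower-right) 4x4 matrices, coupled only through adult movement from the
#' wild-type patch to the transgenic patch: the wild-type adult stay entry is
#' scaled by `1 - m` and the coupling entry (transgenic-adult row, wild-type-
#' adult column) is `m` times the wild-type daily adult survival, i.e.
#' migrants move and then survive the day at the wild-type rate. There is no
#' transgenic-to-wild-type flow.
#'
#' @param M_wt,M_tg 4x4 transition matrices for the two patches.
#' @param m Daily adult migration fraction in [0, 1].
#' @return An 8x8 matrix (stages 1-4: wild-type patch, 5-8: transgenic patch).
#' @export
build_two_patch_matrix <- function(M_wt, M_tg, m) {
  if (m < 0 || m > 1) stop("`m` must lie in [0, 1]", call. = FALSE)
  M8 <- matrix(0, 8, 8)
  M8[1:4, 1:4] <- M_wt
  M8[5:8, 5:8] <- M_tg
  M8[4, 4] <- M_wt[4, 4] * (1 - m)
  M8[8, 4] <- M_wt[4, 4] * m
  M8
}

#' Simulate coupled wild-type and transgenic patches
#'
#' Daily 8x8 projection with per-patch density-dependent adult mortality
#' (`gamma * adults^2` subtracted within each patch). The wild-type patch uses
#' untreated matrices; the transgenic patch uses matrices rebuilt from
#' [apply_treatment()]-ed rates. Temperature interpolation follows the
#' single-population model.
#'
#' @param rates_list Named list of [daily_rates()] at the anchor temperatures
#'   (field-adjusted wild-type rates).
#' @param temps Daily temperatures (vector or data frame with `temperature`).
#' @param gamma Density-dependence coefficient (applied within each patch).
#' @param treatment A [treatment_spec()] for the transgenic patch.
#' @param migration A [migration_spec()] or a plain daily fraction in [0, 1].
#' @param init_wt,init_tg Initial abundances per patch.
#' @param horizon Days to simulate (<= `length(temps)`).
#' @return Data frame with `day`, `temperature` and eight abundance columns
#'   (`wt_eggs` .. `wt_adults`, `tg_eggs` .. `tg_adults`).
#' @export
simulate_two_patch <- function(rates_list, temps, gamma, treatment, migration,
                               init_wt = c(0, 0, 0, 1),
                               init_tg = c(0, 0, 0, 1),
                               horizon = NULL) {
  if (is.data.frame(temps)) temps <- temps$temperature
  if (is.null(horizon)) horizon <- length(temps)
  if (horizon > length(temps)) {
    stop("`horizon` exceeds the length of the temperature series", call. = FALSE)
  }
  m <- if (inherits(migration, "migration_spec")) effective_migration(migration) else migration
  anchors_wt <- anchor_matrices(rates_list)
  anchors_tg <- anchor_matrices(lapply(rates_list, apply_treatment, treatment = treatment))
  cols <- c(paste0("wt_", STAGES), paste0("tg_", STAGES))
  out <- matrix(0, nrow = horizon + 1L, ncol = 8L, dimnames = list(NULL, cols))
  state <- c(as.numeric(init_wt), as.numeric(init_tg))
  out[1L, ] <- state
  for (d in seq_len(horizon)) {
    M8 <- build_two_patch_matrix(
      interpolate_matrix(anchors_wt, temps[d]),
      interpolate_matrix(anchors_tg, temps[d]),
      m
    )
    state <- as.vector(M8 %*% state)
    state[4] <- state[4] - gamma * state[4]^2
    state[8] <- state[8] - gamma * state[8]^2
    state[state < 0] <- 0
    out[d + 1L, ] <- state
  }
  data.frame(
    day = 0:horizon,
    temperature = c(NA_real_, temps[seq_len(horizon)]),
    out
  )
}
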