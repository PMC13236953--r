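test_that("the daily transition matrix is laid out stage by stage", {
  rt <- daily_rates(r = c(0.1, 0.0625, 0.2), d = c(0.05, 0.14375, 0.05),
                    d_adult = 0.05, fecundity = 5, temperature = 28)
  M <- build_matrix(rt)
  expect_equal(M[1, 1], 0.85)       # egg stay
  expect_equal(M[2, 1], 0.1)        # egg -> nymph
  expect_equal(M[2, 2], 0.79375)    # nymph stay
  expect_equal(M[3, 2], 0.0625)     # nymph -> pupa
  expect_equal(M[3, 3], 0.75)       # pupa stay
  expect_equal(M[4, 3], 0.2)        # pupa -> adult
  expect_equal(M[4, 4], 0.95)       # adult survival
  expect_equal(M[1, 4], 5)          # fecundity
  expect_equal(sum(M != 0), 8)

  # degenerate case: no advancement, no death, no reproduction -> identity
  frozen <- daily_rates(c(0, 0, 0), c(0, 0, 0), d_adult = 0, fecundity = 0)
  I4 <- build_matrix(frozen)
  expect_equal(unname(I4), diag(4), ignore_attr = TRUE)
  st <- c(3, 1, 4, 1)
  expect_equal(step_population(st, I4, gamma = 0), st)
})

test_that("without reproduction the population only decays", {
  rt <- daily_rates(r = c(0.1, 0.0625, 0.2), d = c(0.05, 0.14375, 0.05),
                    d_adult = 0.05, fecundity = 0, temperature = 28)
  sim <- simulate_population(list(`28` = rt, `32` = daily_rates(
    r = c(0.1, 0.0625, 0.2), d = c(0.05, 0.14375, 0.05),
    d_adult = 0.05, fecundity = 0, temperature = 32
  )), rep(28, 400), gamma = 0, init = c(100, 50, 20, 10))
  totals <- rowSums(sim[, c("eggs", "nymphs", "pupae", "adults")])
  expect_true(all(diff(totals) <= 1e-12))
  expect_lt(totals[length(totals)], 1e-3)
  expect_true(all(sim[, c("eggs", "nymphs", "pupae", "adults")] >= 0))
})

test_that("matrix interpolation is exact at anchors, linear between, clamped outside", {
  anchors <- anchor_matrices(fixture_rates())
  i24 <- which(anchors$temps == 24)
  expect_identical(interpolate_matrix(anchors, 24), anchors$mats[[i24]])
  M26 <- interpolate_matrix(anchors, 26)
  expect_equal(M26, 0.5 * anchors$mats[[i24]] + 0.5 * anchors$mats[[i24 + 1]],
               ignore_attr = TRUE)
  expect_equal(interpolate_matrix(anchors, 33), anchors$mats[[length(anchors$temps)]],
               ignore_attr = TRUE)
  expect_equal(interpolate_matrix(anchors, 10), anchors$mats[[1]],
               ignore_attr = TRUE)
  # continuity across an anchor
  eps <- 1e-9
  expect_equal(interpolate_matrix(anchors, 24 - eps),
               interpolate_matrix(anchors, 24 + eps),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the daily step applies quadratic adult mortality after projection", {
  I4 <- diag(4)
  expect_equal(step_population(c(0, 0, 0, 0), I4, 0.001), c(0, 0, 0, 0))
  # adults = 100 after projection, gamma = 0.001 -> 100 - 0.001 * 100^2 = 90
  expect_equal(step_population(c(0, 0, 0, 100), I4, 0.001)[4], 90)
  # severe density dependence clamps at zero rather than going negative
  expect_equal(step_population(c(0, 0, 0, 100), I4, 1)[4], 0)
  expect_error(step_population(c(0, 0, 0, 1), I4, -0.1), "non-negative")
})

test_that("simulation honors horizon, treatment identity and input lengths", {
  cal <- fixture_calibrated()
  temps <- rep(28, 100)
  sim0 <- simulate_population(cal$rates_q, temps, cal$gamma, horizon = 0)
  expect_equal(nrow(sim0), 1)
  expect_equal(unlist(sim0[1, c("eggs", "nymphs", "pupae", "adults")],
                      use.names = FALSE), c(0, 0, 0, 1))

  expect_error(simulate_population(cal$rates_q, temps, cal$gamma, horizon = 101),
               "exceeds")

  wt <- simulate_population(cal$rates_q, temps, cal$gamma)
  nul <- simulate_population(cal$rates_q, temps, cal$gamma,
                             treatment = treatment_spec(0, 0, 20))
  expect_identical(wt, nul)
})

test_that("calibrated wild-type dynamics settle on the analytic equilibrium", {
  cal <- fixture_calibrated()
  sim <- simulate_population(cal$rates_q, rep(28, 730), cal$gamma)
  ss <- steady_state_adults(sim, 60)
  expect_equal(ss, cal$K, tolerance = 0.01)
  # independent scalar fixed-point oracle at constant temperature
  a_star <- equilibrium_adults_oracle(cal$ref_q, cal$gamma)
  expect_equal(ss, a_star, tolerance = 0.01)
  # and the trajectory stays within 1% of K once settled
  late <- sim$adults[sim$day >= 500]
  expect_true(all(abs(late - cal$K) / cal$K < 0.01))
})

test_that("density-dependence calibration meets its contract and is monotone", {
  cal <- fixture_calibrated()
  temps <- rep(28, 730)
  expect_equal(steady_state_adults(simulate_population(cal$rates_q, temps, cal$gamma), 60),
               500, tolerance = 0.01)
  # doubling gamma strictly lowers the steady state
  ss2 <- steady_state_adults(simulate_population(cal$rates_q, temps, 2 * cal$gamma), 60)
  expect_lt(ss2, 500)
  # halving the target needs a larger coefficient
  g250 <- calibrate_density_dependence(cal$rates_q, K = 250)
  expect_gt(g250, cal$gamma)
  expect_equal(steady_state_adults(simulate_population(cal$rates_q, temps, g250), 60),
               250, tolerance = 0.01)
  # a population that cannot grow cannot be calibrated
  dead <- lapply(cal$rates_q, function(r) {
    daily_rates(r$r, r$d, r$d_adult, fecundity = 0, temperature = r$temperature)
  })
  expect_error(calibrate_density_dependence(dead, K = 500), "infeasible")
})
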