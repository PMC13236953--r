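test_that("elementary rate formulas and their guards hold", {
  expect_equal(daily_development_rate(1), 1.0)
  expect_equal(daily_development_rate(10), 0.1)
  expect_equal(daily_development_rate(16), 0.0625)
  expect_error(daily_development_rate(0.5), "at least 1 day")

  expect_equal(daily_mortality_rate(1), 0)
  expect_equal(daily_mortality_rate(0.9), 0.1)
  expect_equal(daily_mortality_rate(0.85), 0.15)
  expect_error(daily_mortality_rate(0), "\\(0, 1\\]")
  expect_error(daily_mortality_rate(1.1), "\\(0, 1\\]")
})

test_that("nymphal instar aggregation follows the duration-weighted rule", {
  a <- aggregate_nymph(c(5, 4, 3, 4), c(0, 0, 0, 0))
  expect_equal(a$r, 0.0625)
  expect_equal(a$d, 0)
  expect_equal(a$s, 0.9375)

  b <- aggregate_nymph(c(5, 4, 3, 4), c(0.1, 0.1, 0.2, 0.2))
  expect_equal(b$r, 0.0625)
  expect_equal(b$d, 0.14375)
  expect_equal(b$s, 0.79375)

  expect_error(aggregate_nymph(c(1, 1, 1, 1), c(0.9, 0.9, 0.9, 0.9)),
               "exceeds 1")
})

test_that("per-stage probabilities always partition into advance/die/stay", {
  set.seed(11)
  for (i in 1:25) {
    rt <- random_daily_rates()
    expect_equal(unname(rt$r + rt$d + rt$s), rep(1, 3))
    tr <- apply_treatment(rt, treatment_spec(P_A = runif(1), P_L = runif(1), g = 20))
    expect_equal(unname(tr$r + tr$d + tr$s), rep(1, 3))
    adj <- add_field_mortality(rt, min(rt$s) * runif(1))
    expect_equal(unname(adj$r + adj$d + adj$s), rep(1, 3))
  }
})

test_that("analytic emergence probability matches a brute-force cohort simulation", {
  worked <- daily_rates(r = c(0.1, 0.0625, 0.2), d = c(0.05, 0.14375, 0.05),
                        d_adult = 0.05, fecundity = 5)
  p <- emergence_probability(worked)
  expect_equal(p, (0.1 / 0.15) * (0.0625 / 0.20625) * (0.2 / 0.25))
  expect_equal(p, 0.1616, tolerance = 1e-3)

  expect_equal(emergence_probability(daily_rates(c(0.2, 0.1, 0.3), c(0, 0, 0),
                                                 0.05, 1)), 1.0)
  expect_error(emergence_probability(daily_rates(c(0, 0.1, 0.3), c(0, 0, 0),
                                                 0.05, 1)), "degenerate")

  set.seed(42)
  for (i in 1:20) {
    rt <- random_daily_rates()
    p_hat <- cohort_emergence(rt, n = 1e5)
    p_an <- emergence_probability(rt)
    se <- sqrt(p_an * (1 - p_an) / 1e5)
    expect_lt(abs(p_hat - p_an), 3 * se)
  }
})

test_that("field-mortality calibration round-trips to the target emergence", {
  worked <- daily_rates(r = c(0.1, 0.0625, 0.2), d = c(0.05, 0.14375, 0.05),
                        d_adult = 0.05, fecundity = 5)
  # fixed point: target equal to the baseline needs no adjustment
  expect_equal(calibrate_field_adjustment(worked, emergence_probability(worked)), 0)

  q <- calibrate_field_adjustment(worked, 0.10)
  expect_equal(q, 0.034, tolerance = 0.02)
  expect_equal(emergence_probability(add_field_mortality(worked, q)), 0.10,
               tolerance = 1e-6)

  expect_error(calibrate_field_adjustment(worked, 0.5), "infeasible")
  expect_error(calibrate_field_adjustment(worked, 0), "infeasible")

  # round-trip property on randomized rate sets
  set.seed(99)
  for (i in 1:10) {
    rt <- random_daily_rates()
    target <- emergence_probability(rt) * runif(1, 0.2, 0.9)
    qq <- calibrate_field_adjustment(rt, target)
    expect_equal(emergence_probability(add_field_mortality(rt, qq)), target,
                 tolerance = 1e-6)
  }
})

test_that("treatment converts per-generation kills to compounding daily mortality", {
  rt <- fixture_rates()[["28"]]

  expect_equal(apply_treatment(rt, treatment_spec(0, 0, 20)), rt)
  expect_equal(apply_treatment(rt, treatment_spec(P_A = 1, P_L = 0, g = 20))$d_adult, 1)

  g <- 20
  tr <- apply_treatment(rt, treatment_spec(P_A = 0.6, P_L = 0, g = g))
  extra <- tr$d_adult - rt$d_adult
  expect_equal(extra, 0.04478, tolerance = 1e-3)
  # compounding the daily increment over g days recovers the generation kill
  expect_equal((1 - extra)^g, 1 - 0.6, tolerance = 1e-10)

  # monotone: a larger kill fraction never increases survival
  pa <- seq(0, 1, by = 0.1)
  d_adults <- vapply(pa, function(p) apply_treatment(rt, treatment_spec(p, 0, g))$d_adult,
                     numeric(1))
  d_nymphs <- vapply(pa, function(p) apply_treatment(rt, treatment_spec(0, p, g))$d[["nymph"]],
                     numeric(1))
  expect_true(all(diff(d_adults) >= 0))
  expect_true(all(diff(d_nymphs) >= 0))
})

test_that("generation time is the summed expected stage duration", {
  rt <- daily_rates(r = c(0.1, 0.0625, 0.2), d = c(0, 0, 0), d_adult = 0.05,
                    fecundity = 1)
  expect_equal(generation_time(rt), 31)
  expect_equal(generation_time(daily_rates(c(1, 1, 1), c(0, 0, 0), 0, 0)), 3)
  expect_equal(generation_time(fixture_rates()[["28"]]), 20)
  expect_error(generation_time(daily_rates(c(0, 1, 1), c(0, 0, 0), 0, 0)),
               "degenerate")
})
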