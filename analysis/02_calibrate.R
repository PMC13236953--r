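#!/usr/bin/env Rscript
# Calibrate the two free parameters of the wild-type model:
#   q     -- additive daily field mortality on immature stages, so that
#            egg-to-adult emergence matches the ~10% observed in the field;
#   gamma -- density-dependence coefficient, so that the steady-state adult
#            density at constant 28 C equals the ~500 adults/leaf carrying
#            capacity.

suppressMessages(library(whiteflysim))
dir.create("results", showWarnings = FALSE)

life_tables <- read.csv("results/inputs/life_tables.csv")
rates <- life_table_to_rates(life_tables)
ref <- reference_rates(rates, 28)

base_emergence <- emergence_probability(ref)
q <- calibrate_field_adjustment(ref, target_emergence = 0.10)
rates_q <- lapply(rates, add_field_mortality, q = q)
message(sprintf("lab emergence at 28 C: %.1f%%; field target 10%% => q = %.5f/day",
                100 * base_emergence, q))

g <- generation_time(ref)
message("generation time at 28 C: ", g, " days")

gamma <- calibrate_density_dependence(rates_q, K = 500, ref_temp = 28)
traj <- simulate_population(rates_q, rep(28, 730), gamma)
ss <- steady_state_adults(traj, 60)
message(sprintf("gamma = %.4e => wild-type steady state %.1f adults/leaf at 28 C",
                gamma, ss))

write.csv(
  data.frame(parameter = c("q", "gamma", "generation_days",
                           "emergence_calibrated", "steady_state_adults"),
             value = c(q, gamma, g, emergence_probability(add_field_mortality(ref, q)), ss)),
  "results/calibration.csv", row.names = FALSE
)
message("wrote results/calibration.csv")
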