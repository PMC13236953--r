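#!/usr/bin/env Rscript
# Mixed-landscape scenarios: a transgenic plot (60% per-generation reduction
# of both nymph development and adult survival) coupled to a wild-type plot by
# daily adult migration. Coverage of the transgenic crop varies over
# 20-80% of the landscape; maximum migration is 1% or 10% per day.

suppressMessages(library(whiteflysim))

life_tables <- read.csv("results/inputs/life_tables.csv")
calib <- read.csv("results/calibration.csv")
q <- calib$value[calib$parameter == "q"]
gamma <- calib$value[calib$parameter == "gamma"]

rates_q <- lapply(life_table_to_rates(life_tables), add_field_mortality, q = q)
# grid at the constant 28 C calibration temperature (density-regulated regime)
grid <- run_coverage_grid(rates_q, rep(28, 730), gamma, K = 500)
write.csv(grid, "results/coverage_grid.csv", row.names = FALSE)

for (mm in c(0.01, 0.10)) {
  sub <- grid[!is.na(grid$m_max) & grid$m_max == mm, ]
  message(sprintf("m_max = %2.0f%%/day: transgenic-patch steady state %.1f-%.1f adults/leaf (spread %.1f)",
                  100 * mm, min(sub$steady_state_adults), max(sub$steady_state_adults),
                  diff(range(sub$steady_state_adults))))
}
message("wrote results/coverage_grid.csv")
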