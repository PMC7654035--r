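#!/usr/bin/env Rscript
# Plant calibration and controller tuning for the default configuration.
#
# Part 1 verifies the calibration identities that the constructors solve
# at build time (growth-rate fixed points, consumption couplings) and the
# oxygen-transfer design inequalities:
#   (a) at full actuation (300 rpm, 10 SLPM) the vessel can hold 95% dO2
#       against the uptake of the maximal oxic culture;
#   (b) at minimum actuation (100 rpm, no sparge) the oxygen supply at the
#       1% set point is below the inoculum's uptake, so the plant is
#       controllable from both sides of the microoxic set point.
#
# Part 2 is the gain-tuning study: it sweeps PI gains over a grid and
# reports the closed-loop dO2 medians at both set points, which is how the
# package defaults (kp = 0.5, ki = 60 h^-1) were selected. A full sweep
# takes a few minutes; run with --sweep to enable it.

suppressPackageStartupMessages(library(magnetoferm))
args <- commandArgs(trailingOnly = TRUE)

cat("== Part 1: calibration identities =========================\n")
for (regime in c("oxic95", "microoxic1", "anoxic0")) {
  p <- kinetic_params(regime)
  mu <- growth_rate(p, p$do2_nominal, 15, p$nitrate0)
  cat(sprintf("%-11s mu(%3g%%, 15 mM, %2g mM) = %.4f (target %.2f)\n",
              regime, p$do2_nominal, p$nitrate0, mu, p$mu_nominal))
  stopifnot(abs(mu - p$mu_nominal) / p$mu_nominal < 1e-10)
}

cfg <- reactor_config()
p <- kinetic_params("oxic95")
supply_95 <- kla(cfg, 300, 10) * (100 - 95)
uptake_95 <- p$q_O2 * 0.76 * 95 / (p$K_O2 + 95)
cat(sprintf("95%% holdable: supply %.0f > uptake %.0f %%/h  [%s]\n",
            supply_95, uptake_95, ifelse(supply_95 > uptake_95, "ok", "FAIL")))
stopifnot(supply_95 > uptake_95)

pm <- kinetic_params("microoxic1")
supply_min <- kla(cfg, 100, 0) * (100 - 1)
uptake_min <- pm$q_O2 * pm$inoculum_od * 1 / (pm$K_O2 + 1)
cat(sprintf("1%% controllable: min supply %.0f < inoculum uptake %.0f %%/h  [%s]\n",
            supply_min, uptake_min, ifelse(supply_min < uptake_min, "ok", "FAIL")))
stopifnot(supply_min < uptake_min)

if ("--sweep" %in% args) {
  cat("\n== Part 2: PI gain sweep ==================================\n")
  for (kp in c(0.5, 1, 2)) for (ki in c(20, 40, 60)) {
    meds <- sapply(c("oxic95", "microoxic1"), function(preset) {
      pc <- preset_config(preset)
      ctrl <- controller_config(set_point = pc$params$do2_nominal, kp = kp, ki = ki)
      rec <- simulate_batch(pc$params, pc$reactor, controller = ctrl,
                            sensor = pc$sensor, horizon = 35, seed = 1)
      stats::median(rec$dO2_pct)
    })
    cat(sprintf("kp = %4.1f  ki = %3g: median dO2 = %.2f%% (95%% set point), %.3f%% (1%%)\n",
                kp, ki, meds[1], meds[2]))
  }
} else {
  cat("\n(run with --sweep for the PI gain-tuning study)\n")
}
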