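test_that("kLa correlation has a surface floor, power-law scaling and holds 95%", {
  cfg <- reactor_config()
  k <- cfg$kla_coeffs

  # no sparging: pure surface aeration, scaling linearly with agitation
  expect_equal(kla(cfg, 150, 0), k[["k_surface"]] * 1.5)
  expect_gt(kla(cfg, 100, 0), 0)

  # doubling rpm multiplies the sparged term by 2^alpha
  sparged <- function(rpm, q) kla(cfg, rpm, q) - k[["k_surface"]] * rpm / 100
  expect_equal(sparged(200, 2) / sparged(100, 2), 2^k[["alpha"]])

  # dynamic range and holdability at full actuation: oxygen supply at 95%
  # exceeds the uptake of the maximal oxic culture (OD 0.76)
  expect_gt(kla(cfg, 300, 10) / kla(cfg, 100, 0), 10)
  p <- kinetic_params("oxic95")
  our95 <- p$q_O2 * 0.76 * 95 / (p$K_O2 + 95)
  expect_gt(kla(cfg, 300, 10) * (100 - 95), our95)

  # monotone in both arguments
  expect_true(all(diff(kla(cfg, seq(100, 300, 10), 2)) > 0))
  expect_true(all(diff(kla(cfg, 200, seq(0, 10, 0.5))) >= 0))
  expect_error(kla(cfg, 50, 0), "stirrer minimum")
})

test_that("growth model reproduces the condition-wise rates and its zeros", {
  p <- kinetic_params("microoxic1")
  # calibration fixed points (targets 0.07 / 0.15 / 0.13 h^-1, within 5%)
  expect_equal(growth_rate(p, 95, 15, 4), 0.07, tolerance = 0.05)
  expect_equal(growth_rate(p, 1, 15, 4), 0.15, tolerance = 0.05)
  expect_equal(growth_rate(p, 0, 15, 10), 0.13, tolerance = 0.05)

  # no carbon source or no electron acceptor: no growth
  expect_equal(growth_rate(p, 1, 0, 4), 0)
  expect_equal(growth_rate(p, 0, 15, 0), 0)
  expect_error(growth_rate(p, -1, 15, 4), "non-negative")

  # condition ordering of rates, iron targets and size asymptotes
  expect_true(growth_rate(p, 1, 15, 4) > growth_rate(p, 0, 15, 10))
  expect_true(growth_rate(p, 0, 15, 10) > growth_rate(p, 95, 15, 4))
  it <- p$iron_targets
  expect_true(it[["anoxic0"]] > it[["microoxic1"]])
  expect_true(it[["microoxic1"]] > it[["oxic95"]])
  expect_gt(kinetic_params("anoxic0")$size_asymptote[["mean"]],
            kinetic_params("microoxic1")$size_asymptote[["mean"]])
})

test_that("state derivatives vanish without biomass and relax dO2 under N2", {
  p <- kinetic_params("anoxic0")
  cfg <- reactor_config(gas_o2_fraction = 0, n2_sparge = 0.2)
  s <- c(od = 0, lactate = 15, nitrate = 10, dO2 = 20, iron = 10, size_mean = 26)
  d <- plant_derivatives(20, s, p, cfg, 100, 0)
  expect_equal(unname(d[c("od", "lactate", "nitrate")]), c(0, 0, 0))

  # with zero uptake, dO2 decays to zero at rate kLa
  expect_equal(d[["dO2"]], -kla(cfg, 100, 0.2) * 20)

  s_bad <- s; s_bad[["lactate"]] <- NaN
  expect_error(plant_derivatives(20, s_bad, p, cfg, 100, 0), "lactate")
})

test_that("ODE solution matches the closed-form anoxic nitrate-depletion time", {
  rec <- fx_run_anox()
  p <- attr(rec, "params")
  # exponential growth at mu with consumption q per OD depletes nitrate
  # when X = X0 + S0 mu / q; analytic inversion gives the time
  mu <- p$mu_nominal; q <- p$q_no3_target
  x0 <- p$inoculum_od; s0 <- p$nitrate0
  t_closed <- p$lag + log(1 + s0 * mu / (q * x0)) / mu
  x_closed <- x0 + s0 * mu / q
  t_sim <- rec$time_h[which(rec$nitrate_mM < 0.01 * s0)[1]]
  expect_lt(abs(t_sim - t_closed) / t_closed, 0.01)
  expect_lt(abs(max(rec$od565) - x_closed) / x_closed, 0.01)
})

test_that("substrate limitation switches between nitrate (anoxic) and lactate (microoxic)", {
  anox <- fx_run_anox()
  # nitrate runs out first, lactate remains, OD plateaus afterwards
  t_no3 <- anox$time_h[which(anox$nitrate_mM < 0.05)[1]]
  expect_false(is.na(t_no3))
  expect_gt(min(anox$lactate_mM), 5)
  od_after <- anox$od565[anox$time_h > t_no3 + 1]
  expect_lt(diff(range(od_after)) / max(anox$od565), 0.01)

  micro <- fx_run1()
  t_lac <- micro$time_h[which(micro$lactate_mM < 0.05)[1]]
  expect_false(is.na(t_lac))
  expect_gt(min(micro$nitrate_mM), 0)
})

test_that("biomass yield on lactate is conserved along every noiseless trajectory", {
  for (rec in list(fx_run1(), fx_run_anox(), fx_run95())) {
    p <- attr(rec, "params")
    d_od <- rec$od565 - rec$od565[1]
    d_lac <- rec$lactate_mM[1] - rec$lactate_mM
    grown <- d_lac > 0.5
    expect_true(all(abs(d_od[grown] / d_lac[grown] - p$Y_lac_od) /
                      p$Y_lac_od < 1e-6))
  }
})

test_that("no-growth plant stays at the inoculum OD", {
  p <- kinetic_params("microoxic1", lag = 100)  # lag beyond horizon
  rec <- simulate_batch(p, horizon = 5, seed = 1)
  expect_equal(rec$od565, rep(p$inoculum_od, nrow(rec)), tolerance = 1e-10)
  expect_equal(rec$lactate_mM, rep(15, nrow(rec)), tolerance = 1e-10)
})

test_that("simulation records are deterministic given the seed", {
  a <- simulate_batch(kinetic_params("microoxic1"), horizon = 3, seed = 9)
  b <- simulate_batch(kinetic_params("microoxic1"), horizon = 3, seed = 9)
  c <- simulate_batch(kinetic_params("microoxic1"), horizon = 3, seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$dO2_pct, c$dO2_pct))
})

test_that("at-line observation subsamples, adds calibrated noise and truncates", {
  rec <- fx_run1()
  # noiseless observation equals the dense rows at the sample times
  obs0 <- observe_record(rec, 1, noise = 0, seed = 1)
  expect_equal(nrow(obs0), 36)
  dense <- rec[abs(rec$time_h - round(rec$time_h)) < 1e-9, ]
  expect_equal(obs0$od565, dense$od565)

  # multiplicative noise has the configured CV
  df <- make_record_df(seq_len(1e4), od = 1)
  obs <- observe_record(structure(df, class = c("fermentation_record", "data.frame")),
                        1, noise = 0.02, seed = 3)
  expect_lt(abs(sd(obs$od565) / mean(obs$od565) - 0.02), 0.002)
  expect_true(all(obs$od565 > 0))
  expect_error(observe_record(rec[0, ], 1, 0.02), "empty")
})

test_that("particle sampler reproduces the condition trajectories", {
  # anoxic end of growth: pooled triplicate of ~1000 recovers mean/sd
  ds <- sample_particles("anoxic0", 34, n_per_replicate = 1000, seed = 11)
  s <- summarize_sizes(ds)
  expect_equal(s$n, 3000)
  expect_lt(abs(s$mean - 33.8), 0.5)
  expect_lt(abs(s$sd - 9.4), 0.5)

  # microoxic seed-train mean approaches its tabulated value
  ds0 <- sample_particles("microoxic1", 0, n_per_replicate = 4000,
                          replicates = 1, seed = 12)
  expect_lt(abs(summarize_sizes(ds0)$mean - 26.7), 0.4)

  # empty draw is allowed; unknown regimes are not
  expect_equal(nrow(sample_particles("anoxic0", 34, n_per_replicate = 0,
                                     seed = 1)$particles), 0)
  expect_error(sample_particles("oxic", 0), "unknown regime")
})

test_that("dO2/pO2 conversion is linear at 2.12 mbar per percent", {
  cfg <- reactor_config()
  expect_equal(po2_from_do2(cfg, 100), 212)
  expect_equal(po2_from_do2(cfg, 0), 0)
  expect_equal(po2_from_do2(cfg, 1), 2.12)
  expect_equal(do2_from_po2(cfg, po2_from_do2(cfg, 37.5)), 37.5)
  expect_error(po2_from_do2(cfg, -1), ">= 0")
})
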