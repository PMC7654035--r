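# Shared fixtures. Full-length closed-loop batches are expensive (~10 s),
# so they are simulated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 35 h oxystat batch at the oxic set point (95% dO2)
fx_run95 <- function() fixture("run95", function()
  simulate_batch(kinetic_params("oxic95"), horizon = 35, seed = 101))

# triplicate 35 h microoxic batches (1% dO2); first one doubles as the
# single-record microoxic fixture
fx_runs1 <- function() fixture("runs1", function()
  lapply(c(201, 202, 203), function(s)
    simulate_batch(kinetic_params("microoxic1"), horizon = 35, seed = s)))

fx_run1 <- function() fx_runs1()[[1]]

# 35 h anoxic batch (N2 sparge, fixed actuation)
fx_run_anox <- function() fixture("run_anox", function()
  simulate_batch(kinetic_params("anoxic0"), horizon = 35, seed = 104))

# orientation-averaged cylinder (disc) form factor: independent generator
# for platelet round-trip tests
disc_intensity <- function(q, radius_A, thickness_A) {
  vapply(q, function(qq) {
    f <- function(a) {
      s <- sin(a)
      x <- qq * radius_A * s
      y <- qq * thickness_A * cos(a) / 2
      A <- ifelse(x < 1e-8, 1, 2 * besselJ(x, 1) / x)
      B <- ifelse(abs(y) < 1e-8, 1, sin(y) / y)
      (A * B)^2 * s
    }
    stats::integrate(f, 0, pi / 2, rel.tol = 1e-9)$value
  }, numeric(1))
}

# minimal record data.frame for IO/observation tests
make_record_df <- function(times, od = 0.5, do2 = 1) {
  data.frame(time_h = times, od565 = od, dO2_pct = do2,
             lactate_mM = 10, nitrate_mM = 4, cmag = 0.5,
             fe_mg_per_gdw = 10, rpm = 100, airflow_slpm = 0)
}
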