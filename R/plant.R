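# ODE plant: batch growth, substrate consumption, oxygen balance, iron and
# crystal-size dynamics, and the sampled fermentation record.

#' Magnetic response as a function of cellular iron
#'
#' Monotone piecewise-linear map from cellular iron content to the Cmag
#' light-scattering statistic, calibrated to the condition-wise end points
#' (3.3 -> 0.10, 14.4 -> 0.74, 25.3 -> 0.99 mg g_dw^-1) and anchored at
#' (0, 0); constant beyond the last knot.
#'
#' @param iron cellular iron, mg per g dry weight.
#' @return Cmag (dimensionless).
#' @export
cmag_from_iron <- function(iron) {
  stop_if(any(iron < 0), "iron content must be >= 0")
  stats::approx(x = c(0, 3.3, 14.4, 25.3), y = c(0, 0.10, 0.74, 0.99),
                xout = iron, rule = 2)$y
}

#' Time derivatives of the fermentation state
#'
#' Right-hand side of the batch model:
#' \itemize{
#'   \item `d od/dt = mu * od` (zero before the lag phase ends);
#'   \item `d lactate/dt = -(mu / Y_lac_od) * od` — growth-coupled, so the
#'     biomass formed per lactate consumed equals the configured yield at
#'     all times;
#'   \item `d nitrate/dt = -[f_assim + f_resp * Fnr(C) * Monod(NO3)] * od *
#'     (mu / mu_nominal)` — assimilation plus oxygen-repressed respiration,
#'     gated by growth activity so lag and stationary phases do not consume
#'     nitrate;
#'   \item `d dO2/dt = kLa * (c_star * gas_o2_fraction / 0.21 - C) - OUR`
#'     with `OUR = q_O2 * od * C / (K_O2 + C)`;
#'   \item cellular iron and mean crystal diameter relax first-order
#'     towards their regime targets while the culture grows.
#' }
#'
#' @param time time, hours (lag-phase gating).
#' @param state named numeric: `od`, `lactate`, `nitrate`, `dO2`, `iron`,
#'   `size_mean`.
#' @param params a [kinetic_params()].
#' @param config a [reactor_config()].
#' @param rpm,airflow actuator settings (zero-order hold).
#' @return named numeric of derivatives, same order as `state`.
#' @export
plant_derivatives <- function(time, state, params, config, rpm, airflow) {
  stopifnot(inherits(params, "kinetic_params"), inherits(config, "reactor_config"))
  bad <- !is.finite(state)
  stop_if(any(bad), sprintf("state component(s) %s non-finite",
                            paste(names(state)[bad], collapse = ", ")))
  od <- state[["od"]]; Sl <- state[["lactate"]]; Sn <- state[["nitrate"]]
  C <- max(state[["dO2"]], 0)
  mu <- if (time >= params$lag) growth_rate(params, C, max(Sl, 0), max(Sn, 0)) else 0
  act <- mu / params$mu_nominal
  our <- params$q_O2 * od * C / (params$K_O2 + C)
  transfer <- kla(config, rpm, airflow + config$n2_sparge)
  c_eq <- config$c_star * config$gas_o2_fraction / 0.21
  d_od <- mu * od
  d_lac <- -mu / params$Y_lac_od * od
  d_no3 <- -(params$f_assim + params$f_resp *
               params$K_fnr / (params$K_fnr + C) * Sn / (params$K_no3 + Sn)) * od * act
  d_c <- transfer * (c_eq - C) - our
  growing <- if (time >= params$lag) 1 else 0
  d_fe <- params$k_iron * (params$iron_target - state[["iron"]]) * growing
  d_size <- params$k_size * (params$size_asymptote[["mean"]] - state[["size_mean"]]) * growing
  c(od = d_od, lactate = d_lac, nitrate = d_no3, dO2 = d_c,
    iron = d_fe, size_mean = d_size)
}

#' Build a plant-step callback for the closed control loop
#'
#' Wraps [plant_derivatives()] in an adaptive stiff-capable integrator
#' ([deSolve::lsoda]) advancing the state over one zero-order-hold interval.
#' Concentrations are projected onto non-negativity and dO2 onto
#' \[0, 100\] after each step.
#'
#' @param params a [kinetic_params()].
#' @param config a [reactor_config()].
#' @param rtol,atol integrator tolerances.
#' @return function `(state, rpm, airflow, dt) -> state`.
#' @export
make_plant <- function(params, config, rtol = 1e-9, atol = 1e-11) {
  force(params); force(config)
  time_env <- new.env(); time_env$t <- 0
  function(state, rpm, airflow, dt) {
    y <- unlist(state)
    t0 <- time_env$t
    sol <- deSolve::lsoda(y, c(t0, t0 + dt),
                          function(t, y, p) list(plant_derivatives(t, y, params, config, rpm, airflow)),
                          parms = NULL, rtol = rtol, atol = atol)
    stop_if(nrow(sol) < 2, sprintf("integrator failed after t = %.4f h", t0))
    time_env$t <- t0 + dt
    y2 <- sol[2, -1]
    y2[c("od", "lactate", "nitrate", "iron")] <- pmax(y2[c("od", "lactate", "nitrate", "iron")], 0)
    y2[["dO2"]] <- clamp(y2[["dO2"]], 0, 100)
    as.list(y2)
  }
}

initial_state <- function(params, config) {
  c_eq <- config$c_star * config$gas_o2_fraction / 0.21
  # oxic runs start from air-saturated medium; microoxic/anoxic media are
  # gassed out with N2 before inoculation
  c0 <- if (params$do2_nominal >= 50) c_eq else 0
  list(od = params$inoculum_od, lactate = params$lactate0,
       nitrate = params$nitrate0, dO2 = c0,
       iron = params$iron0, size_mean = params$seed_size[["mean"]])
}

#' Simulate one oxystat (or fixed-actuation) batch
#'
#' Integrates the plant over the horizon. Under a controller the actuators
#' are updated at every controller sample time from the noisy sensor
#' reading (zero-order hold in between); with `fixed_actuation` the
#' actuators are constant, as in the anoxic mode where the vessel is
#' N2-sparged at constant agitation.
#'
#' @param params a [kinetic_params()].
#' @param config a [reactor_config()]; `NULL` builds the regime default
#'   (air sparge for controlled runs, N2 sparge for `anoxic0`).
#' @param controller a [controller_config()], or `NULL` with
#'   `fixed_actuation`.
#' @param sensor a [sensor_model()]; default noise by regime (0.5% at the
#'   oxic set point, 0.2% microoxic, 0.1% anoxic).
#' @param fixed_actuation named numeric `(rpm, airflow)` for uncontrolled
#'   runs.
#' @param horizon hours.
#' @param seed integer seed (sensor noise stream).
#' @param record_interval spacing of recorded rows, hours.
#' @return a `fermentation_record`: data.frame with columns `time_h`,
#'   `od565`, `dO2_pct` (sensor-recorded), `lactate_mM`, `nitrate_mM`,
#'   `cmag`, `fe_mg_per_gdw`, `rpm`, `airflow_slpm`, plus `dO2_true_pct`
#'   and `output_pct`; metadata in attributes (`condition`, `seed`,
#'   `params`).
#' @export
simulate_batch <- function(params,
                           config = NULL,
                           controller = NULL,
                           sensor = NULL,
                           fixed_actuation = NULL,
                           horizon = 35,
                           seed = 1,
                           record_interval = 1 / 60) {
  stopifnot(inherits(params, "kinetic_params"))
  check_positive(horizon, "horizon")
  if (is.null(config)) {
    config <- if (params$regime == "anoxic0")
      reactor_config(gas_o2_fraction = 0, n2_sparge = 0.2)
    else reactor_config()
  }
  if (is.null(sensor)) {
    sensor <- sensor_model(noise_sd = switch(params$regime,
                                             oxic95 = 0.5, microoxic1 = 0.2, 0.1))
  }
  if (is.null(controller) && is.null(fixed_actuation)) {
    if (params$regime == "anoxic0") fixed_actuation <- c(rpm = 100, airflow = 0)
    else controller <- controller_config(set_point = params$do2_nominal)
  }
  state0 <- initial_state(params, config)

  if (!is.null(controller)) {
    plant <- make_plant(params, config)
    trace <- closed_loop(controller, sensor, plant, state0, horizon, seed = seed)
    states <- attr(trace, "states")
    smat <- do.call(rbind, lapply(states, function(s) unlist(s)))
    rec <- data.frame(time_h = trace$time_h,
                      od565 = smat[, "od"],
                      dO2_pct = trace$dO2_pct,
                      lactate_mM = smat[, "lactate"],
                      nitrate_mM = smat[, "nitrate"],
                      cmag = cmag_from_iron(smat[, "iron"]),
                      fe_mg_per_gdw = smat[, "iron"],
                      rpm = trace$rpm,
                      airflow_slpm = trace$airflow_slpm,
                      dO2_true_pct = trace$dO2_true_pct,
                      output_pct = trace$output_pct,
                      size_mean_nm = smat[, "size_mean"])
  } else {
    stop_if(length(fixed_actuation) < 2, "'fixed_actuation' needs rpm and airflow")
    rpm <- fixed_actuation[["rpm"]]; airflow <- fixed_actuation[["airflow"]]
    times <- seq(0, horizon, by = record_interval)
    sol <- deSolve::lsoda(unlist(state0), times,
                          function(t, y, p) list(plant_derivatives(t, y, params, config, rpm, airflow)),
                          parms = NULL, rtol = 1e-9, atol = 1e-11)
    stop_if(nrow(sol) < length(times),
            sprintf("integrator failed after t = %.4f h", sol[nrow(sol), 1]))
    smat <- sol[, -1, drop = FALSE]
    smat[, c("od", "lactate", "nitrate", "iron")] <-
      pmax(smat[, c("od", "lactate", "nitrate", "iron")], 0)
    true_c <- clamp(smat[, "dO2"], 0, 100)
    meas <- with_seed(seed, clamp(true_c + stats::rnorm(length(true_c), 0, sensor$noise_sd),
                                  sensor$detection_floor, 100 * (1 + sensor$accuracy)))
    rec <- data.frame(time_h = times,
                      od565 = smat[, "od"],
                      dO2_pct = meas,
                      lactate_mM = smat[, "lactate"],
                      nitrate_mM = smat[, "nitrate"],
                      cmag = cmag_from_iron(smat[, "iron"]),
                      fe_mg_per_gdw = smat[, "iron"],
                      rpm = rpm,
                      airflow_slpm = airflow,
                      dO2_true_pct = true_c,
                      output_pct = NA_real_,
                      size_mean_nm = smat[, "size_mean"])
  }
  rownames(rec) <- NULL
  structure(rec,
            condition = params$regime, seed = seed,
            params = params, reactor = config,
            class = c("fermentation_record", "data.frame"))
}

#' @export
print.fermentation_record <- function(x, ...) {
  cat(sprintf("fermentation_record [%s]: %d samples over %.1f h (seed %s)\n",
              attr(x, "condition") %||% "?", nrow(x), max(x$time_h),
              format(attr(x, "seed"))))
  cat(sprintf("  final OD565 %.3f | median dO2 %.2f%% | lactate %.2f mM | nitrate %.2f mM\n",
              x$od565[nrow(x)], stats::median(x$dO2_pct),
              x$lactate_mM[nrow(x)], x$nitrate_mM[nrow(x)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subsample a dense record into noisy at-line observations
#'
#' Emulates at-line sampling: rows are taken every `sampling_interval`
#' hours; OD, lactate, nitrate and iron receive multiplicative lognormal
#' noise with the given coefficient of variation, dO2 receives additive
#' Gaussian noise of the same magnitude (percentage points); all values are
#' truncated at zero.
#'
#' @param record a `fermentation_record`.
#' @param sampling_interval hours between observations.
#' @param noise relative standard deviation (e.g. 0.02 for 2%).
#' @param seed integer seed.
#' @return a sparse `fermentation_record`.
#' @export
observe_record <- function(record, sampling_interval = 1, noise = 0.02, seed = 1) {
  stopifnot(inherits(record, "data.frame"))
  stop_if(nrow(record) == 0, "empty record rejected")
  check_positive(sampling_interval, "sampling_interval")
  check_positive(noise, "noise", strict = FALSE)
  t <- record$time_h
  keep <- abs((t / sampling_interval) - round(t / sampling_interval)) < 1e-8
  out <- record[keep, , drop = FALSE]
  n <- nrow(out)
  if (noise > 0) {
    sdlog <- sqrt(log(1 + noise^2))
    out <- with_seed(seed, {
      for (col in c("od565", "lactate_mM", "nitrate_mM", "fe_mg_per_gdw"))
        out[[col]] <- out[[col]] * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      out$dO2_pct <- pmax(out$dO2_pct + stats::rnorm(n, 0, noise), 0)
      out
    })
  }
  rownames(out) <- NULL
  structure(out, condition = attr(record, "condition"),
            seed = seed, params = attr(record, "params"),
            class = c("fermentation_record", "data.frame"))
}
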