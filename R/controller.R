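# PI-controlled split-range cascade for dissolved-oxygen regulation.
#
# The controller maps the dO2 error through a discrete-time PI law to a
# single output u in [0, 100] %, which a split-range cascade translates into
# stepwise agitation (first half of the output range) and airflow (second
# half) commands, mimicking an oxystat regime where both actuators are
# raised independently and monotonically with controller output.

#' Controller configuration for the dO2 cascade
#'
#' Bundles the PI gains, the split-range breakpoint and the actuator ranges
#' and step quanta of the oxystat cascade. Defaults reflect a 3 L stirred
#' tank whose agitation spans 100-300 rpm and whose air sparge spans
#' 0-10 SLPM, actuated in discrete steps of 10 rpm and 0.1 SLPM.
#'
#' The PI gains default to kp = 0.5 and ki = 60 h^-1, tuned against the
#' default plant of [make_plant()]: at a 1% air-saturation set point the
#' control error is bounded by ~1 percentage point, so tracking the
#' exponentially growing oxygen demand of the culture requires a strong
#' integral action, while a small proportional gain keeps sensor noise from
#' exciting the quantized actuators.
#'
#' @param set_point dO2 set point, percent air saturation.
#' @param kp proportional gain (dimensionless).
#' @param ki integral gain, h^-1.
#' @param sample_interval controller sampling interval in hours.
#' @param u_split controller output (percent) at which actuation hands over
#'   from agitation to airflow.
#' @param rpm_bounds numeric(2), agitation range in rpm.
#' @param airflow_bounds numeric(2), airflow range in SLPM.
#' @param rpm_step agitation quantum in rpm.
#' @param airflow_step airflow quantum in SLPM.
#' @param integral_limits numeric(2), clamp on the integral term
#'   (percent*hours); defaults to +/- 100/ki so the integral alone can span
#'   the full output range without winding further.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(set_point = 95,
                              kp = 0.5,
                              ki = 60,
                              sample_interval = 1 / 60,
                              u_split = 50,
                              rpm_bounds = c(100, 300),
                              airflow_bounds = c(0, 10),
                              rpm_step = 10,
                              airflow_step = 0.1,
                              integral_limits = NULL) {
  check_finite(set_point, "set_point")
  stop_if(set_point < 0, "'set_point' must be >= 0")
  check_positive(sample_interval, "sample_interval")
  stop_if(u_split <= 0 || u_split >= 100, "'u_split' must lie strictly between 0 and 100")
  stop_if(length(rpm_bounds) != 2 || diff(rpm_bounds) <= 0, "'rpm_bounds' must be increasing (min, max)")
  stop_if(length(airflow_bounds) != 2 || diff(airflow_bounds) <= 0,
          "'airflow_bounds' must be increasing (min, max)")
  check_positive(rpm_step, "rpm_step")
  check_positive(airflow_step, "airflow_step")
  if (is.null(integral_limits)) {
    span <- if (ki > 0) 100 / ki else 100
    integral_limits <- c(-span, span)
  }
  stop_if(diff(integral_limits) <= 0, "'integral_limits' must be increasing")
  structure(list(set_point = set_point, kp = kp, ki = ki,
                 sample_interval = sample_interval, u_split = u_split,
                 rpm_bounds = rpm_bounds, airflow_bounds = airflow_bounds,
                 rpm_step = rpm_step, airflow_step = airflow_step,
                 integral_limits = integral_limits),
            class = "controller_config")
}

#' @export
print.controller_config <- function(x, ...) {
  cat("dO2 PI cascade controller\n")
  cat(sprintf("  set point    : %g %% air saturation\n", x$set_point))
  cat(sprintf("  gains        : kp = %g, ki = %g h^-1, dt = %g h\n",
              x$kp, x$ki, x$sample_interval))
  cat(sprintf("  agitation    : %g-%g rpm (step %g), output <= %g%%\n",
              x$rpm_bounds[1], x$rpm_bounds[2], x$rpm_step, x$u_split))
  cat(sprintf("  airflow      : %g-%g SLPM (step %g), output > %g%%\n",
              x$airflow_bounds[1], x$airflow_bounds[2], x$airflow_step, x$u_split))
  invisible(x)
}

#' Dissolved-oxygen sensor model
#'
#' Additive Gaussian read noise with clamping to the probe's working range.
#' The default detection floor converts the probe's 6 ppb lower limit to
#' percent air saturation using 8.0 mg O2 L^-1 at air saturation and 28 C
#' (0.006 mg L^-1 / 8.0 mg L^-1 = 0.075%); the conversion constant is
#' explicit so other temperatures/salinities can be configured.
#'
#' @param noise_sd read-noise standard deviation, percent air saturation.
#' @param detection_floor lower reading limit, percent air saturation.
#' @param accuracy relative accuracy of the probe (0.01 = +/- 1%); readings
#'   are clamped to `100 * (1 + accuracy)` at the top.
#' @param sat_mg_per_l dissolved O2 at air saturation, mg L^-1 (conversion
#'   provenance for the default floor).
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(noise_sd = 0.5,
                         detection_floor = 0.006 / 8.0 * 100,
                         accuracy = 0.01,
                         sat_mg_per_l = 8.0) {
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(detection_floor, "detection_floor", strict = FALSE)
  check_positive(accuracy, "accuracy", strict = FALSE)
  structure(list(noise_sd = noise_sd, detection_floor = detection_floor,
                 accuracy = accuracy, sat_mg_per_l = sat_mg_per_l),
            class = "sensor_model")
}

#' One discrete PI step
#'
#' Computes the controller output from the measured dO2 and the accumulated
#' integral. The integral is clamped to `config$integral_limits` and, as
#' anti-windup, is frozen whenever the unsaturated output is already pinned
#' against the bound the error is pushing towards.
#'
#' @param config a [controller_config()].
#' @param measured measured dO2, percent air saturation.
#' @param integral accumulated error, percent*hours.
#' @return list with `output` (percent, in \[0, 100\]) and `integral`.
#' @examples
#' cfg <- controller_config(set_point = 10, kp = 10, ki = 0.1, sample_interval = 1)
#' pi_step(cfg, measured = 8, integral = 0)  # output 20.2
#' @export
pi_step <- function(config, measured, integral = 0) {
  stopifnot(inherits(config, "controller_config"))
  stop_if(!is.finite(measured), "non-finite dO2 measurement rejected")
  stop_if(measured < 0, "negative dO2 measurement rejected")
  stop_if(config$sample_interval <= 0, "sample interval must be positive")
  e <- config$set_point - measured
  unsat <- config$kp * e + config$ki * integral
  windup_hi <- unsat >= 100 && e > 0
  windup_lo <- unsat <= 0 && e < 0
  new_integral <- if (windup_hi || windup_lo) integral else
    clamp(integral + e * config$sample_interval,
          config$integral_limits[1], config$integral_limits[2])
  output <- clamp(config$kp * e + config$ki * new_integral, 0, 100)
  list(output = output, integral = new_integral)
}

#' Split-range cascade: controller output to actuator commands
#'
#' For output below the split point the agitation ramps linearly from its
#' minimum to its maximum (quantized down to whole rpm steps) while airflow
#' stays at its minimum; above the split point agitation is held at maximum
#' and airflow ramps linearly (quantized down to whole SLPM steps). Both
#' maps are monotone non-decreasing, so the two actuators rise stepwise and
#' independently with controller output.
#'
#' @param config a [controller_config()].
#' @param output controller output, percent in \[0, 100\].
#' @return named numeric: `rpm`, `airflow`.
#' @examples
#' cfg <- controller_config()
#' cascade_map(cfg, 0)    # 100 rpm, 0 SLPM
#' cascade_map(cfg, 100)  # 300 rpm, 10 SLPM
#' @export
cascade_map <- function(config, output) {
  stopifnot(inherits(config, "controller_config"))
  stop_if(!is.finite(output) || output < 0 || output > 100,
          "controller output must lie in [0, 100]")
  rb <- config$rpm_bounds; ab <- config$airflow_bounds
  if (output <= config$u_split) {
    raw <- rb[1] + output / config$u_split * (rb[2] - rb[1])
    rpm <- rb[1] + floor((raw - rb[1]) / config$rpm_step + 1e-9) * config$rpm_step
    rpm <- min(rpm, rb[2])
    airflow <- ab[1]
  } else {
    # largest quantized agitation not exceeding the bound
    rpm <- rb[1] + floor((rb[2] - rb[1]) / config$rpm_step + 1e-9) * config$rpm_step
    raw <- ab[1] + (output - config$u_split) / (100 - config$u_split) * (ab[2] - ab[1])
    airflow <- ab[1] + floor((raw - ab[1]) / config$airflow_step + 1e-9) * config$airflow_step
    airflow <- min(airflow, ab[2])
  }
  c(rpm = rpm, airflow = airflow)
}

#' Simulate one noisy sensor reading
#'
#' @param model a [sensor_model()].
#' @param true_do2 true dO2, percent air saturation, in \[0, 100\].
#' @param seed optional seed for a reproducible single draw; when `NULL` the
#'   current RNG stream is used (as inside [closed_loop()]).
#' @return measured dO2 (percent), clamped to the probe range.
#' @export
sensor_read <- function(model, true_do2, seed = NULL) {
  stopifnot(inherits(model, "sensor_model"))
  stop_if(!is.finite(true_do2), "non-finite dO2 rejected")
  stop_if(true_do2 < 0, "negative true dO2 rejected")
  stop_if(true_do2 > 100, "true dO2 above air saturation rejected")
  reading <- with_seed(seed, true_do2 + stats::rnorm(1, 0, model$noise_sd))
  clamp(reading, model$detection_floor, 100 * (1 + model$accuracy))
}

#' Run the closed dO2 control loop against a plant
#'
#' At every controller sample time the loop reads the sensor, executes one
#' PI step, maps the output to actuator commands and advances the plant
#' under zero-order hold. The plant is supplied as a callback
#' `plant_step(state, rpm, airflow, dt)` returning the advanced state; the
#' state must carry the true dO2 in an element named `dO2`.
#'
#' @param config a [controller_config()].
#' @param sensor a [sensor_model()].
#' @param plant_step callback advancing the plant state over `dt` hours at
#'   the given actuator settings.
#' @param state0 initial plant state (list or named numeric with `dO2`).
#' @param horizon simulation horizon, hours.
#' @param seed integer seed for the sensor-noise stream.
#' @return data.frame trace with columns `time_h`, `dO2_pct` (measured),
#'   `dO2_true_pct`, `output_pct`, `rpm`, `airflow_slpm`, one row per
#'   controller sample, plus attribute `states` holding the plant state at
#'   each sample time.
#' @export
closed_loop <- function(config, sensor, plant_step, state0, horizon, seed = 1) {
  stopifnot(inherits(config, "controller_config"), inherits(sensor, "sensor_model"))
  check_positive(horizon, "horizon")
  stop_if(!is.function(plant_step), "'plant_step' must be a function")
  dt <- config$sample_interval
  n <- floor(horizon / dt + 1e-9)
  trace <- data.frame(time_h = numeric(n + 1), dO2_pct = numeric(n + 1),
                      dO2_true_pct = numeric(n + 1), output_pct = numeric(n + 1),
                      rpm = numeric(n + 1), airflow_slpm = numeric(n + 1))
  states <- vector("list", n + 1)
  with_seed(seed, {
    state <- state0
    integral <- 0
    for (i in 0:n) {
      t <- i * dt
      true_do2 <- as.numeric(state[["dO2"]])
      stop_if(!is.finite(true_do2),
              sprintf("plant returned non-finite dO2 at t = %.4f h", t))
      measured <- sensor_read(sensor, clamp(true_do2, 0, 100))
      step <- pi_step(config, measured, integral)
      integral <- step$integral
      act <- cascade_map(config, step$output)
      trace[i + 1, ] <- c(t, measured, true_do2, step$output, act[["rpm"]], act[["airflow"]])
      states[[i + 1]] <- state
      if (i < n) {
        state <- plant_step(state, act[["rpm"]], act[["airflow"]], dt)
        bad <- !is.finite(unlist(state))
        stop_if(any(bad), sprintf("plant state became non-finite at t = %.4f h (%s)",
                                  t + dt, paste(names(unlist(state))[bad], collapse = ", ")))
      }
    }
  })
  attr(trace, "states") <- states
  attr(trace, "config") <- config
  trace
}
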