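# Growth, consumption, yield, productivity and magnetic-response analytics
# on fermentation time series.

new_rate_estimate <- function(value, sd, window, n_points, units) {
  structure(list(value = value, sd = sd, window = window,
                 n_points = n_points, units = units),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.4g %s (sd %.3g, window %g-%g h, n = %d)\n",
              x$value, x$units, x$sd %||% NA, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

window_points <- function(times, values, window) {
  stop_if(length(window) != 2 || window[1] >= window[2],
          "'window' must be (t_start, t_end) with start < end")
  idx <- times >= window[1] & times <= window[2]
  list(t = times[idx], v = values[idx])
}

#' Fit the specific growth rate over a time window
#'
#' Least-squares slope of `ln(OD)` against time over the main-growth
#' window. Several records may be supplied as a list, in which case the
#' per-replicate slopes are averaged and their standard deviation reported.
#' Non-positive OD points are dropped with a warning.
#'
#' @param times hours, or a `fermentation_record` / list of records (then
#'   `od` is ignored).
#' @param od OD565 values matching `times`.
#' @param window numeric(2), fit window in hours.
#' @return a `rate_estimate` (h^-1).
#' @examples
#' t <- seq(0, 10, 0.5)
#' fit_growth_rate(t, 0.1 * exp(0.15 * t), window = c(0, 10))$value  # 0.15
#' @export
fit_growth_rate <- function(times, od = NULL, window) {
  if (inherits(times, "fermentation_record")) times <- list(times)
  if (is.list(times) && !is.data.frame(times)) {
    mus <- vapply(times, function(r)
      fit_growth_rate(r$time_h, r$od565, window)$value, numeric(1))
    return(new_rate_estimate(mean(mus), stats::sd(mus), window, length(mus), "h^-1"))
  }
  w <- window_points(times, od, window)
  ok <- is.finite(w$v) & w$v > 0
  if (any(!ok)) warning(sprintf("%d non-positive OD point(s) excluded from growth fit", sum(!ok)))
  stop_if(sum(ok) < 3, "need at least 3 positive OD points inside the window")
  fit <- stats::lm(log(w$v[ok]) ~ w$t[ok])
  new_rate_estimate(unname(stats::coef(fit)[2]), NA_real_, window, sum(ok), "h^-1")
}

#' Doubling time from a specific growth rate
#'
#' @param mu specific growth rate, h^-1 (must be positive).
#' @return doubling time `ln(2)/mu` in hours.
#' @export
doubling_time <- function(mu) {
  stop_if(any(!is.finite(mu)) || any(mu <= 0),
          "doubling time undefined for mu <= 0")
  log(2) / mu
}

#' Biomass-specific substrate consumption rate
#'
#' Negative slope of the concentration over the window divided by the
#' time-averaged OD over the same window, yielding mM h^-1 per OD565 unit.
#' A negative estimate (rising concentration) is floored at zero with a
#' warning.
#'
#' @param times hours.
#' @param conc substrate concentration, mM.
#' @param od OD565 values matching `times`.
#' @param window numeric(2), hours.
#' @return a `rate_estimate` (mM h^-1 OD^-1).
#' @export
consumption_rate <- function(times, conc, od, window) {
  w <- window_points(times, conc, window)
  wod <- window_points(times, od, window)
  stop_if(length(w$t) < 3, "need at least 3 points inside the window")
  stop_if(any(w$v < 0), "concentrations must be >= 0")
  mean_od <- mean(wod$v)
  stop_if(!is.finite(mean_od) || mean_od <= 0, "mean OD over the window is zero")
  slope <- unname(stats::coef(stats::lm(w$v ~ w$t))[2])
  rate <- -slope / mean_od
  if (rate < 0) {
    if (rate < -1e-10) warning("negative consumption rate floored at 0")
    rate <- 0
  }
  new_rate_estimate(rate, NA_real_, window, length(w$t), "mM h^-1 OD^-1")
}

#' Biomass yield per substrate
#'
#' `Y_x/s = delta_OD * od_to_dw * 1000 / delta_S` in mg dry weight per mmol
#' substrate, evaluated start-to-end-of-growth. The OD-to-dry-weight
#' conversion is a required argument: it is recorded alongside the value
#' because reported yields are not reproducible without it.
#'
#' @param delta_od OD565 gained over the growth phase.
#' @param delta_substrate substrate consumed, mM (= mmol L^-1).
#' @param od_to_dw conversion, g dry weight L^-1 per OD unit.
#' @param substrate label for the substrate.
#' @return list with `value` (mg_dw mmol^-1), `substrate`, `od_to_dw`.
#' @export
yield_per_substrate <- function(delta_od, delta_substrate, od_to_dw,
                                substrate = "lactate") {
  stop_if(delta_substrate <= 0, "substrate consumption must be > 0")
  stop_if(delta_od < 0, "OD gain must be >= 0")
  check_positive(od_to_dw, "od_to_dw")
  structure(list(value = delta_od * od_to_dw * 1000 / delta_substrate,
                 substrate = substrate, od_to_dw = od_to_dw),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  cat(sprintf("%.3g mg_dw mmol_%s^-1 (od_to_dw = %.3g g/L/OD)\n",
              x$value, x$substrate, x$od_to_dw))
  invisible(x)
}

#' Volumetric magnetite productivity
#'
#' Converts cellular iron to magnetite assuming a fixed fraction of the
#' intracellular iron is bound as Fe3O4 (default 99%), using the mass ratio
#' M(Fe3O4) / (3 M(Fe)) = 231.53 / 167.54 = 1.382:
#' `P = fraction * iron * biomass * 1.382 / process_time`.
#'
#' @param iron cellular iron, mg per g dry weight.
#' @param biomass dry biomass concentration, g_dw L^-1.
#' @param process_time total process time, hours.
#' @param magnetite_fraction fraction of iron bound in magnetite, in (0, 1].
#' @return productivity, mg magnetite L^-1 h^-1.
#' @export
magnetite_productivity <- function(iron, biomass, process_time,
                                   magnetite_fraction = 0.99) {
  stop_if(any(iron < 0), "iron must be >= 0")
  check_positive(biomass, "biomass")
  stop_if(process_time <= 0, "process time must be > 0")
  stop_if(magnetite_fraction <= 0 || magnetite_fraction > 1,
          "magnetite_fraction must lie in (0, 1]")
  fe3o4_per_fe <- 231.53 / 167.54
  magnetite_fraction * iron * biomass * fe3o4_per_fe / process_time
}

#' Magnetic response (Cmag) from aligned optical densities
#'
#' Ratio of the scattering intensities of cells magnetically aligned
#' perpendicular versus parallel to the light beam, minus one. Zero means
#' magnetically unresponsive.
#'
#' @param od_max optical density with cells aligned perpendicular.
#' @param od_min optical density with cells aligned parallel.
#' @return Cmag (dimensionless, >= 0).
#' @export
cmag <- function(od_max, od_min) {
  check_positive(od_min, "od_min")
  stop_if(any(od_max < od_min),
          "od_max < od_min: orientation swap suspected")
  od_max / od_min - 1
}
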