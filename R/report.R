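# Pipeline orchestration: one-call simulation runs with provenance
# sidecars, and the analysis report bundling growth, particle and SAXS
# summaries with controller performance metrics.

#' Default main-growth fit window for a condition
#'
#' The condition-wise windows of the study protocol: 12-18 h (oxic),
#' 10-17 h (microoxic), 17-23 h (anoxic). With `auto = TRUE` the window is
#' instead detected as the 6 h span maximizing the log-OD slope.
#'
#' @param condition regime name.
#' @param record optional `fermentation_record` for auto-detection.
#' @param auto detect the window from the data instead.
#' @return numeric(2) window in hours.
#' @export
growth_window <- function(condition, record = NULL, auto = FALSE) {
  if (auto) {
    stop_if(is.null(record), "auto window detection needs a record")
    t <- record$time_h; od <- record$od565
    starts <- seq(min(t), max(t) - 6, by = 0.5)
    slopes <- vapply(starts, function(s) {
      idx <- t >= s & t <= s + 6 & od > 0
      if (sum(idx) < 3) return(-Inf)
      unname(stats::coef(stats::lm(log(od[idx]) ~ t[idx]))[2])
    }, numeric(1))
    s <- starts[which.max(slopes)]
    return(c(s, s + 6))
  }
  switch(condition,
         oxic95 = c(12, 18), microoxic1 = c(10, 17), anoxic0 = c(17, 23),
         stop(sprintf("no default window for condition '%s'", condition), call. = FALSE))
}

#' Simulate a preset batch and write record + metadata files
#'
#' Runs [simulate_batch()] for a named preset and writes the record CSV
#' together with a sidecar JSON carrying the seed, condition and parameter
#' snapshot, so every number in the record is reproducible from the files
#' alone.
#'
#' @param preset preset name (see [preset_config()]).
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param horizon hours.
#' @param sampling_interval observation spacing for the additionally
#'   written at-line record, hours.
#' @param noise relative observation noise for the at-line record.
#' @return invisibly, list with the `record`, `observed` record and file
#'   paths.
#' @export
run_simulation <- function(preset, seed = 1, out_dir = ".", horizon = 35,
                           sampling_interval = 1, noise = 0.02) {
  check_positive(horizon, "horizon")
  pc <- preset_config(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- simulate_batch(pc$params, pc$reactor, controller = pc$controller,
                        sensor = pc$sensor, fixed_actuation = pc$fixed_actuation,
                        horizon = horizon, seed = child_seed(seed, 1))
  obs <- observe_record(rec, sampling_interval, noise, seed = child_seed(seed, 2))
  rec_path <- file.path(out_dir, sprintf("%s_record.csv", preset))
  obs_path <- file.path(out_dir, sprintf("%s_atline.csv", preset))
  meta_path <- file.path(out_dir, sprintf("%s_meta.json", preset))
  write_record(rec, rec_path)
  write_record(obs, obs_path)
  p <- pc$params
  meta <- list(preset = preset, seed = seed,
               child_seeds = c(simulate = child_seed(seed, 1), observe = child_seed(seed, 2)),
               horizon_h = horizon,
               nitrate0_mM = p$nitrate0, lactate0_mM = p$lactate0,
               inoculum_od = p$inoculum_od, lag_h = p$lag,
               mu_nominal = p$mu_nominal, od_to_dw = p$od_to_dw,
               package_version = as.character(utils::packageVersion("magnetoferm")))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(record = rec, observed = obs,
                 paths = c(record = rec_path, atline = obs_path, meta = meta_path)))
}

not_computed <- function(reason) structure(list(reason = reason), class = "not_computed")

#' Analyze fermentation records, particle tables and SAXS curves
#'
#' Runs whichever analytics the supplied inputs allow and assembles a
#' report bundle mirroring the study's summary tables: growth /
#' consumption / yield statistics with controller performance per record,
#' particle-size and per-cell summaries, and the SAXS sphere-fit +
#' membrane/core decomposition. Missing input classes yield explicit
#' `not_computed` markers rather than empty sections.
#'
#' @param records a `fermentation_record`, list of records, or character
#'   paths of record CSVs (replicates of one condition).
#' @param particles a `particle_dataset` or `c(particles_path, cells_path)`.
#' @param saxs a `saxs_curve` (already reduced) or a path to a `.dat` file.
#' @param condition condition label; default from the first record.
#' @param window growth window; default per condition.
#' @param od_to_dw biomass conversion, g_dw L^-1 per OD.
#' @param membrane_thickness_nm membrane thickness subtracted from the
#'   SAXS diameter for the core estimate.
#' @param band half-width (percentage points) for the time-in-band
#'   controller metric.
#' @return an object of class `report_bundle`.
#' @export
run_analysis <- function(records = NULL, particles = NULL, saxs = NULL,
                         condition = NULL, window = NULL,
                         od_to_dw = 0.4 / 1.4,
                         membrane_thickness_nm = 1.7,
                         band = 1) {
  stop_if(is.null(records) && is.null(particles) && is.null(saxs),
          "at least one input class (records, particles, saxs) is required")
  report <- list()

  if (!is.null(records)) {
    if (is.character(records)) records <- lapply(records, read_record)
    if (inherits(records, "fermentation_record")) records <- list(records)
    if (is.null(condition)) condition <- attr(records[[1]], "condition") %||% "custom"
    if (is.null(window)) window <- growth_window(condition)
    mu <- fit_growth_rate(records, window = window)
    per_rec <- lapply(records, function(r) {
      mu_r <- fit_growth_rate(r$time_h, r$od565, window)$value
      q_lac <- consumption_rate(r$time_h, r$lactate_mM, r$od565, window)$value
      q_no3 <- consumption_rate(r$time_h, r$nitrate_mM, r$od565, window)$value
      i_max <- which.max(r$od565)
      d_od <- r$od565[i_max] - r$od565[1]
      d_lac <- r$lactate_mM[1] - r$lactate_mM[i_max]
      d_no3 <- r$nitrate_mM[1] - r$nitrate_mM[i_max]
      y_lac <- if (d_lac > 0) yield_per_substrate(d_od, d_lac, od_to_dw, "lactate")$value else NA
      y_no3 <- if (d_no3 > 0) yield_per_substrate(d_od, d_no3, od_to_dw, "nitrate")$value else NA
      iron_end <- r$fe_mg_per_gdw[nrow(r)]
      t_end <- r$time_h[nrow(r)]
      c(mu = mu_r, doubling_time_h = doubling_time(mu_r),
        q_lac = q_lac, q_no3 = q_no3,
        y_lac = y_lac, y_no3 = y_no3,
        od_max = max(r$od565), iron_mg_gdw = iron_end,
        cmag = r$cmag[nrow(r)],
        productivity_mg_l_h = magnetite_productivity(
          iron_end, max(r$od565) * od_to_dw, t_end))
    })
    tab <- do.call(rbind, per_rec)
    report$growth <- list(
      condition = condition, window = window, od_to_dw = od_to_dw,
      per_replicate = as.data.frame(tab),
      pooled = apply(tab, 2, mean, na.rm = TRUE),
      pooled_sd = apply(tab, 2, stats::sd, na.rm = TRUE),
      mu = mu)
    report$controller <- lapply(records, function(r) {
      sp <- attr(r, "params")$do2_nominal %||% NA
      dev <- if (is.na(sp)) NA else abs(r$dO2_pct - sp)
      list(median_do2 = stats::median(r$dO2_pct),
           fluctuation_sd = stats::sd(r$dO2_pct),
           time_in_band = if (is.na(sp)) NA else mean(dev <= band),
           set_point = sp)
    })
  } else {
    report$growth <- not_computed("no fermentation records supplied")
    report$controller <- not_computed("no fermentation records supplied")
  }

  if (!is.null(particles)) {
    if (is.character(particles))
      particles <- read_particles(particles[1],
                                  if (length(particles) > 1) particles[2] else NULL)
    sizes <- summarize_sizes(particles)
    dens <- if (nrow(particles$cells %||% data.frame()) > 0)
      per_cell_density(particles) else not_computed("no cell table supplied")
    report$particles <- list(sizes = sizes, per_cell = dens)
  } else {
    report$particles <- not_computed("no particle tables supplied")
  }

  if (!is.null(saxs)) {
    if (is.character(saxs)) saxs <- read_saxs(saxs)
    fit <- fit_sphere_model(saxs)
    report$saxs <- list(
      fit = fit,
      first_minimum_q = find_first_minimum(saxs),
      membrane_thickness_nm = membrane_thickness_nm,
      core_diameter_nm = core_diameter(fit$mean_diameter_nm, membrane_thickness_nm))
  } else {
    report$saxs <- not_computed("no SAXS curve supplied")
  }

  structure(report, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  if (!inherits(x$growth, "not_computed")) {
    g <- x$growth
    cat(sprintf("  growth [%s, window %g-%g h]: mu = %.3f +/- %.3f h^-1, q_lac = %.2f, q_NO3 = %.2f mM h^-1 OD^-1\n",
                g$condition, g$window[1], g$window[2],
                g$pooled[["mu"]], if (is.na(g$pooled_sd[["mu"]])) 0 else g$pooled_sd[["mu"]],
                g$pooled[["q_lac"]], g$pooled[["q_no3"]]))
  } else cat("  growth: not computed —", x$growth$reason, "\n")
  if (!inherits(x$particles, "not_computed")) {
    s <- x$particles$sizes
    cat(sprintf("  particles: %.1f +/- %.1f nm (n = %d), %.1f%% > %g nm\n",
                s$mean, s$sd, s$n, 100 * s$fraction_above, s$threshold_nm))
  } else cat("  particles: not computed —", x$particles$reason, "\n")
  if (!inherits(x$saxs, "not_computed")) {
    cat(sprintf("  saxs: 2R = %.1f nm, core = %.1f nm (membrane %.1f nm)\n",
                x$saxs$fit$mean_diameter_nm, x$saxs$core_diameter_nm,
                x$saxs$membrane_thickness_nm))
  } else cat("  saxs: not computed —", x$saxs$reason, "\n")
  invisible(x)
}

strip_unserializable <- function(x) {
  if (inherits(x, "not_computed")) return(list(not_computed = x$reason))
  if (inherits(x, "sphere_fit")) x$fit <- NULL
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip_unserializable))
  x
}

#' Write a report bundle as JSON
#'
#' @param report a `report_bundle` from [run_analysis()].
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  payload <- strip_unserializable(unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
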