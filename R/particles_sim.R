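# Synthetic TEM particle datasets: Gaussian diameter samples and per-cell
# counts/lengths following the measured condition-wise trajectories.

# Condition-wise magnetosome trajectories (diameter mean/sd in nm, cell
# length mean/sd in um, magnetosomes per cell) at the measured process
# times; values between timepoints are linearly interpolated, outside they
# are held constant.
size_trajectory <- function(regime) {
  tab <- list(
    anoxic0 = data.frame(
      timepoint_h = c(0, 15, 20, 34),
      diam_mean = c(25.8, 32.0, 33.5, 33.8),
      diam_sd   = c(8.9, 9.5, 9.1, 9.4),
      len_mean  = c(3.0, 2.9, 3.0, 3.1),
      len_sd    = c(0.7, 0.6, 0.8, 0.7),
      count_mean = c(24.4, 25.6, 25.5, 25.3)),
    microoxic1 = data.frame(
      timepoint_h = c(0, 14, 18),
      diam_mean = c(26.7, 26.7, 29.3),
      diam_sd   = c(8.5, 8.4, 7.9),
      len_mean  = c(3.3, 3.1, 3.4),
      len_sd    = c(0.8, 0.8, 0.9),
      count_mean = c(29.2, 27.9, 28.4)))
  stop_if(!regime %in% names(tab),
          sprintf("unknown regime '%s'; available: %s", regime,
                  paste(names(tab), collapse = ", ")))
  tab[[regime]]
}

interp_trajectory <- function(traj, timepoint) {
  vapply(setdiff(names(traj), "timepoint_h"), function(col)
    stats::approx(traj$timepoint_h, traj[[col]], xout = timepoint, rule = 2)$y,
    numeric(1))
}

#' Draw a synthetic magnetosome particle dataset
#'
#' Emulates the quantitative TEM workflow: per biological replicate,
#' `n_per_replicate` particle diameters are drawn from a Gaussian with the
#' condition- and time-interpolated mean and standard deviation (redrawing
#' non-positive values), and a companion cell table records per-cell
#' magnetosome counts and cell lengths. The empirical distributions of real
#' micrograph measurements are visibly non-Gaussian; the Gaussian stand-in
#' matches their first two moments only.
#'
#' @param regime `"anoxic0"` or `"microoxic1"` (timepoint 0 is the
#'   seed-train culture).
#' @param timepoint process time, hours.
#' @param n_per_replicate particles measured per replicate (about 1000 in
#'   the TEM protocol).
#' @param replicates number of biological replicates pooled.
#' @param n_cells cells measured per replicate for the cell table.
#' @param count_sd residual between-cell standard deviation of the
#'   magnetosome count around its length-proportional expectation.
#' @param seed integer seed.
#' @return an object of class `particle_dataset`: list with data.frames
#'   `particles` (`condition`, `replicate`, `timepoint_h`, `diameter_nm`)
#'   and `cells` (`condition`, `replicate`, `timepoint_h`, `cell_id`,
#'   `length_um`, `ms_count`).
#' @export
sample_particles <- function(regime, timepoint,
                             n_per_replicate = 1000, replicates = 3,
                             n_cells = 100, count_sd = 2.5, seed = 1) {
  traj <- size_trajectory(regime)
  stop_if(timepoint < 0, "timepoint must be >= 0")
  stop_if(n_per_replicate < 0, "n_per_replicate must be >= 0")
  p <- interp_trajectory(traj, timepoint)
  with_seed(seed, {
    parts <- lapply(seq_len(replicates), function(r) {
      d <- numeric(0)
      while (length(d) < n_per_replicate) {
        draw <- stats::rnorm(n_per_replicate - length(d), p[["diam_mean"]], p[["diam_sd"]])
        d <- c(d, draw[draw > 0])
      }
      data.frame(condition = rep(regime, length(d)),
                 replicate = rep(r, length(d)),
                 timepoint_h = rep(timepoint, length(d)),
                 diameter_nm = d)
    })
    cells <- lapply(seq_len(replicates), function(r) {
      len <- stats::rnorm(n_cells, p[["len_mean"]], p[["len_sd"]])
      len[len <= 0.2] <- 0.2
      # chains run along the cell axis: expected count scales with length
      dens <- p[["count_mean"]] / p[["len_mean"]]
      cnt <- pmax(round(stats::rnorm(n_cells, dens * len, count_sd)), 0)
      data.frame(condition = regime, replicate = r, timepoint_h = timepoint,
                 cell_id = seq_len(n_cells), length_um = len, ms_count = cnt)
    })
    structure(list(particles = do.call(rbind, parts),
                   cells = do.call(rbind, cells)),
              class = "particle_dataset")
  })
}

#' @export
print.particle_dataset <- function(x, ...) {
  cat(sprintf("particle_dataset: %d particles, %d cells (%s)\n",
              nrow(x$particles), nrow(x$cells),
              paste(unique(x$particles$condition), collapse = ", ")))
  invisible(x)
}
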