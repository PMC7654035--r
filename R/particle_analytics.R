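# Magnetosome particle statistics: pooling, size summaries, per-cell
# densities and the rank-sum comparison used for condition contrasts.

particles_of <- function(dataset) {
  if (inherits(dataset, "particle_dataset")) dataset$particles else dataset
}

#' Pool particle measurements across replicates
#'
#' Concatenates the per-replicate particle measurements of one condition
#' and timepoint (the TEM protocol counts ~1000 particles per replicate and
#' combines the triplicate for evaluation), preserving provenance columns.
#'
#' @param dataset a `particle_dataset` or a particles data.frame with
#'   columns `condition`, `replicate`, `timepoint_h`, `diameter_nm`.
#' @param condition condition label to select.
#' @param timepoint process time (hours) to select.
#' @return data.frame of pooled rows.
#' @export
pool_triplicates <- function(dataset, condition, timepoint) {
  df <- particles_of(dataset)
  keys <- unique(df[, c("condition", "timepoint_h")])
  idx <- df$condition == condition & abs(df$timepoint_h - timepoint) < 1e-8
  stop_if(!any(idx), sprintf(
    "no particles for condition '%s' at %g h; available: %s",
    condition, timepoint,
    paste(sprintf("%s@%gh", keys$condition, keys$timepoint_h), collapse = ", ")))
  out <- df[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a particle-size sample
#'
#' Arithmetic mean, sample standard deviation (n - 1), median,
#' interquartile range and the fraction of particles strictly larger than
#' the threshold (default 30 nm, the size class reported to survive
#' magnetosome isolation).
#'
#' @param diameters particle diameters in nm (or a `particle_dataset` /
#'   particles data.frame, whose `diameter_nm` column is used).
#' @param threshold_nm exceedance threshold, nm.
#' @return an object of class `size_summary`: list with `n`, `mean`, `sd`,
#'   `median`, `iqr`, `fraction_above`.
#' @export
summarize_sizes <- function(diameters, threshold_nm = 30) {
  if (is.data.frame(diameters) || inherits(diameters, "particle_dataset"))
    diameters <- particles_of(diameters)$diameter_nm
  bad <- which(!is.finite(diameters) | diameters <= 0)
  stop_if(length(bad) > 0,
          sprintf("non-positive diameter at row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  stop_if(length(diameters) < 2, "need at least 2 diameters")
  structure(list(n = length(diameters),
                 mean = mean(diameters),
                 sd = stats::sd(diameters),
                 median = stats::median(diameters),
                 iqr = stats::IQR(diameters),
                 fraction_above = mean(diameters > threshold_nm),
                 threshold_nm = threshold_nm),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("n = %d: %.1f +/- %.1f nm (median %.1f, IQR %.1f); %.1f%% > %g nm\n",
              x$n, x$mean, x$sd, x$median, x$iqr,
              100 * x$fraction_above, x$threshold_nm))
  invisible(x)
}

#' Per-cell magnetosome density
#'
#' Mean and standard deviation of the magnetosome count per cell and of
#' the count normalized to cell length. The per-micron figure is the mean
#' of per-cell ratios (not the ratio of means), matching the spread seen
#' in per-cell measurements.
#'
#' @param cell_table data.frame with `length_um` and `ms_count` (as in a
#'   `particle_dataset$cells`), or a `particle_dataset`.
#' @return list with `ms_per_cell` and `ms_per_um`, each `c(mean, sd)`,
#'   and `n_cells`.
#' @export
per_cell_density <- function(cell_table) {
  if (inherits(cell_table, "particle_dataset")) cell_table <- cell_table$cells
  stop_if(nrow(cell_table) == 0, "empty cell table")
  stop_if(any(cell_table$length_um <= 0), "zero-length cell rejected")
  ratio <- cell_table$ms_count / cell_table$length_um
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(ms_per_cell = c(mean = mean(cell_table$ms_count), sd = sd0(cell_table$ms_count)),
       ms_per_um = c(mean = mean(ratio), sd = sd0(ratio)),
       n_cells = nrow(cell_table))
}

# tie-corrected normal-approximation variance of the rank sum
ranksum_var <- function(pooled, na, nb) {
  N <- na + nb
  ties <- table(pooled)
  corr <- sum(ties^3 - ties) / (N * (N - 1))
  na * nb / 12 * ((N + 1) - corr)
}

#' Wilcoxon rank-sum test (two-sample, two-sided)
#'
#' Rank-sum statistic with midranks for ties. The p-value is exact where
#' tractable — via the exact null distribution for tie-free samples, or by
#' full enumeration of rank assignments when ties are present and
#' `n_a + n_b <= 12` — and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction. Two-sided p-values
#' double the smaller tail, capped at 1.
#'
#' @param a,b numeric samples (diameters).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (rank sum of `a`, midranks), `p_value`,
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stop_if(length(a) == 0 || length(b) == 0, "both samples must be non-empty")
  check_finite(c(a, b), "samples")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(na)])
  has_ties <- anyDuplicated(pooled) > 0

  exact_feasible <- !has_ties || N <= 12
  use_exact <- switch(mode,
    exact = {
      stop_if(!exact_feasible,
              "exact mode with ties needs n_a + n_b <= 12; use mode = 'normal'")
      TRUE
    },
    normal = FALSE,
    auto = exact_feasible && N <= 50)

  if (use_exact) {
    if (!has_ties) {
      # exact null distribution of U = W - na(na+1)/2
      U <- W - na * (na + 1) / 2
      p_le <- stats::pwilcox(U, na, nb)
      p_ge <- 1 - stats::pwilcox(U - 1, na, nb)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact (rank-sum null distribution)"
    } else {
      combos <- utils::combn(N, na)
      Ws <- colSums(matrix(rk[combos], nrow = na))
      p_le <- mean(Ws <= W + 1e-9)
      p_ge <- mean(Ws >= W - 1e-9)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact (enumeration with midranks)"
    }
  } else {
    mu <- na * (N + 1) / 2
    sigma <- sqrt(ranksum_var(pooled, na, nb))
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  list(statistic = W, p_value = p, method = method)
}
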