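# Small-angle X-ray scattering toolkit: curve container and reduction,
# sphere form factor with Gaussian polydispersity, Guinier analyses and the
# membrane/core size decomposition. q is always in inverse Angstrom;
# reported lengths are in nm (1 nm = 10 Angstrom).

FIRST_SPHERE_ZERO <- 4.493409457909064  # first positive root of tan(x) = x

#' SAXS curve container
#'
#' A one-dimensional scattering profile I(q) with uncertainties and the
#' reduction metadata (accumulation time, sample thickness, transmission)
#' needed for normalization.
#'
#' @param q scattering vector, inverse Angstrom, strictly increasing, > 0.
#' @param intensity intensities, arbitrary units.
#' @param sigma 1-sigma uncertainties (same units); default 0.
#' @param accumulation_time,thickness,transmission normalization metadata
#'   (positive; default 1, i.e. already normalized).
#' @return an object of class `saxs_curve`.
#' @export
saxs_curve <- function(q, intensity, sigma = rep(0, length(q)),
                       accumulation_time = 1, thickness = 1, transmission = 1) {
  stop_if(length(q) == 0, "empty curve")
  stop_if(any(q <= 0), "q must be > 0")
  stop_if(any(diff(q) <= 0), "q must be strictly increasing")
  check_finite(intensity, "intensity")
  stop_if(length(intensity) != length(q) || length(sigma) != length(q),
          "q, intensity and sigma must have equal length")
  stop_if(any(sigma < 0), "sigma must be >= 0")
  check_positive(c(accumulation_time, thickness, transmission), "normalization metadata")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 accumulation_time = accumulation_time,
                 thickness = thickness, transmission = transmission),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve: %d points, q = %.4g-%.4g A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Normalize and background-subtract a SAXS curve
#'
#' Each curve is normalized to accumulation time, sample thickness and
#' transmission; the normalized buffer scattering is then subtracted:
#' `I_red = I_s/(t_s d_s T_s) - I_b/(t_b d_b T_b)`. Uncertainties propagate
#' in quadrature. If the q grids differ, the buffer is interpolated onto
#' the sample grid; sample points outside the buffer's q range are dropped
#' with a warning.
#'
#' @param sample,buffer `saxs_curve` objects.
#' @return a reduced `saxs_curve` (metadata reset to 1).
#' @export
reduce_curve <- function(sample, buffer) {
  stopifnot(inherits(sample, "saxs_curve"), inherits(buffer, "saxs_curve"))
  ns <- sample$accumulation_time * sample$thickness * sample$transmission
  nb <- buffer$accumulation_time * buffer$thickness * buffer$transmission
  inside <- sample$q >= min(buffer$q) & sample$q <= max(buffer$q)
  stop_if(sum(inside) < 2, "q ranges do not overlap enough for subtraction")
  if (any(!inside))
    warning(sprintf("%d sample point(s) outside buffer q range dropped", sum(!inside)))
  q <- sample$q[inside]
  ib <- stats::approx(buffer$q, buffer$intensity, xout = q)$y
  sb <- stats::approx(buffer$q, buffer$sigma, xout = q)$y
  saxs_curve(q,
             sample$intensity[inside] / ns - ib / nb,
             sqrt((sample$sigma[inside] / ns)^2 + (sb / nb)^2))
}

#' Sphere form factor
#'
#' Normalized single-sphere scattering `P(q) = [3 (sin x - x cos x)/x^3]^2`
#' with `x = qR`; `P(0) = 1` by the analytic limit (a series expansion is
#' used for small `x` to avoid cancellation).
#'
#' @param q scattering vector, inverse Angstrom (vectorized).
#' @param radius sphere radius in Angstrom.
#' @return P(q), dimensionless, in \[0, 1\].
#' @export
sphere_form_factor <- function(q, radius) {
  stop_if(any(q < 0), "q must be >= 0")
  check_positive(radius, "radius")
  x <- q * radius
  amp <- ifelse(x < 1e-2,
                1 - x^2 / 10 + x^4 / 280,
                3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

#' Polydisperse-sphere model intensity
#'
#' Gaussian number distribution of sphere diameters, averaged numerically
#' over `n_nodes` quadrature points truncated at +/- 4 standard deviations
#' (non-positive radii excluded, weights renormalized), with each radius
#' contributing its volume-squared weight R^6:
#' `I(q) = scale * <(R/nm)^6 P(q, R)> + background`.
#' At `sd = 0` this reduces exactly to the monodisperse
#' `scale * (R/nm)^6 * P(q, R) + background`.
#'
#' @param q scattering vector, inverse Angstrom.
#' @param mean_diameter_nm mean of the diameter distribution, nm.
#' @param sd_nm standard deviation of the diameter distribution, nm.
#' @param scale intensity scale factor.
#' @param background flat background.
#' @param n_nodes number of quadrature nodes (>= 51 for smooth averages).
#' @return model intensities on `q`.
#' @export
polydisperse_intensity <- function(q, mean_diameter_nm, sd_nm,
                                   scale = 1, background = 0, n_nodes = 101) {
  check_positive(mean_diameter_nm, "mean_diameter_nm")
  stop_if(sd_nm < 0, "sd_nm must be >= 0")
  r_mean <- mean_diameter_nm / 2          # nm
  r_sd <- sd_nm / 2
  if (r_sd == 0)
    return(scale * r_mean^6 * sphere_form_factor(q, 10 * r_mean) + background)
  if (stats::pnorm(0, r_mean, r_sd) > 0.1)
    warning("more than 10% of the size distribution lies at non-positive radii (truncated)")
  nodes <- seq(r_mean - 4 * r_sd, r_mean + 4 * r_sd, length.out = n_nodes)
  keep <- nodes > 0
  nodes <- nodes[keep]
  w <- stats::dnorm(nodes, r_mean, r_sd)
  w <- w / sum(w)
  acc <- numeric(length(q))
  for (i in seq_along(nodes))
    acc <- acc + w[i] * nodes[i]^6 * sphere_form_factor(q, 10 * nodes[i])
  scale * acc + background
}

#' Pearl-chain model intensity
#'
#' Magnetosomes sit in linear chains; the dilute-sphere model ignores the
#' inter-particle interference this causes. This optional variant multiplies
#' the polydisperse sphere form factor by the structure factor of a linear
#' chain of `n_pearls` touching pearls with center spacing equal to the
#' mean diameter:
#' `S(q) = 1 + (2/N) * sum_{k=1}^{N-1} (N-k) * sin(q k d) / (q k d)`.
#' `S` tends to `N` at low q and to 1 at high q, so the size-determining
#' features (the first form-factor minimum) are barely affected — the
#' rationale for using the dilute limit in the standard analysis.
#'
#' @inheritParams polydisperse_intensity
#' @param n_pearls number of pearls in the chain (1 recovers the dilute
#'   sphere model exactly).
#' @return model intensities on `q`.
#' @export
pearl_chain_intensity <- function(q, mean_diameter_nm, sd_nm,
                                  scale = 1, background = 0, n_pearls = 1,
                                  n_nodes = 101) {
  stop_if(n_pearls < 1 || n_pearls != round(n_pearls),
          "'n_pearls' must be a positive integer")
  base <- polydisperse_intensity(q, mean_diameter_nm, sd_nm, scale, 0, n_nodes)
  if (n_pearls > 1) {
    d <- 10 * mean_diameter_nm            # center spacing, Angstrom
    S <- rep(1, length(q))
    for (k in seq_len(n_pearls - 1)) {
      x <- q * k * d
      S <- S + (2 / n_pearls) * (n_pearls - k) * ifelse(x < 1e-8, 1, sin(x) / x)
    }
    base <- base * S
  }
  base + background
}

#' Sphere radius from the first form-factor minimum
#'
#' The first zero of the sphere form factor sits at `qR = x1` with `x1 =
#' 4.49340946...` (first positive root of `tan x = x`), so a minimum
#' observed at `q_min` implies `R = x1 / q_min`.
#'
#' @param q_min position of the first intensity minimum, inverse Angstrom.
#' @return sphere radius in Angstrom.
#' @export
first_minimum_radius <- function(q_min) {
  check_positive(q_min, "q_min")
  FIRST_SPHERE_ZERO / q_min
}

#' Guinier fit
#'
#' Linear fit of `ln I` against `q^2` over the given q window:
#' `Rg = sqrt(-3 * slope)`. The fit is flagged invalid when
#' `q_max * Rg` exceeds the validity bound (1.3, the customary limit for
#' globular scatterers); a non-decaying profile (slope >= 0) is rejected.
#'
#' @param curve a `saxs_curve`.
#' @param q_range numeric(2) window in inverse Angstrom.
#' @param validity_bound maximal admissible `q_max * Rg`.
#' @return an object of class `guinier_result`: list with `rg_nm`,
#'   `intercept`, `q_range`, `qmax_rg`, `valid`, and
#'   `equivalent_sphere_radius_nm` (= sqrt(5/3) Rg).
#' @export
guinier_fit <- function(curve, q_range, validity_bound = 1.3) {
  stopifnot(inherits(curve, "saxs_curve"))
  idx <- curve$q >= q_range[1] & curve$q <= q_range[2] & curve$intensity > 0
  stop_if(sum(idx) < 5, "need at least 5 positive-intensity points in the Guinier window")
  q2 <- curve$q[idx]^2
  fit <- stats::lm(log(curve$intensity[idx]) ~ q2)
  slope <- unname(stats::coef(fit)[2])
  stop_if(slope >= 0, "intensity does not decay over the window: not a Guinier regime")
  rg_A <- sqrt(-3 * slope)
  qmax_rg <- max(curve$q[idx]) * rg_A
  structure(list(rg_nm = rg_A / 10,
                 intercept = unname(stats::coef(fit)[1]),
                 q_range = q_range,
                 qmax_rg = qmax_rg,
                 valid = qmax_rg <= validity_bound,
                 equivalent_sphere_radius_nm = sqrt(5 / 3) * rg_A / 10),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.3g nm (q %.3g-%.3g A^-1, qmax*Rg = %.2f%s)\n",
              x$rg_nm, x$q_range[1], x$q_range[2], x$qmax_rg,
              if (x$valid) "" else ", OUTSIDE validity bound"))
  invisible(x)
}

#' Solid-sphere radius from a radius of gyration
#'
#' `R = sqrt(5/3) * Rg` for a homogeneous sphere. Applied to the Guinier
#' radius of the empty-vesicle envelope scattering, this yields the
#' membrane-subunit radius used as the membrane-thickness estimate.
#'
#' @param rg radius of gyration (any length unit).
#' @return radius in the same unit.
#' @export
radius_from_rg <- function(rg) {
  check_positive(rg, "rg")
  sqrt(5 / 3) * rg
}

#' Magnetite core diameter from the overall SAXS diameter
#'
#' TEM contrast is dominated by the magnetite core, whereas the SAXS
#' diameter includes the enveloping membrane; the membrane thickness is
#' subtracted on both sides before comparison:
#' `d_core = 2R_overall - 2 * membrane`.
#'
#' @param overall_2r overall particle diameter from the sphere fit, nm.
#' @param membrane_thickness membrane thickness, nm.
#' @return core diameter in nm.
#' @export
core_diameter <- function(overall_2r, membrane_thickness) {
  check_positive(overall_2r, "overall_2r")
  stop_if(membrane_thickness < 0, "membrane thickness must be >= 0")
  stop_if(membrane_thickness >= overall_2r / 2,
          "membrane thickness >= particle radius: non-physical")
  overall_2r - 2 * membrane_thickness
}

#' Flake-like (platelet) Guinier analysis
#'
#' Cross-section analysis for thin, plate-like scatterers: the thickness
#' follows from the modified Guinier plot `ln(I q^2)` vs `q^2`
#' (`T = sqrt(12) * Rg_t`), and the radial size from the standard low-q
#' Guinier radius corrected for the flat-particle relation
#' `Rg^2 = R^2/2 + T^2/12`. The `flake_like` flag requires both a nearly
#' linear cross-section plot (R^2 >= 0.9; globular scatterers decay as
#' q^-4 and curve strongly there) and a thickness well below the diameter;
#' a globular input fails the discriminant.
#'
#' @param curve a `saxs_curve` covering the low and intermediate q range.
#' @param thickness_window numeric(2), q window for the cross-section plot,
#'   inverse Angstrom.
#' @param radius_window numeric(2), low-q window for the radial Guinier;
#'   default from the curve minimum up to 0.016.
#' @return list with `radius_nm`, `thickness_nm`, `rg_t_nm`,
#'   `cross_section_r2`, `flake_like`.
#' @export
disc_guinier <- function(curve, thickness_window = c(0.04, 0.10),
                         radius_window = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (is.null(radius_window)) radius_window <- c(min(curve$q), 0.016)
  it <- curve$q >= thickness_window[1] & curve$q <= thickness_window[2] &
    curve$intensity > 0
  stop_if(sum(it) < 5, "thickness window too narrow (need >= 5 points)")
  q2 <- curve$q[it]^2
  ft <- stats::lm(log(curve$intensity[it] * q2) ~ q2)
  slope_t <- unname(stats::coef(ft)[2])
  stop_if(slope_t >= 0,
          "no cross-section decay in the thickness window (zero-thickness or non-platelet)")
  rg_t <- sqrt(-slope_t)                       # Angstrom
  thickness <- sqrt(12) * rg_t
  stop_if(thickness < 1,
          "cross-section thickness below resolution: zero-thickness limit")
  g <- guinier_fit(curve, radius_window, validity_bound = 1.4)
  rg <- g$rg_nm * 10
  disc2 <- 2 * (rg^2 - thickness^2 / 12)
  stop_if(disc2 <= 0, "overall Rg smaller than thickness contribution: not flake-like")
  radius <- sqrt(disc2)
  r2 <- summary(ft)$r.squared
  list(radius_nm = radius / 10,
       thickness_nm = thickness / 10,
       rg_t_nm = rg_t / 10,
       cross_section_r2 = r2,
       flake_like = r2 >= 0.9 && thickness < (2 * radius) / 3)
}

#' Generate a synthetic polydisperse-sphere SAXS curve
#'
#' Model intensity from [polydisperse_intensity()] plus Gaussian noise with
#' `sd = max(floor, fraction * I)`; the sigma column reports the true noise
#' level used.
#'
#' @param q q grid, inverse Angstrom.
#' @param mean_diameter_nm,sd_nm,scale,background model parameters.
#' @param noise_frac relative noise level.
#' @param noise_floor absolute noise floor.
#' @param seed integer seed.
#' @return a `saxs_curve`.
#' @export
synth_curve <- function(q, mean_diameter_nm = 39, sd_nm = 7,
                        scale = 1, background = 0,
                        noise_frac = 0.02, noise_floor = 0, seed = 1) {
  model <- polydisperse_intensity(q, mean_diameter_nm, sd_nm, scale, background)
  sigma <- pmax(noise_floor, noise_frac * model)
  intensity <- with_seed(seed, model + stats::rnorm(length(q), 0, sigma))
  saxs_curve(q, intensity, sigma)
}

#' Fit the polydisperse-sphere model to a reduced curve
#'
#' Levenberg-Marquardt least squares of [polydisperse_intensity()] against
#' the measured intensities, weighted by the reported uncertainties where
#' available. Starting values default to the first-minimum diameter
#' estimate and a relative polydispersity of 20%.
#'
#' @param curve a `saxs_curve`.
#' @param start optional named list/vector with `mean_diameter_nm`,
#'   `sd_nm`, `scale`, `background`.
#' @param fit_background fit a flat background term (default TRUE).
#' @return an object of class `sphere_fit`: list with `mean_diameter_nm`,
#'   `sd_nm`, `scale`, `background`, `gof` (reduced chi-square against
#'   sigma where available, else residual standard error), and the `fit`
#'   object.
#' @export
fit_sphere_model <- function(curve, start = NULL, fit_background = TRUE) {
  stopifnot(inherits(curve, "saxs_curve"))
  q <- curve$q; I <- curve$intensity
  if (is.null(start)) {
    qm <- find_first_minimum(curve)
    d0 <- if (is.na(qm)) 30 else 2 * first_minimum_radius(qm) / 10
    start <- list(mean_diameter_nm = d0, sd_nm = 0.2 * d0,
                  scale = max(I) / (d0 / 2)^6, background = 0)
  }
  w <- if (any(curve$sigma > 0)) 1 / pmax(curve$sigma, max(curve$sigma) * 1e-3)^2
       else rep(1, length(q))
  df <- data.frame(q = q, I = I)
  fml <- if (fit_background)
    I ~ suppressWarnings(polydisperse_intensity(q, m, s, exp(lsc), bg))
  else I ~ suppressWarnings(polydisperse_intensity(q, m, s, exp(lsc), 0))
  st <- list(m = start$mean_diameter_nm, s = start$sd_nm,
             lsc = log(max(start$scale, 1e-300)))
  lower <- c(m = 1, s = 0.01, lsc = -Inf)
  if (fit_background) { st$bg <- start$background; lower <- c(lower, bg = -Inf) }
  fit <- minpack.lm::nlsLM(fml, data = df, start = st, weights = w,
                           lower = lower,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid <- I - stats::predict(fit)
  gof <- if (any(curve$sigma > 0))
    sum((resid / pmax(curve$sigma, 1e-300))^2) / (length(q) - length(cf))
  else sqrt(sum(resid^2) / (length(q) - length(cf)))
  structure(list(mean_diameter_nm = unname(cf[["m"]]),
                 sd_nm = unname(cf[["s"]]),
                 scale = exp(unname(cf[["lsc"]])),
                 background = if (fit_background) unname(cf[["bg"]]) else 0,
                 gof = gof, fit = fit),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere fit: 2R = %.2f nm, Gaussian sd = %.2f nm (gof %.3g)\n",
              x$mean_diameter_nm, x$sd_nm, x$gof))
  invisible(x)
}

#' Locate the first form-factor minimum of a curve
#'
#' Searches the Porod-weighted intensity `q^4 I(q)`, in which the steep
#' power-law decay is flattened so that even a polydispersity-smeared
#' first minimum appears as a genuine local minimum. A light running-mean
#' smooth suppresses noise-induced spurious minima.
#'
#' @param curve a `saxs_curve`.
#' @param q_window search window, inverse Angstrom.
#' @return q position of the first interior local minimum of `q^4 I`, or
#'   `NA` if none.
#' @export
find_first_minimum <- function(curve, q_window = c(0.015, 0.06)) {
  idx <- which(curve$q >= q_window[1] & curve$q <= q_window[2])
  if (length(idx) < 5) return(NA_real_)
  y <- curve$q[idx]^4 * curve$intensity[idx]
  k <- min(7, 2 * (length(y) %/% 8) + 1)
  if (k >= 3) y <- stats::filter(y, rep(1 / k, k), sides = 2)
  interior <- which(diff(sign(diff(y))) > 0) + 1
  interior <- interior[!is.na(y[interior])]
  if (length(interior) == 0) return(NA_real_)
  curve$q[idx[interior[1]]]
}
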