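test_that("sphere form factor: limit, hand values and bracketed-root zeros", {
  expect_equal(sphere_form_factor(0, 100), 1)
  # at qR = pi, sin = 0: P = (3 pi / pi^3)^2 = (3/pi^2)^2
  expect_equal(sphere_form_factor(pi / 100, 100), (3 / pi^2)^2, tolerance = 1e-12)

  # zeros lie exactly at the roots of tan x = x (independent root-finder)
  for (k in 1:3) {
    lo <- (k + 0.26) * pi; hi <- (k + 0.49) * pi
    root <- uniroot(function(x) tan(x) - x, c(lo, hi), tol = 1e-14)$root
    expect_lt(sphere_form_factor(root / 50, 50), 1e-9)
  }

  # bounded in [0, 1] across the oscillating tail
  q <- seq(1e-5, 1, length.out = 4000)
  P <- sphere_form_factor(q, 30)
  expect_true(all(P >= 0 & P <= 1 + 1e-12))
  expect_error(sphere_form_factor(-0.1, 30), ">= 0")
})

test_that("polydisperse model collapses to monodisperse and fills the minimum", {
  q <- seq(0.005, 0.08, by = 0.0005)
  mono <- polydisperse_intensity(q, 39, 0, scale = 2, background = 0.1)
  expect_equal(mono, 2 * 19.5^6 * sphere_form_factor(q, 195) + 0.1)

  near0 <- polydisperse_intensity(q, 39, 1e-4, scale = 2, background = 0.1)
  expect_lt(max(abs(near0 - mono)) / max(mono), 1e-6)

  # polydispersity lifts the first form-factor minimum
  dip <- function(I) {
    w <- q >= 0.02 & q <= 0.04
    min(I[w]) / max(I)
  }
  expect_gt(dip(polydisperse_intensity(q, 39, 3.9)), 10 * dip(mono))

  expect_warning(polydisperse_intensity(q, 10, 9), "truncated")
})

test_that("pearl-chain structure factor boosts low q but preserves the minimum", {
  q <- seq(0.0005, 0.08, by = 0.0005)
  dilute <- pearl_chain_intensity(q, 39, 7, n_pearls = 1)
  expect_equal(dilute, polydisperse_intensity(q, 39, 7))

  chain <- pearl_chain_intensity(q, 39, 7, n_pearls = 5)
  # forward scattering approaches N times the dilute intensity
  expect_gt(chain[1] / dilute[1], 4.5)
  # interference decays away at high q
  n <- length(q)
  expect_lt(max(abs(chain[(n - 20):n] / dilute[(n - 20):n] - 1)), 0.1)
  # the first-minimum position is essentially unchanged
  qm_d <- find_first_minimum(saxs_curve(q, dilute))
  qm_c <- find_first_minimum(saxs_curve(q, chain))
  expect_lt(abs(qm_c - qm_d) / qm_d, 0.05)
  expect_error(pearl_chain_intensity(q, 39, 7, n_pearls = 2.5), "integer")
})

test_that("first-minimum estimator inverts the sphere zero relation", {
  expect_equal(first_minimum_radius(0.0449341), 100, tolerance = 1e-5)
  # at the q ~ 0.03 minimum the monodisperse relation gives 2R ~ 30 nm
  expect_equal(2 * first_minimum_radius(0.03) / 10, 29.96, tolerance = 1e-3)
  expect_equal(first_minimum_radius(0.01), 2 * first_minimum_radius(0.02))
  expect_error(first_minimum_radius(0), "> 0")
})

test_that("synthetic curves are seeded, honest about noise, and show the minimum", {
  q <- seq(0.003, 0.1, by = 0.0005)
  clean <- synth_curve(q, 39, 7, noise_frac = 0)
  expect_equal(clean$intensity, polydisperse_intensity(q, 39, 7))

  a <- synth_curve(q, 39, 7, noise_frac = 0.02, seed = 1)
  b <- synth_curve(q, 39, 7, noise_frac = 0.02, seed = 1)
  c <- synth_curve(q, 39, 7, noise_frac = 0.02, seed = 2)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
  expect_equal(a$sigma, c$sigma)  # same model, same noise level

  # smeared first minimum of the anoxic-like curve sits in 0.02-0.04
  qm <- find_first_minimum(clean)
  expect_gt(qm, 0.02); expect_lt(qm, 0.04)
})

test_that("sphere-model fit recovers generating parameters and ignores scale", {
  q <- seq(0.003, 0.1, by = 0.0005)
  cv <- synth_curve(q, 39, 7, scale = 1, noise_frac = 0.02, seed = 3)
  fit <- fit_sphere_model(cv)
  expect_lt(abs(fit$mean_diameter_nm - 39) / 39, 0.02)
  expect_lt(abs(fit$sd_nm - 7) / 7, 0.02)

  # intensity rescaling is absorbed entirely by the scale parameter
  cv10 <- saxs_curve(cv$q, 10 * cv$intensity, 10 * cv$sigma)
  fit10 <- fit_sphere_model(cv10)
  expect_equal(fit10$mean_diameter_nm, fit$mean_diameter_nm, tolerance = 1e-6)
  expect_equal(fit10$sd_nm, fit$sd_nm, tolerance = 1e-6)
  expect_equal(fit10$scale / fit$scale, 10, tolerance = 1e-4)

  # microoxic-like parameters are recovered as well
  cv2 <- synth_curve(q, 34, 7, scale = 5, noise_frac = 0.02, seed = 4)
  fit2 <- fit_sphere_model(cv2)
  expect_lt(abs(fit2$mean_diameter_nm - 34) / 34, 0.02)
})

test_that("Guinier analysis recovers sphere radii inside its validity range", {
  # R = 10 A sphere: Rg = sqrt(3/5) R = 7.746 A
  q <- seq(0.005, 0.15, by = 0.002)
  mono <- saxs_curve(q, sphere_form_factor(q, 10))
  g <- guinier_fit(mono, c(0.005, 0.15))
  expect_lt(abs(g$rg_nm * 10 - sqrt(3 / 5) * 10) / (sqrt(3 / 5) * 10), 0.02)
  expect_true(g$valid)
  expect_lt(abs(radius_from_rg(g$rg_nm) * 10 - 10) / 10, 0.02)

  # outside the validity bound the flag drops
  q2 <- seq(0.01, 0.3, by = 0.004)
  big <- saxs_curve(q2, sphere_form_factor(q2, 12))
  expect_false(guinier_fit(big, c(0.01, 0.3))$valid)

  # a flat curve has no Guinier decay
  flat <- saxs_curve(q, rep(2, length(q)))
  expect_error(guinier_fit(flat, c(0.005, 0.15)), "decay")

  # round trip across radii: recover R within 2% inside the validity range
  for (R in c(8, 15, 25)) {
    rg_true <- sqrt(3 / 5) * R
    qmax <- 1.2 / rg_true
    qq <- seq(qmax / 30, qmax, length.out = 40)
    cv <- saxs_curve(qq, 7 * sphere_form_factor(qq, R))
    gf <- guinier_fit(cv, range(qq))
    expect_true(gf$valid)
    expect_lt(abs(radius_from_rg(gf$rg_nm) * 10 - R) / R, 0.02)
  }
})

test_that("membrane and core arithmetic matches the size decomposition", {
  # Rg = 1.3 nm vesicle envelope: membrane thickness 1.7 nm at one decimal
  expect_equal(round(radius_from_rg(1.3), 1), 1.7)
  expect_equal(radius_from_rg(sqrt(3 / 5)), 1)

  expect_equal(core_diameter(39, 1.7), 35.6)
  expect_equal(core_diameter(34, 1.7), 30.6)
  expect_equal(core_diameter(10, 0), 10)
  expect_error(core_diameter(3, 1.7), "non-physical")
})

test_that("platelet Guinier analysis separates flakes from globules", {
  q <- seq(0.004, 0.15, by = 0.001)
  # thin disc R = 100 A, T = 35 A (flake-like oxic precursor scenario)
  disc <- saxs_curve(q, disc_intensity(q, 100, 35))
  d <- disc_guinier(disc)
  expect_lt(abs(d$radius_nm - 10), 1)
  expect_lt(abs(d$thickness_nm - 3.5), 0.4)
  expect_true(d$flake_like)

  # a globular scatterer fails the flake discriminant
  sph <- saxs_curve(q, sphere_form_factor(q, 30))
  res <- tryCatch(disc_guinier(sph), error = function(e) e)
  if (inherits(res, "error")) succeed() else expect_false(res$flake_like)

  # zero-thickness limit: thin-disc formula, rejected
  thin <- saxs_curve(q, disc_intensity(q, 100, 1e-6))
  expect_error(disc_guinier(thin), "thickness|decay")
})

test_that("curve reduction normalizes, self-subtracts and stays linear", {
  q <- seq(0.005, 0.1, by = 0.001)
  model <- polydisperse_intensity(q, 39, 7, scale = 1, background = 0.5)
  buf <- synth_curve(q, 39, 7, scale = 0, background = 0.5,
                     noise_frac = 0, noise_floor = 0.01, seed = 6)

  # buffer against itself: residual below the propagated uncertainty
  self <- reduce_curve(buf, buf)
  expect_true(all(abs(self$intensity) <= self$sigma + 1e-12))

  # doubling accumulation time with doubled counts is a no-op
  s1 <- saxs_curve(q, model, accumulation_time = 1)
  s2 <- saxs_curve(q, 2 * model, accumulation_time = 2)
  flatbuf <- saxs_curve(q, rep(0.5, length(q)))
  expect_equal(reduce_curve(s1, flatbuf)$intensity,
               reduce_curve(s2, flatbuf)$intensity)

  # round trip: sample + known flat background recovers the model
  sample <- synth_curve(q, 39, 7, scale = 1, background = 0.5,
                        noise_frac = 0.01, seed = 7)
  red <- reduce_curve(sample, flatbuf)
  expect_lt(max(abs(red$intensity - polydisperse_intensity(q, 39, 7))) /
              max(model), 0.05)

  # reduction is linear in the sample intensity
  sA <- saxs_curve(q, model); sB <- saxs_curve(q, 3 * model)
  sAB <- saxs_curve(q, 4 * model)
  expect_equal(reduce_curve(sA, flatbuf)$intensity +
                 reduce_curve(sB, flatbuf)$intensity + 0.5,  # extra subtraction
               reduce_curve(sAB, flatbuf)$intensity)

  # disjoint q ranges are rejected
  other <- saxs_curve(q + 1, model)
  expect_error(reduce_curve(s1, other), "overlap")
})
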