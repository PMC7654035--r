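---
title: "The oxystat digital twin: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oxystat digital twin: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetoferm)
```

# Scope

`magnetoferm` is a digital twin of an oxystat batch fermentation of
magnetotactic bacteria (*Magnetospirillum*-type physiology) together with
the analytics used to quantify growth and magnetosome biomineralization.
It has three layers:

1. a **control layer** — a discrete PI controller whose output drives a
   split-range cascade of quantized agitation (100–300 rpm) and airflow
   (0–10 SLPM) commands, plus a noisy, floor-limited dissolved-oxygen
   sensor;
2. a **plant layer** — an ODE model of batch growth on lactate with two
   respiratory routes (oxygen and nitrate), a kLa-limited oxygen balance,
   and first-order relaxation dynamics for cellular iron and mean crystal
   size;
3. an **analytics layer** — estimators for specific growth rate, specific
   consumption rates, yields, magnetite productivity and magnetic
   response; particle-size statistics with rank-sum tests; and a SAXS
   toolkit (sphere form factor with Gaussian polydispersity, Guinier
   analyses, membrane/core decomposition).

Everything is seeded and deterministic; no wet-lab data enter the package.

# The growth model

The specific growth rate combines Monod kinetics on lactate with an
electron-acceptor availability term:

$$
\mu(C, S_{lac}, S_{NO_3}) =
\left[\mu_{ox}\,\frac{C}{K_{O_2}+C}\,(1-sC)
+ \mu_{den}\,\frac{K_{fnr}}{K_{fnr}+C}\,
\frac{S_{NO_3}}{K_{NO_3}+S_{NO_3}}\right]
\frac{S_{lac}}{K_{lac}+S_{lac}},
$$

where $C$ is dissolved oxygen in percent air saturation. The first branch
is oxygen respiration, attenuated linearly in $C$ to represent oxidative
stress at high oxygen; the second is denitrification, repressed by oxygen
through an Fnr-type switch with half-repression constant $K_{fnr}$. With
neither acceptor available, $\mu = 0$.

Only condition-wise rates are published for this organism, not mechanistic
constants. The constructor therefore treats the three measured growth
rates as **fixed points**: given the half-saturation constants
($K_{lac} = 0.3$ mM, $K_{O_2} = 0.05$ %, $K_{fnr} = 0.3$ %,
$K_{NO_3} = 0.02$ mM), it solves the three coefficients
$(\mu_{ox}, s, \mu_{den})$ so that

```{r}
p <- kinetic_params("microoxic1")
c(oxic = growth_rate(p, 95, 15, 4),
  microoxic = growth_rate(p, 1, 15, 4),
  anoxic = growth_rate(p, 0, 15, 10))
```

equal 0.07, 0.15 and 0.13 h$^{-1}$ exactly at the calibration operating
points (95%/1%/0% dO2, 15 mM lactate, 4/4/10 mM nitrate). This gives the
model a mild growth optimum between 0 and 1% dO2 — consistent with the
organism's microaerophilic lifestyle — and implies that closed-loop
excursions below a microoxic set point slightly *raise* instantaneous
growth, a small upward bias (≈ +0.002 h$^{-1}$) visible in parameter
recovery.

Substrates are growth-coupled:

* lactate: $dS_{lac}/dt = -(\mu/Y^{OD}_{lac}) X$ with
  $Y^{OD}_{lac} = \mu^\ast/q^\ast_{lac}$ from the condition's nominal rate
  pair, so the biomass formed per lactate consumed equals the configured
  yield along the entire trajectory (a linear invariant the integrator
  preserves to ~1e-14);
* nitrate: assimilation plus Fnr-gated respiration,
  $dS_{NO_3}/dt = -[f_{as} + f_{resp}\frac{K_{fnr}}{K_{fnr}+C}
  \frac{S_{NO_3}}{K_{NO_3}+S_{NO_3}}] X \cdot (\mu/\mu^\ast)$. The final
  factor gates consumption by growth activity: without it, the lag and
  stationary phases would consume several mM of nitrate, contradicting the
  flat pre-growth nitrate traces of batch data. At the calibration point
  the factor is 1, so the condition-wise rates (0.71 / 1.09 / 6.13
  mM h$^{-1}$ OD$^{-1}$) are unchanged.

Iron content relaxes first-order (k = 0.15 h$^{-1}$) towards a
condition-dependent target (25.3 / 14.4 / 3.3 mg g$_{dw}^{-1}$ at
0/1/95% dO2) once growth starts; the magnetic response Cmag is a monotone
piecewise-linear map of iron calibrated to the condition end points
(3.3 → 0.10, 14.4 → 0.74, 25.3 → 0.99), because both quantities are
reported but no transfer law is.

## Oxygen balance and kLa

$$ dC/dt = k_La \cdot (C^\ast_{gas} - C) - q_{O_2} X \frac{C}{K_{O_2}+C},
\qquad k_La = a\,(N/100)^{\alpha} Q^{\beta} + k_s\,(N/100) $$

with $N$ in rpm and $Q$ in SLPM, and $C^\ast_{gas}$ set by the sparged gas
(100% for air, 0 for N2). No transfer correlation is published for the
vessel, and the specific uptake $q_{O_2}$ has no printed value, so both
are design parameters chosen — before any acceptance measurement — to
satisfy three physical requirements (asserted in
`scripts/calibration.R`):

1. at full actuation the vessel holds 95% dO2 against the uptake of the
   maximal oxic culture (OD 0.76);
2. at minimum actuation (100 rpm, unsparged surface aeration) the oxygen
   supply at 1% dO2 is *below* the inoculum's uptake, so the microoxic
   set point is controllable from both sides from inoculation onwards;
3. one airflow quantum (0.1 SLPM) moves the supply smoothly near the
   cascade handover — the quadratic airflow exponent ($\beta = 2$)
   concentrates actuation resolution at low airflow, where the microoxic
   regime operates, at the cost of coarser steps near full flow where the
   relative demand is large anyway.

Defaults: $a = 0.8$, $\alpha = 1.4$, $\beta = 2$, $k_s = 0.3$ h$^{-1}$,
$q_{O_2} = 600$ % h$^{-1}$ OD$^{-1}$.

## Lag phases and initial conditions

The inoculum is OD 0.077 (an OD 0.8 seed culture, 300 mL into 2.8 L) with
10 mg g$^{-1}$ cellular iron (microoxically grown seed). Lag phases are
not printed anywhere; they are read qualitatively from batch growth
curves: 8 h (microoxic), 4 h (oxic). For the anoxic mode the package uses
15 h rather than a shorter value so that nitrate depletion — the anoxic
growth-limiting event, analytically at
$t_{dep} = \text{lag} + \ln(1 + S_0\mu/(q X_0))/\mu \approx \text{lag} +
10.2$ h — lands at ≈ 25 h, matching the reported depletion time, and so
that the 17–23 h main-growth analysis window lies entirely inside the
growth phase. Oxic runs start air-saturated ($C_0 = 100$); microoxic and
anoxic media are gassed out with N2 before inoculation ($C_0 = 0$).

# The controller

The discrete PI law runs at 1-minute intervals:
$u = \mathrm{clamp}(k_p e + k_i I, 0, 100)$ with $e$ the set-point error
in percentage points and $I$ the clamped integral. Anti-windup is by
conditional integration: the integral is frozen whenever the unsaturated
output is already pinned against the bound the error pushes towards.
Integral limits default to $\pm 100/k_i$ so the integral alone can span
the output range but no further.

The split-range cascade maps $u \le u_{split} = 50$ to the agitation ramp
(quantized down to 10 rpm steps, airflow closed) and $u > u_{split}$ to
the airflow ramp (quantized to 0.1 SLPM, agitation pinned at maximum) —
both actuators rise stepwise, monotonically and independently.

**Gain tuning.** The shipped defaults are $k_p = 0.5$, $k_i = 60$
h$^{-1}$. The determining constraint is the microoxic regime: at a 1% set
point the error is bounded by about one percentage point, so the integral
term must supply essentially the whole output ramp that tracks the
culture's exponentially growing oxygen demand (≈ 8 output-units/h during
main growth); gains with $k_i \lesssim 10$ h$^{-1}$ let dissolved oxygen
collapse towards zero regardless of $k_p$. Conversely a large $k_p$
couples sensor noise (0.2–0.5%) into the quantized actuators and excites
limit cycles around the airflow handover. The grid study behind the
choice is reproducible via `Rscript scripts/calibration.R --sweep`; with
the defaults, the closed-loop medians are ≈ 95.0% at the oxic and ≈ 0.93%
at the microoxic set point over a 35 h batch.

The sensor model adds Gaussian read noise (0.5% at the oxic, 0.2% at the
microoxic set point), clamps at $100(1+\text{accuracy})$ above and at the
probe's detection floor below; the floor converts the probe's 6 ppb lower
limit via 8.0 mg O2 L$^{-1}$ at air saturation and 28 °C to 0.075% air
saturation. The conversion constant is exposed in `sensor_model()`.

# Synthetic data: what it does and does not emulate

`simulate_batch()` + `observe_record()` emulate a fermenter log plus
at-line sampling (multiplicative lognormal noise, mean-unbiased, on OD,
lactate, nitrate and iron; additive noise on dO2; truncation at zero).
`sample_particles()` draws TEM-style particle-diameter samples from
Gaussians whose mean/sd follow the measured condition trajectories
(linearly interpolated between timepoints, e.g. anoxic 25.8 ± 8.9 nm at
0 h to 33.8 ± 9.4 nm at 34 h), plus a companion cell table in which
magnetosome counts scale with cell length (chains run along the cell
axis), giving ≈ 25 magnetosomes per cell and ≈ 8 per µm under anoxic
conditions. `synth_curve()` generates polydisperse-sphere SAXS curves
with honest per-point uncertainties.

Limitations to keep in mind when reading test results:

* empirical magnetosome-size distributions are visibly non-Gaussian
  (skewed violins); the Gaussian stand-in matches two moments only, so
  exceedance fractions (e.g. the share of particles above 30 nm)
  reproduce reported values to within a few percentage points, not
  exactly;
* condition-wise rates, yields and trajectory end points cannot all be
  satisfied simultaneously under a single OD-to-dry-weight constant; the
  simulator prioritizes the rate pairs $(\mu, q)$, so its plateau ODs are
  lower than reported maxima (e.g. anoxic OD 0.29 vs 0.49). For the same
  reason every dry-weight-dependent analytic takes `od_to_dw` (default
  0.4/1.4 ≈ 0.286 g L$^{-1}$ per OD, from a cited biomass/OD pair) as an
  explicit argument rather than a hidden constant;
* the real cause of microoxic dO2 fluctuations (probe noise vs cascade
  switching) is unresolved; the simulator exposes both knobs
  (`sensor_model()` noise, actuator quanta) rather than asserting one.

# Analytics conventions

* growth rate: least-squares slope of $\ln$ OD over the condition's
  main-growth window (12–18 h oxic, 10–17 h microoxic, 17–23 h anoxic;
  auto-detection of the maximal-slope 6 h window available via
  `growth_window(auto = TRUE)`). Doubling times are computed per
  replicate and then averaged, which is why a reported doubling time can
  differ from $\ln 2 /$ (mean rate);
* consumption rate: window slope of concentration over time-averaged OD —
  robust to sampling jitter and dimensionally mM h$^{-1}$ OD$^{-1}$;
* productivity: iron → magnetite via the mass ratio
  $M_{Fe_3O_4}/(3 M_{Fe}) = 1.382$ and a configurable magnetite fraction
  (default 0.99) over the whole process time;
* exceedance threshold "larger than 30 nm" is strict (> 30);
* per-µm magnetosome density is the mean of per-cell ratios, not the
  ratio of means;
* rank-sum test: midranks; exact p via the exact null distribution for
  tie-free samples, by full enumeration when ties are present and
  $n_a + n_b \le 12$; otherwise the tie-corrected, continuity-corrected
  normal approximation. Two-sided p doubles the smaller tail (capped at
  1). Exact and normal p agree within 10% relative at moderate
  significance levels; at $p < 10^{-2}$ the normal tail deviates
  relatively, as expected for tail approximations.

# SAXS conventions and numerics

$q$ is always in Å$^{-1}$; reported lengths in nm. The sphere form factor
uses a series expansion below $qR = 10^{-2}$ to avoid cancellation; its
zeros are at the roots of $\tan x = x$. Polydispersity is a Gaussian
number distribution over the diameter, integrated on 101 nodes truncated
at ±4 sd with non-positive radii excluded and weights renormalized
(truncating more than 10% of the mass warns); each radius contributes its
volume-squared weight $R^6$. At sd = 0 the model reduces exactly to the
monodisperse curve. Fitting is Levenberg–Marquardt on the intensities,
weighted by reported uncertainties, with the scale parameter fit on a log
scale; starting diameters come from the first-minimum relation
$R = 4.4934/q_{min}$.

The first minimum is located on the Porod-weighted curve $q^4 I(q)$ —
after flattening the power-law decay, even a polydispersity-smeared
minimum is a genuine local minimum — with a light running-mean smooth
against noise.

Guinier analysis fits $\ln I$ vs $q^2$ and flags validity at
$q_{max} R_g \le 1.3$ (the customary bound for globular scatterers). On ideal sphere data truncated exactly at the bound
the recovered radius is biased by ≈ +1.9% (the next-order term of the
expansion), which is why round-trip tests sample to $q_{max} R_g = 1.2$.
The membrane estimate treats the empty-vesicle envelope as small
spherical subunits: $R_{mem} = \sqrt{5/3} R_g$; with $R_g = 1.3$ nm this
gives 1.7 nm, subtracted on both sides of the fitted overall diameter for
comparison with TEM (39 → 35.6 nm anoxic, 34 → 30.6 nm microoxic).

For flake-like scatterers the thickness comes from the cross-section plot
$\ln(I q^2)$ vs $q^2$ ($T = \sqrt{12} R_{g,t}$, window 0.04–0.10
Å$^{-1}$). The radial size uses the standard low-q Guinier radius with
the flat-particle relation $R_g^2 = R^2/2 + T^2/12$; the rod-type
modified Guinier ($I\,q$), sometimes quoted for this purpose, does not
linearize for discs and is not used. The flake discriminant requires both
a nearly linear cross-section plot ($R^2 \ge 0.9$; globular scatterers
curve strongly there) and $T < \tfrac{2}{3}\,2R$.

The chain arrangement of magnetosomes is approximated by the dilute
sphere limit for analysis; `pearl_chain_intensity()` provides the
optional linear-chain structure factor (N touching pearls, center spacing
one diameter), which boosts forward scattering by up to N but leaves the
size-determining first minimum essentially unchanged — the rationale for
the dilute default.

# Reproducibility and problem sizes

A single master seed fans out to per-module child seeds
(`child_seed()`), so simulation, observation noise and particle sampling
can be re-run independently; identical seeds give bit-identical records.
The packaged studies use 35 h batches at 1-minute control intervals
(2101 samples), triplicate synthetic TEM datasets of ~1000 particles per
replicate with 100 cells each, and SAXS grids of ~200 points — sizes
chosen to match the scale of the emulated protocols while keeping a full
run of the suite in the order of a minute.

Integration uses an adaptive stiff-capable solver (lsoda) per
zero-order-hold interval at rtol 1e-9 / atol 1e-11, with non-negativity
projection of concentrations and clamping of dO2 to [0, 100] at sample
boundaries. The anoxic closed form for the nitrate-depletion time
(exponential growth, growth-coupled consumption) agrees with the solver
to well within 1% with $K_{NO_3} = 0.02$ mM; larger Monod constants
visibly stretch the depletion tail.
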