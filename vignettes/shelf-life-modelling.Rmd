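---
title: "Shelf-life modelling of hygroscopic food powders with hygrostab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shelf-life modelling of hygroscopic food powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hygrostab)
```

## The problem

A dry, amorphous food powder — instant coffee is the motivating case — is
hygroscopic: left in a humid environment it equilibrates toward the ambient
relative humidity, and the absorbed water plasticizes the amorphous solids.
Two thresholds govern what happens next. The *monolayer moisture* `m0` is
the classical stability optimum of sorption theory: below it water is
tightly bound, above it mobile water becomes available for deteriorative
chemistry. The *glass transition* `T_g` drops steeply as water content
rises; once the storage temperature exceeds `T_g`, the powder passes from a
glassy to a rubbery state, viscosity collapses, particles form liquid
bridges (caking), optical properties change, and hydrolytic reactions
acidify the resulting brew. `hygrostab` packages the standard analysis
chain that turns storage-study measurements into these thresholds and into
time-to-failure predictions.

## Models

### Sorption isotherm (GAB)

Equilibrium dry-basis moisture versus water activity is modelled with the
three-parameter Guggenheim–Anderson–de Boer equation

$$M(a_w) = \frac{m_0\,b\,C\,a_w}{(1-b a_w)(1-b a_w + C b a_w)},$$

with `m0` the monolayer moisture (g water / g dry solids), `C` an energy
constant and `b` a correction factor. All model-facing moisture is dry
basis; wet-basis percentages (the gravimetric method of moisture
determination reports `(w_i − w_f)/w_i · 100`) are converted at ingestion
via `convert_basis()`, because mixing the two bases silently is a classic
source of error in this literature. The monolayer water activity is the
root of `M(a_w) = m0`, found by bracketed root-finding on (0, 0.95]; for
the printed parameter set (m0 = 0.06, C = 1.10, b = 0.99) this gives
`a_w0` = `r round(monolayer_activity(gab_params(0.06, 1.10, 0.99)), 3)`.
Published readouts of such studies often differ slightly from what the
rounded printed parameters imply, because the original unrounded fits are
unavailable; the package always reports values computed from the supplied
parameters.

Fitting (`fit_gab`) is nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) with starts m0 = moisture at the grid midpoint, C = 1,
b = 0.9, deterministic restarts, and bounds m0 ∈ (0, 1], C ∈ (0, 1e4],
b ∈ (0, 0.9999]: the model is ill-conditioned as `b → 1` (a pole enters the
working range), so the upper bound on b matters more than the others. At
least 4 points are required for 3 free parameters.

### Glass transition (Gordon–Taylor)

$$T_g = \frac{k\,T_{gi} + \varepsilon W T_{gw}}{k + \varepsilon W},$$

with `W` the water mass fraction of the *total* mass, `k = 1 − W` the
solids fraction, `T_gi` the anhydrous-solids transition, `T_gw = −135` °C
for water (fixed, overridable), and one interaction parameter ε. Only
(`T_gi`, ε) are fitted. Since the isotherm yields dry-basis moisture, the
composition is converted as `W = M_db / (1 + M_db)` before evaluating the
mixing rule.

### Modified state diagram

Chaining the two fitted curves gives `T_g(a_w)`: the isotherm supplies the
moisture at a given water activity, the Gordon–Taylor rule the transition
temperature at that composition. The *critical water activity* at a storage
temperature `T` is the root of `T_g(a_w) = T` (monotone, bracketed on
[0, 0.95]); the corresponding isotherm moisture is the *critical
moisture*. Conditions are classified by `ΔT = T − T_g`: glassy for
`ΔT < 0`, *transition* for the closed band `0 ≤ ΔT ≤ 5` °C — a small
temperature excess is not sufficient for a complete glass-to-rubber
transition — and rubbery beyond. The band width is a parameter
(`transition_band`, default 5 °C). Storage at an environmental relative
humidity ERH is mapped to `a_w = ERH/100`, the standard equilibrium
assumption for salt-solution-conditioned chambers.

### Storage kinetics and failure clocks

Moisture uptake (days) and dissolution absorbance at 420 nm (seconds)
follow the empirical asymptotic first-order law
`Y(t) = Y∞ − (Y∞ − Y0)e^{−kt}`; brew pH follows the pseudo-first-order
decay `pH(t) = pH0·e^{−kt}`. Both are fitted by least squares on the
original response scale (no log-linearization, so additive measurement
noise stays additive). Starting values are taken from the data (endpoints;
rate from the half-range crossing time, or a log-linear regression for the
pH decay), which is robust for rising *and* falling series — a powder
drying toward a low-humidity environment has `Y∞ < Y0` and is handled
identically. Times-to-threshold are closed-form inversions; a level outside
the open interval between `Y0` and `Y∞` is "never reached" and reported as
such rather than extrapolated.

One unit subtlety: tabulated pH-decay rates in this literature are
typically printed as dimensionless numbers of order 0.4–2 that are only
physically consistent with rates of order 10⁻⁴ day⁻¹ (a brew pH drifts by
~0.1 over half a year). The package stores and computes with raw day⁻¹
values everywhere; the study-config defaults therefore use the tabulated
values × 10⁻⁴, and the CSV export prints both `k_per_day` and `k_x1e4` so
the display convention is explicit and never silently applied to the math.

### Freshness index

Powder photographs are reduced to a binary mask: a pixel is "fresh" when
its R, G and B values all lie inclusively within calibrated ranges
(defaults R 70–190, G 55–170, B 10–90 — the ranges established for fresh
instant coffee). Inclusive bounds and the three-channel conjunction are the
most literal reading of "within the selected ranges"; both choices are
explicit in the code. The freshness index is 100 × (in-range count) /
(in-range count of the time-zero image); values above 100 are reported, not
clamped. `calibrate_ranges()` replaces the manual screening step of the
original method with symmetric per-channel quantile intervals (coverage
0.99 by default, rounded outward), which is reproducible and degrades
gracefully to min/max at coverage 1. No illumination correction or colour
management is attempted; L\*a\*b\* colour data are treated as tabular
inputs, never derived from photographs.

### Group statistics

Between-condition comparisons use one-way ANOVA; within-condition temporal
comparisons use one-way repeated-measures ANOVA with the replicate as the
subject (which replicate unit plays "subject" is a design choice the
synthetic generator parameterizes explicitly). No sphericity correction is
applied — the convention of the emulated analyses — and the function warns
about the assumption. Post hoc testing is Tukey HSD on the studentized
range with Tukey–Kramer scaling for unequal group sizes; critical values
come from R's numerically computed studentized-range distribution. Letter
displays use insert-and-absorb with groups ordered by descending mean, and
the result is verified on every call against the pairwise relation (a
violation is an error, not a silent mislabel).

## The synthetic-data generator

`study_config()` encodes the emulated design: 11/32/65 % ERH at 20 °C,
three replicates, isotherm over a_w 0–0.9 in 0.1 steps, T_g points at the
seven salt humidities (1, 11, 23, 32, 43, 54, 65 %), and per-condition
kinetic parameters set to the published fitted rows of the motivating
study. Noise is additive Gaussian per response with SDs at the replicate
scatter reported there (0.15 % moisture, 0.003 absorbance, 0.03 pH,
0.002 g/g isotherm moisture, 1 °C on T_g) and no autocorrelation. Sampling
grids use dense regular spacing over the published spans (0–19 d moisture,
3–120 s dissolution, 0–180 d pH at 15-d intervals), since exact sampling
dates are not published.

Powder images are generated by exact pixel-count replacement: image *t* has
exactly `round(fraction_t × n)` pixels drawn uniformly inside the fresh
ranges and the rest drawn brighter than every range maximum, so the
freshness index is analytically known (100 × fraction). The default 65 %
ERH schedule drops to 31 % within the first simulated week, the trajectory
reported for coffee stored at that humidity. A secondary mode
(`freshness_fraction_from_moisture`) couples the fraction to simulated
moisture through a logistic link with its midpoint near the
monolayer-equivalent moisture, for more realistic coupled simulations.

What passing tests on these data do and do not show: they demonstrate that
the estimators recover the generating parameters under the study's noise
structure and that the pipeline's logic (state classification, failure
clocks, letters) is correct. They do not validate the models against real
powders — real isotherms have hysteresis, real images have illumination
gradients and texture, real residuals are autocorrelated. The generator is
a correctness harness, not a physics simulator.

## Numerical choices

- Root-finding is Brent's bracketed method (`uniroot`, tolerance 1e-9 on a
  unit-scale bracket), deterministic and derivative-free; all bracketed
  quantities (`monolayer_activity`, `invert_gab`, `critical_aw`) are
  monotone on their brackets.
- Nonlinear fits use Levenberg–Marquardt with tight convergence tolerances
  and a short, fixed list of restart points; noiseless round-trips recover
  parameters to better than 1e-3 relative, which the test suite asserts for
  every published parameter row.
- The DVS equilibrium window uses inclusive endpoints with linear
  interpolation at the right edge, since instrument sampling (every
  20 min) rarely aligns with an 8.5 h window.
- Degenerate inputs fail loudly: all-zero isotherms, flat kinetic series,
  unbalanced repeated-measures tables and grayscale images are errors, not
  NA propagation. An ANOVA with zero between-group variation (up to
  floating-point rounding) reports F = 0, p = 1 rather than 0/0.
- Pipeline problem sizes: the shipped configuration fits 9 isotherm points,
  7 T_g points, and 3 replicates × 3 conditions per response (20 moisture,
  7 absorbance and 13 pH time points), with 100×100-pixel images — the
  scale of the emulated study itself.

## Limitations

- Single storage temperature: no Arrhenius/WLF temperature dependence.
- Adsorption branch only: no desorption/hysteresis, no BET comparison.
- The repeated-measures ANOVA assumes sphericity and complete balanced
  tables.
- The freshness index is camera- and lighting-specific; calibrated ranges
  do not transfer between imaging setups.
- No single "shelf life = X days" endpoint is declared: the report presents
  the three failure clocks (monolayer crossing, pH threshold, freshness
  collapse) side by side and leaves the acceptability criterion to the
  user.
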