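---
title: "Plateau species distribution models with physiological priors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plateau species distribution models with physiological priors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateauSDM)
```

## The model

`plateauSDM` models presence/pseudo-absence data with a *plateau*
(trapezoidal envelope) response per predictor. For predictor $j$ with
normalized value $x_j$, the contribution to the linear predictor is

$$f_j(x_j) = -b_{1j}\,\max(0,\, c_{1j} - x_j) \;-\; b_{2j}\,\max(0,\, x_j - c_{2j}),$$

zero on the plateau $[c_{1j}, c_{2j}]$ and linearly declining outside it with
slopes $b_{1j}, b_{2j} \ge 0$ (logit units per normalized unit). The
presence probability of a cell is

$$p = \mathrm{logit}^{-1}\Big(\beta_0 + \sum_j f_j(x_j)\Big),$$

so a single global intercept $\beta_0$ acts as the *apex*: the response
attains its maximum $\mathrm{logit}^{-1}(\beta_0)$ exactly when every
predictor sits on its plateau. We use one global apex rather than
per-predictor apexes because per-predictor maxima are not jointly
identifiable with an intercept; the geometry (two intersecting linear
functions capped by an apex) is unchanged. The link is logistic throughout;
the qualitative contrasts the package targets are link-invariant, so no
probit variant is provided.

Predictors are min–max normalized to $[0,1]$ over the cells of the
*largest* calibration buffer, and the same stored affine transform maps
physical constants (26 °C, 200 m, …) and future climate layers onto the
model scale. Future values may exceed 1 and are deliberately not clipped:
extrapolation beyond the calibrated range is exactly the regime the
comparison is about.

## Priors

*Naive* mode uses vague priors on the normalized scale: plateau edges are
the order statistics of two independent Uniform(0, 1) draws (i.e. jointly
uniform on $\{c_1 \le c_2\}$), slopes are half-Normal(sd = 10), and the
intercept is Normal(0, sd = 5).

*Informed* mode modifies only the predictors named in the physiological
constraint table (shipped default: annual-mean temperature and depth, the
sea-cucumber analogue):

- temperature: both edges are restricted to the normalized image of the
  optimal range 15–18 °C (uniform within it, ordered);
- depth: the plateau is pinned at the 0–40 m optimum;
- the descending slope on the limit side is not a free parameter but a
  deterministic link,
  $$b_2 = \frac{\beta_0 - L}{x_{\text{limit}} - c_2}, \qquad L = \mathrm{logit}(0.01),$$
  so that the response at the hard tolerance limit (26 °C, 200 m) equals the
  configurable "effectively absent" floor of 0.01 whenever the other
  predictors are on-plateau. This is the most direct reading of *calculating*
  the slope from the limit and the apex; it also couples $\beta_0$ to the
  slopes, implicitly truncating $\beta_0 > L$.

Salinity, current velocity, temperature range and distance to shore keep
the vague plateau priors in *both* modes, so the naive/informed contrast is
carried solely by the two constrained predictors.

## Posterior computation

The posterior is sampled with an adaptive component-wise random-walk
Metropolis sampler written in C++ (Rcpp). Step sizes adapt toward a 0.44
acceptance rate in batches of 50 iterations during warm-up only, and are
frozen afterwards, so the retained chain is a valid Markov chain. The
default schedule follows the study design: 2 chains started from the same
central initial values, 5000 iterations each with 4000 warm-up, leaving
2 × 1000 retained draws. An optional `init_jitter` perturbs the shared
inits, which sharpens split-R-hat as a dispersion diagnostic; the default
honours the same-initial-values convention. Fits are bitwise reproducible
from the seed because the sampler draws through R's RNG.

Diagnostics are split-R-hat and an initial-positive-sequence effective
sample size per free parameter, computed from the standard formulas; R-hat
above 1.1 warns rather than fails. Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ inside the likelihood so extreme draws keep a
finite log-likelihood.

## The synthetic landscape

The generator emulates the statistical structure the analysis assumes, on a
regular equirectangular grid (great-circle distances by haversine,
$R = 6371$ km):

- a meandering north–south coastline (land west, sea east), roughness set
  by `coast_complexity` (0 = straight);
- annual-mean benthic temperature decreasing linearly from 28 °C to 2 °C
  with latitude plus smooth noise — the physiological constants 15–18 °C
  and 26 °C fall inside the gradient;
- distance to shore as great-circle distance to the nearest land cell, and
  depth increasing hyperbolically with it
  ($z = z_{\max}\, d/(d + d_{1/2})$, $d_{1/2} = 2000$ km by default). The
  half-saturation default is deliberately large so that nearshore cells are
  a few tens of metres deep, as on the wide Bohai/Yellow-Sea-type shelf;
  with a steep profile every cell at ~55 km grid resolution would already
  be hundreds of metres deep and a species with a 40 m optimum would have
  no habitat at all;
- temperature range, salinity (29–35) and current velocity as
  Gaussian-kernel-smoothed random fields (white noise smoothed and rescaled;
  no geostatistics dependency);
- a warmed future stack: smooth warming fields with exact sea-mean
  `delta_temp` (default +2 °C) added to the temperature layers; depth,
  distance to shore, salinity and currents are copied unchanged.

The default ground truth (`default_true_response()`) places the temperature
plateau on 15–18 °C with its slope reaching the absence floor at 26 °C, the
depth plateau at 0–40 m with the floor at 200 m, and zero slopes elsewhere,
with apex $\beta_0 = 2.5$ (maximum suitability ≈ 0.92). Presences are
sampled without replacement with probability proportional to suitability
times an optional smoothed bias field raised to `bias_strength`
(0 = unbiased survey effort).

**Warm-truncated sampling.** The truncation experiments sample presences
only from cells at or below 24 °C — 2 °C short of the hard limit —
emulating an occurrence compilation whose annual-mean temperatures approach
but never reach the limit. The cutoff matters: if sampling is truncated far
below the limit (say 20 °C), the naive model learns a spurious warm edge at
the truncation boundary, and future warming then clips its range *more*
than the informed model's, reversing the range-contraction contrast. With
the cutoff near the limit the naive posterior keeps the warm edge loose and
all three qualitative directions (higher informed cross-buffer Jaccard,
larger naive expansion, smaller naive contraction) reproduce.

What the generator does *not* emulate: ocean dynamics (currents advect
nothing), spatially autocorrelated sampling error in the predictors,
coastline fractality below the grid scale, and real bathymetric complexity.
Passing tests on this landscape show that the estimation and comparison
machinery behaves as designed under known truth — not that any real
species' range obeys a trapezoid.

## Evaluation and comparison choices

- **Spatial block CV**: the records' bounding box is split into a 10 × 10
  block grid; non-empty blocks are allocated to 5 folds by a randomized
  greedy rule that balances per-fold presence counts to within one block.
- **Boyce index**: 100 windows of width one tenth of the background
  suitability range; windows with zero expected share are dropped; Spearman
  correlation of P/E against the window center. The background is *all*
  calibration-area cells, not the pseudo-absence sample — the index is
  presence-only and the full background removes pseudo-absence noise. Note
  the null distribution of this estimator is wide (overlapping windows
  correlate neighbouring P/E values): single null draws of |Boyce| ≈ 0.5
  are unremarkable, which is why the package's tests assert null behaviour
  on the ensemble mean.
- **Permutation importance**: 1 − Pearson correlation between posterior-mean
  predictions on intact and column-permuted data, averaged over 5
  permutations, clipped to [0, 1].
- **Response curves** vary one predictor with the others held at reference
  medians. For the thermal-limit contrast the reference cells are the
  training presences (favorable conditions): over the whole calibration
  area the median cell is deep enough that the depth penalty floors both
  curves near zero and would mask the temperature contrast being examined.
- **Binarization** at the 10% omission threshold: the 10th percentile
  (linear interpolation) of the model's own training-presence
  suitabilities.
- **Jaccard stability** is computed over the full largest-buffer domain for
  every replicate pair across calibration extents (25 × 25 = 625 pairs per
  extent pair and model type under study defaults).
- **Range change** counts cells (no area weighting) under unlimited
  dispersal; a `cos-lat` weighting option exists.
- **Paired contrasts** use the Wilcoxon signed-rank test (the V statistic
  identifies the signed-rank, not rank-sum, test), exact for ≤ 25 untied
  pairs.
- **Pseudo-absences** are drawn uniformly from calibration-area cells with
  complete predictor data, excluding presence cells, once per replicate
  (not redrawn inside CV folds).

## Problem sizes

The shipped tests and experiments run at deliberately reduced sizes chosen
once: landscapes of 30 × 40 to 40 × 50 cells, 40–100 presences, reduced
Metropolis schedules (300–2500 iterations) for the replicated experiment
grids, and the full 5000/4000 schedule where the draw-count contract itself
is under test. Parameter recovery uses 20 replicates of 600 labelled points
from a three-predictor teacher with signal on every predictor; with six
predictors and weak slopes some edges are only weakly identified, which is
a property of the model, not the sampler.

## Known limitations

- The sampler is component-wise; for strongly correlated posteriors
  (e.g. apex vs. linked slopes) mixing is adequate but not optimal, and
  split-R-hat occasionally sits slightly above 1.1 at the default schedule
  with shared inits. Use `init_jitter` and longer chains for publication-
  grade inference.
- Min–max normalization ties the model scale to the observed extremes of
  the largest buffer; a different buffer choice changes the scale (by
  design, this is the effect under study).
- No spatial random effect: residual spatial autocorrelation inflates
  apparent precision, as in the modelled study design.
- `boyce_index()` requires at least three usable windows and errors
  otherwise (degenerate, near-constant suitability surfaces).
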