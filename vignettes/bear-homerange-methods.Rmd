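---
title: "Methods: home-range estimation and sex-versus-size inference in bearhr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home-range estimation and sex-versus-size inference in bearhr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearhr)
```

## The scientific problem

Adult male brown bears are strongly dimorphic — typically 30% or more heavier
than females — and both sex and body size are candidate drivers of how much
space an individual uses. `bearhr` implements a complete analysis chain for
separating those drivers in a single GPS-collared population: quality control
of raw fixes, home-range estimation by two complementary estimators, a
usability screen for the kernel estimator, morphometric dimension reduction,
and a log-scale information-theoretic comparison of candidate models of home
range size. A synthetic-population generator with known ground truth makes the
whole chain testable without field data.

## The movement model behind the generator

The generator is not meant to be behaviourally realistic; it is built so that
the quantity every downstream estimator targets has a closed form. Each bear
moves as a discrete-time Ornstein-Uhlenbeck (OU) process per axis:

$$x_{t+\Delta} = \mu + e^{-\beta\Delta}(x_t - \mu) +
  \varepsilon,\qquad \varepsilon \sim N\!\left(0,\ \sigma^2(1-e^{-2\beta\Delta})\right),$$

with the first position drawn from the stationary law $N(\mu, \sigma^2)$ —
the exact transition, not an Euler step, so tracks are stationary from the
first fix. The stationary distribution is an isotropic bivariate normal, whose
95% probability region has area

$$A_{95} = \pi\,\sigma^2\, \chi^2_{0.95,2} \approx 5.991\,\pi\,\sigma^2 .$$

This identity is used in both directions: `population_spec()` draws each
bear's true area on the log scale,
$\log A = \log A_F + \beta_{\mathrm{sex}}\,I(\text{male}) + N(0, \tau^2)$,
and converts it to the $\sigma$ that the OU track is simulated with
(`sigma_from_area_km2()`); the tests convert back to check estimators against
truth.

Generator defaults are the study conditions: 46 males and 23 females, a 1-h
fix schedule, a male-female contrast of $\beta_{\mathrm{sex}} = 0.65$ natural-log
units (area ratio $e^{0.65} = 1.92$), a typical female range of 40 km²
(hence a typical male range of about 76.6 km²), between-bear SD
$\tau = 0.7$ on the log scale (right-skewed areas spanning roughly 5–200 km²),
and five bears with missing mass. Default track length is 2000 fixes (about
83 days of hourly fixes, i.e. an active season); the mean-reversion rate
defaults to $\beta = 0.25\,\mathrm{h^{-1}}$, a ~4-h range-crossing time that
keeps successive hourly fixes realistically autocorrelated. Morphometric
traits are drawn per sex from a multivariate normal whose correlation matrix
reproduces the published correlations among mass, body length, chest
circumference and shoulder height (e.g. mass-chest 0.93), extended with
plausible values for the remaining traits; mass is generated independently of
range area given sex, so any apparent mass effect downstream is either the
sex contrast in disguise or noise.

Defects are injected on disjoint fix sets with ground-truth flags: missing
coordinates, demoted fix types (`2D-low`/`0D`), HDOP drawn above 5 with
300 m positional noise, 20 km teleport displacements, and dropout gaps. What
the generator does *not* emulate: denning or mating excursions, terrain and
habitat effects, fix-rate dependence on canopy, or serially correlated GPS
error. Passing tests therefore demonstrate correctness of the estimators and
inference machinery under a stationary range model — not robustness to every
pathology of field telemetry.

## Quality control

`filter_fixes()` applies, in order: missing coordinates; disallowed fix
types; HDOP missing or strictly above 5; altitude present but outside the
plausible band; then three movement rules iterated to convergence — a
coordinate-jump rule (> 1 km within ≤ 5 min), a speed rule (> 10 km/h over
intervals ≥ 30 min), and a step-length rule (> 2.5 × the individual's 99th
percentile step, the multiplier configurable in [2, 3]). Distances use the
haversine formula with mean Earth radius 6,371,000 m, since QC precedes
projection. The later fix (destination) of a failing step is dropped — the
standard, deterministic telemetry convention — and within a pass a failing
step whose origin is itself being removed is skipped, because the return step
out of an outlier is an artefact of the outlier, not evidence against the
next fix. Rules iterate because removing a fix merges its neighbouring steps;
iteration guarantees idempotence, which the tests assert. Percentiles use
linear interpolation between order statistics (type-7), documented because
the 99th percentile is convention-sensitive at small n. Missing HDOP is
treated as unreliable and dropped; missing altitude alone is tolerated.

## Projection and home-range estimators

Coordinates are projected with a spherical Albers equal-area conic on the
authalic sphere (standard parallels placed 1/6 in from the data's latitude
extremes), implemented from the classical closed forms; round-trip error is
sub-metre over the study window and projected polygon areas match spherical
areas to well within 0.1%, which the tests verify against the spherical-excess
closed form.

The 95% minimum convex polygon (`mcp()`) retains the
$\lfloor 0.95\,n \rfloor$ fixes nearest the arithmetic mean centre and
returns their convex hull — the common default peeling rule. The kernel
utilisation distribution (`kud()`) evaluates an isotropic Gaussian kernel
with the reference bandwidth

$$h_{\mathrm{ref}} = \sqrt{\tfrac12\,(s_x^2 + s_y^2)}\; n^{-1/6}$$

on a 250 m grid with a 10 km buffer, normalised to unit mass over the grid.
The 95% isopleth (`ud_isopleth()`) accumulates cells by descending density
(ties broken by row-major cell index, so isopleths are bit-reproducible)
until 95% of the mass is enclosed; its area is the cell count times the cell
area, and patches are counted under 8-connectivity (4-connectivity would
split diagonally touching cells spuriously). Building the isopleth from the
cell union rather than interpolated contours trades cosmetic smoothness for
exact mass bookkeeping and reproducible areas. For a clean OU track the
KUD95 area converges on $5.991\,\pi(\sigma^2 + h^2)$ — the 95% region of the
kernel-smoothed stationary law — and the tests require agreement within 10%
at n = 2000, σ = 2000 m. Tracking days are the elapsed first-to-last time
rounded up; bears with fewer than 30 usable fixes (configurable) are excluded
with a reason.

## The usability screen

`assess_usability()` evaluates five a priori criteria per bear: (i)
sufficiency — at least 150 usable fixes spanning at least 45 days; (ii)
temporal regularity — median fix interval at most 6 h (inclusive) and no gap
longer than 10 days; (iii) bandwidth stability — $h_{\mathrm{ref}}$ within
0.5–3.0 times the median nearest-neighbour distance among fixes; (iv)
convergence — the KUD95-versus-cumulative-fix curve (chronological prefixes,
recomputing $h_{\mathrm{ref}}$ each time, 50-fix steps) must change by less
than 1% per step at its terminal segment (a trailing-k-segments mode is
available in `usability_config()`); and (v) shape — at most 10% of total UD
mass outside the 1 km-buffered convex hull of the fixes, and at most five
disjoint isopleth patches. All five are always evaluated and reported; the
overall verdict is their conjunction, and degenerate inputs (zero
nearest-neighbour distance, unevaluable curves) fail the criterion rather
than erroring. Bears failing the screen keep their MCP95 but lose KUD
summaries. Criteria are evaluated once per bear (annual/active-season
ranges); "kernel mass" in (v) is read as total UD mass rather than mass
within the isopleth — simpler and stricter.

**A known internal tension.** Criterion (iii) cannot coexist with criterion
(i) for densely sampled tracks: $h_{\mathrm{ref}}$ shrinks as $n^{-1/6}$
while the median nearest-neighbour distance of a two-dimensional point cloud
shrinks as $n^{-1/2}$, so their ratio grows as $\approx 0.58\,n^{1/3}$
regardless of range size — about 3.05 at exactly 150 fixes and about 7.2 at
2000 hourly fixes. In other words, any bear sampled well enough to satisfy
(i) sits at or above the upper bound of (iii). The package implements the
criterion literally and exposes the band in `usability_config()`; users
screening dense hourly data should either widen `href_nn_ratio` or treat
(iii) as a flag for *undersmoothing relative to granularity* only (the lower
bound). The acceptance checks record this honestly: a clean reference bear
passes four of the five criteria, failing only (iii).

## The inference layer

The response is log MCP95 area (natural log throughout the candidate set;
log10 is supported and the base is recorded in every fit so back-transformed
ratios stay honest). Sex is coded with females as the reference level. The
default candidate set mirrors the published one — Sex, Sex + log(Mass),
Sex × log(Mass), log(Mass), Null — and all candidates are refit on the
intersection of their complete cases so AICc values are comparable (the
per-model analyzable n is reported). K counts the intercept, slopes, and the
residual variance, matching the published convention (K = 3 for the sex-only
model). AICc, ΔAICc, Akaike weights and evidence ratios
($w_{best}/w_i$) follow the standard formulas; model-averaged estimates use
natural averaging (weights renormalised within the subset of models
containing the term) with the usual unconditional variance
$\sum_i w_i\,(\mathrm{se}_i^2 + (\hat\beta_i - \bar\beta)^2)$. No
multiple-testing correction is applied, matching the information-theoretic
(non-NHST) stance; p-values are reported descriptively.

Distributional comparisons: the Fligner-Killeen test (via `stats::fligner.test`)
with descriptive IQRs; a permutation energy-distance test implemented from
the pairwise-distance definition with the standard $1/n^2$ within-sample
means (so the statistic is exactly zero for coincident samples), 10,000
label permutations by default and the add-one p-value
$(1 + \#\{E^* \ge E\})/(B+1)$, which bounds p below by $1/(B+1)$; and
quantile regression of log area on sex at τ = 0.25/0.50/0.75. With a single
binary predictor the check-loss minimiser is exactly the pair of group
τ-quantiles (type-1, the lower endpoint of the minimising interval when it
is an interval), so the sex contrast is the male-female difference of group
quantiles; the tests verify this against brute-force minimisation of the
pinball loss. Confidence intervals are case-resampling bootstrap percentile
intervals (B = 2000, seeded), since no interval method was prescribed.

Robustness: `influence_diagnostics()` flags observations with Cook's
distance above 4/n and refits without them, comparing the sex coefficient's
sign and CI; `robustness_refits()` fits OLS on the raw area scale with HC3
standard errors (`sandwich::vcovHC`) and a Gamma GLM with log link, returning
an agreement report rather than a hypothesis decision.

## Morphometrics

`fit_pca()` standardises complete cases (mean 0, SD 1, n−1 denominators) and
decomposes the correlation matrix; components are ordered by eigenvalue and
any component whose loading sum is negative is flipped so the general size
axis loads positively. Ties in eigenvalues are left to the decomposition's
stable ordering and documented as a non-identifiable rotation. Two trait
presets ship: the four-trait set (mass, body length, head length, tail
length) used by the published model is the default; an eight-trait set (adds
chest circumference, shoulder height and paw widths) is available, since the
source describes both. Correlation matrices use pairwise-complete Pearson
correlations; the PCA itself is complete-case, and the error message names
the traits driving missingness.

## Numerical choices and problem sizes

Key defaults: 250 m cells and a 10 km buffer (the buffer exceeds 5h for every
realistic bandwidth, so UD mass is conserved to 1e-6); grid origins snap to
cell multiples, making KUD95 areas exactly invariant to translations by a
whole number of cells; isopleth ties break by cell index; permutation and
bootstrap procedures take explicit seeds and are bit-reproducible. The test
suite exercises the full chain at 69 bears × 500 fixes over 100 seeds for
parameter recovery (a size chosen to make a hundred end-to-end replicates a
couple of minutes' work), n = 2000 tracks for the kernel oracle and the
usability screen, and 500 replicates × 199 permutations for the energy
test's type-I calibration, which lands near the nominal 5% level.

## Limitations

MCP95 on finite, autocorrelated samples is biased low relative to the true
95% region (the hull of ~500 correlated fixes does not reach the region's
boundary); the bias is shared across bears of both sexes, so the *contrast*
— the quantity of scientific interest — is recovered essentially unbiased
(mean recovered sex coefficient ≈ 0.65 across seeds), while absolute
synthetic medians sit below their generating values. The kernel estimator
inherits the usual href oversmoothing of multimodal ranges. Autocorrelation-
aware estimators (AKDE, Brownian bridges), seasonal range partitioning, and
habitat covariates are out of scope. Model selection by AICc over a
candidate set containing a sex-collinear mass term has an irreducible chance
component: even fitting the true areas directly, the sex-only model is
top-ranked in only ~75–80% of replicates, with the remainder lost to
spurious likelihood gains of the richer models — a property of the procedure,
not of the implementation, and the package reports it as measured.
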