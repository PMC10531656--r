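---
title: "Functional redundancy and diversity modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional redundancy and diversity modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoredundancy)
```

## What the package computes

`ecoredundancy` analyses presence/absence community data — the
motivating case is a national butterfly atlas on a 10-km grid — along
three linked axes:

1. **Functional entities and redundancy.** Species are described by
   four categorical traits (wing-span class, voltinism class,
   overwintering stage, diet breadth). A *functional entity* (FE) is a
   unique combination of the four trait values. For a community with
   `S` species spread over `FE` entities with `n_i` species in entity
   `i`,

   * functional redundancy `FR = sum(n_i) / FE = S / FE` — the mean
     number of species per entity present, between 1 (all entities
     singletons) and `S` (one entity);
   * functional vulnerability
     `FV = (FE - sum(min(n_i - 1, 1))) / FE` — the fraction of present
     entities carried by exactly one species, between 0 and 1.

   High FR means trait combinations are buffered by interchangeable
   species; high FV means single extinctions erase trait combinations.

2. **Trait-space richness.** Gower distance between species (with four
   categorical traits this is simply the proportion of mismatching
   traits, values on the grid 0, 0.25, ..., 1) is embedded by principal
   coordinates analysis; functional richness (FRic) of a site is the
   convex-hull volume of its species in the first `m` axes divided by
   the pool's hull volume. A fixed-margin swap null model (below)
   yields a standardized effect size (SES) of FRic.

3. **β-diversity and its drivers.** Pairwise Jaccard dissimilarity is
   computed taxonomically (species overlap) and functionally
   (trait-space hull overlap), then modelled by generalized
   dissimilarity models (GDM) with monotone I-spline transforms of
   climate and landscape predictors plus geographic distance, with the
   explained deviance partitioned into unique-environment,
   unique-geography and shared components, and site-level predictions
   summarised as an RGB ordination. Per-site metrics are related to
   predictors by penalized additive models (mgcv).

## Per-site FE convention

In the FR/FV formulas, `FE` counts the entities *present at the site*,
not in the regional pool. With the pool convention FR would no longer
be the mean number of species per occupied entity and its stated
bounds `[1, S]` would fail for any community missing a pool entity, so
the site convention is the only one consistent with the definitions
above. Empty sites propagate `NA` rather than zero: an unoccupied cell
has no community to describe.

## Hull geometry

No convex-hull engine is assumed; volumes are computed by exhaustive
facet enumeration (every hyperplane through `d` points that supports
the point set is a facet; the volume is assembled from facet areas and
centroid distances, recursing down one dimension for facet areas so
coplanar vertex sets are handled exactly). Intersection volumes come
from the combined facet half-spaces of both hulls: candidate vertices
are intersections of `d` facet planes, kept when feasible for every
half-space, and the vertex set's own hull volume is returned. This is
exact (up to floating point) in 2–6 dimensions and fast for the point
counts that occur here (≤ 57 species). Both primitives are validated
against 10^6-point Monte-Carlo rejection estimates in the test suite.

Numerical choices: duplicate coordinates (species in the same entity
share a PCoA position) are deduplicated before hull construction —
duplicates cannot change a hull volume but would break facet
enumeration. Point sets with affine rank below the ambient dimension
(e.g. a site whose species are collinear in 2 axes) are *degenerate*:
FRic and functional dissimilarity report `NA` for such sites rather
than 0, mirroring the behaviour of refusing hulls below full
dimension. Facet and feasibility tolerances are relative (1e-8 and
1e-7 of the coordinate scale).

FRic uses `m_axes = 3` by default: a fixed-axis contract is
reproducible, whereas tools that shrink the axis count for
species-poor sites make FRic values incomparable across sites.
Functional β-diversity uses `m_axes = 2` by default — pairwise
intersection volumes are computed for every site pair, and the planar
case keeps an all-pairs run cheap; 3–4 axes are supported and exact
but markedly slower at atlas scale. The ≥ 5-species filter is applied
before hull construction, and excluded sites are reported with
reasons in an `excluded` attribute.

## The swap null and SES

The null model shuffles presences while preserving every row sum
(site richness) and column sum (species prevalence) exactly, by 2×2
checkerboard swaps. Each of the `n` randomizations is an independent
chain restarted from the observed matrix with a fresh derived seed and
run for `10 × fill` accepted swaps (`fill` = number of presences),
with a trial cap so matrices admitting few or no swaps (forced
margins) terminate. Independent chains make null draws exchangeable,
which keeps the SES denominator well behaved; this deliberately
differs from sequential-swap samplers whose consecutive draws are
autocorrelated. SES is `(observed − null mean) / null SD`; sites whose
null SD is zero (e.g. any metric that is a function of the margins,
such as richness itself) return `NA` with a warning rather than a
spurious number.

One property of the SES worth knowing: across sites of one dataset the
SES values share a single null ensemble, so their mean carries a
global offset that does not shrink as sites are added. On unstructured
data the per-dataset mean SES is unbiased but has an across-dataset SD
near 0.07; the package's acceptance check of "mean SES ≈ 0" therefore
averages the statistic over three replicate datasets rather than
trusting one draw.

## GDM: basis, likelihood, optimisation

Each predictor enters through three monotone I-spline basis functions
of order 2 (piecewise quadratic), with knots at the minimum, median
and maximum of the predictor's values; each basis function rises from
0 at the minimum to 1 at the maximum. The basis is constructed from
the cumulative-sum identity with order-3 B-splines, so linear
transforms are exactly representable with non-negative coefficients.
For environmental predictors the model term is `|I(x_i) − I(x_j)|`;
for geography it is the spline of the pair distance itself. The model
is `d = 1 − exp(−η)` with `η` an intercept plus non-negative
coefficient combination of the terms — predicted dissimilarity is
therefore monotone in every predictor separation by construction.

Fitting minimises the binomial-type deviance
`D = −2 Σ [d log(d/μ) + (1−d) log((1−d)/(1−μ))]` (0·log 0 = 0, μ
clamped to [1e-6, 1−1e-6]) by iteratively reweighted least squares
with a non-negativity constraint solved by a Lawson–Hanson active-set
NNLS on the working response, at most 100 iterations, relative
deviance change < 1e-8. A perfect fit drives the deviance itself to
zero, where a relative criterion cannot fire; an absolute floor
(deviance < 1e-9 per pair) therefore also counts as convergence.
Deviance explained is `100 (1 − D_model / D_null)` with the
intercept-only null fitted by the same routine; when all observed
dissimilarities are zero the fit is defined as all-zero with 0%
explained. Predictor importance is the sum of the three coefficients
per predictor; deviance partitioning fits full, environment-only and
geography-only models on identical pairs and reports
`unique_env = full − geo_only`, `unique_geo = full − env_only`,
`shared = env_only + geo_only − full`, which sum to the full model's
deviance explained by construction.

Predictions clamp out-of-range predictor values to the training range
(with a warning) since I-splines are undefined beyond their knots. The
RGB ordination applies uncorrected PCoA to the predicted
dissimilarity matrix and min–max scales the first three axes to
[0, 1]; constant or missing axes map to the neutral 0.5.

## Additive models

"Thin-plate regression splines with k = 3" is honoured as a contract:
each predictor gets a penalized thin-plate smooth with basis size 3,
spatial autocorrelation is absorbed by a bivariate thin-plate smooth
of the site coordinates, smoothing parameters are selected by GCV
(REML available), and the report is percent deviance explained plus
partial-effect curves. mgcv provides the backend — the recovery
properties (exact fit of noiseless linear responses, shape recovery of
saturating responses, near-zero explained deviance for spatially
unstructured noise) are asserted in the test suite rather than assumed.
P-values of smooth terms are deliberately not reported: they are
approximation-dependent and none of the package's claims rest on them.

## The synthetic world

The atlas itself is an observational dataset with no generating model,
so the generator states one explicitly and documents it as a stand-in:

* **Landscape.** Sites are a rectangular grid (default 20 × 10 = 200
  cells); temperature declines linearly from the warm southern edge
  across rows, spanning 5–11 °C (the British mean-annual-temperature
  range) with 0.5 °C Gaussian noise. Land cover per site is a
  six-class Dirichlet draw (forest, cropland, grassland, other, water,
  settlement) whose class weights tilt smoothly along the gradient —
  cropland rises towards the warm end, forest and sparse cover towards
  the cold end — so cover predictors are deliberately confounded with
  temperature, exercising VIF screening the way the real landscape
  does. Grassland is generated even though the atlas analysis dropped
  it after VIF screening: exclusion is the screening stage's job, not
  the generator's. Population is log-normal (median 10^4); elevation
  mean rises towards the cold end with noise; a single temperature
  variable is generated (the atlas used two five-year windows, but
  which entered the models is unstated, so the generator does not
  pretend to know).
* **Species pool.** 57 species (the atlas pool size). Four categorical
  traits are sampled independently per species with probabilities
  shaped like a north-temperate fauna (mostly univoltine, overwintering
  as larva or pupa, oligophagous, mid-sized). Each species has a
  Gaussian thermal niche: optimum placed in the landscape's temperature
  range with a warm-skewed Beta(2, 1) position — a mildly warm-adapted
  pool, which is what produces the south-to-north richness decline —
  and breadth uniform on 1.5–4 °C; baseline occupancy at the optimum
  is 0.8.
* **Communities.** Occurrence is an independent Bernoulli draw per
  site × species with probability
  `baseline × exp(−(T_site − opt)² / (2 breadth²))`.
* **Presets.** `"default"` is the above; `"single-driver-temperature"`
  shuffles temperature across sites (destroying its spatial structure),
  flattens the cover tilt and narrows niches to 0.8–1.6 °C so that
  temperature is the *only* turnover driver and geographic distance
  carries no signal; `"no-structure"` replaces the niche model with iid
  Bernoulli(0.3) occupancy.

What the generator does **not** emulate: real geography and
coastlines, recording effort and detection bias, species' dispersal
limitation and range cohesion, trait–niche correlations, and spatial
autocorrelation of occupancy beyond what the temperature gradient
induces. A green test on this world therefore establishes that the
*algorithms* behave as intended (formulas exact, nulls
margin-preserving, models recover known drivers), not that the
package would reproduce any atlas-scale estimate; atlas-scale
headline numbers depend on the real data and serve as structure
templates only.

For the additive-model shape-recovery check, the saturating test
response is `s(T) = 1 − exp(−(T − 5)/2)` on 5–11 °C, which plateaus
near 9 °C — the kind of richness–temperature saturation these models
are meant to detect in British-range temperatures. A harder
saturation makes Spearman shape recovery degenerate for a reason worth
recording: on a long plateau the true curve is effectively constant,
so rank correlation is decided by noise-order among ties and stops
measuring fit quality.

## Known limitations

* Hull intersection volumes above 4 axes are computed by the same
  exact enumeration but become expensive at all-pairs scale; the
  functional β default stays at 2 axes and the pair count is capped
  (seeded subsampling) for very large grids.
* The swap sampler's burn-in (10 × fill accepted swaps) follows common
  practice; sequential-swap tools differ in their variant and burn-in
  choices, so SES values are comparable within this package, not
  across tools.
* GDM deviance is the binomial-type form; other GDM implementations
  differ in likelihood details, so percent-deviance values are
  comparable within this package.
* The ≥ 5-species filter plus 2-axis hulls can retain a site whose
  five species occupy fewer than three unique trait positions; such
  sites are excluded with an explicit reason instead of silently
  passing.
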