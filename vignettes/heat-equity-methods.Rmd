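---
title: "Methods: quantifying demographic disparities in surface urban heat island exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying demographic disparities in surface urban heat island exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatEquity)
```

## The problem

Built-up areas are hotter than their rural surroundings. The surface urban
heat island (SUHI) intensity of a census tract isolates this urban
contribution to heat exposure: it is the difference between the tract's
mean land surface temperature (LST) and a rural reference temperature for
the urbanized area the tract belongs to. Because demographic composition
varies across tracts, SUHI exposure can be distributed unevenly across
racial, income and age groups within a city. `heatEquity` provides the
full chain needed to quantify such disparities: zonal SUHI statistics from
gridded LST and land cover, demographic group construction from tract count
tables, population-weighted exposure comparisons with cluster-robust
inference, Kolm–Pollak inequality summaries, and a synthetic-city generator
with recoverable ground truth that lets every stage be validated without
any external data.

## Tract-level SUHI: the simplified urban extent method

For tract $t$ inside urbanized area $u$,

$$\mathrm{SUHI}_t = \mathrm{LST}_t - \mathrm{LST}_r,$$

where $\mathrm{LST}_t$ averages the non-missing LST pixels assigned to both
the tract and its urbanized area, and the rural reference $\mathrm{LST}_r$
averages the nonurban, nonwater pixels of the urbanized area. Conventions
the implementation fixes:

* **Water on the urban side.** The reference side excludes water by
  definition; whether the tract mean should too is a genuine choice. The
  default excludes water pixels from $\mathrm{LST}_t$, mirroring the
  nonwater rule, because open water does not represent residential heat
  exposure; `includeWater = TRUE` restores the inclusive mean, and the
  choice is recorded in the output's `include_water` attribute.
* **Pixels are atomic.** A pixel belongs to a zone by center containment;
  there is no area weighting of boundary pixels, matching the pixel-level
  character of satellite sources.
* **Missing data.** Missing LST pixels are excluded from every mean. A
  tract whose urbanized-area portion contains no valid pixel is skipped and
  logged (never a silent `NaN`); an urbanized area with no valid rural
  pixel is a hard error naming the area, since no SUHI there is
  computable.
* **Tolerances.** Invariant checks (uniform grid gives zero SUHI;
  adding a constant to every pixel changes nothing) hold to 1e-9 °C.

Grids travel as plain-text ESRI ASCII rasters (LST in °C with a nodata
sentinel; land cover coded 1 = urban, 2 = nonurban, 3 = water; integer
urbanized-area and tract zone grids).

## Exposure estimands and inference

Every resident of a tract is assigned the tract's SUHI, so the mean
exposure of group $g$ is the weighted mean over tracts with person counts
as weights,
$\bar x_g = \sum_t w_{gt} x_t / \sum_t w_{gt}$, with the population-form
weighted SD alongside. Tracts where a group has zero members contribute
zero weight rather than being dropped — identical estimates, cleaner
bookkeeping. Unmatched tract ids between the SUHI table and the
demographics are logged and excluded from both sides.

Group gaps are estimated by weighted least squares on stacked
(tract × group) observations of SUHI on a group indicator with person-count
weights; the slope equals the difference in weighted means exactly, which
the test suite asserts to 1e-9 °C. Standard errors are cluster-robust
(CR1 sandwich, the $\tfrac{G}{G-1}\tfrac{N-1}{N-K}$ small-sample scaling)
by urbanized area, because tracts within a city share the same rural
reference and any city-level shock; the reference distribution is $t$ with
$G-1$ degrees of freedom, a deliberately conservative small-$G$ choice.
With a single cluster the functions fall back to heteroskedasticity-robust
(HC1) errors with a warning. Significance stars follow the 10% / 5% / 1%
convention.

Per-city tests use the same weighted estimand with HC1 errors (tracts are
the units within one city; no clustering is possible) and a 5% significance
flag. The per-city tests weight tracts by group population, consistent with
the pooled estimand, rather than treating tracts equally — the alternative
would answer a question about tracts, not about people. City tallies count
the comparable cities in which each group is worse off and the significant
subsets; threshold counts use strict inequality, so ties sit below the
threshold. City-mean kernel densities use a Gaussian kernel with
Silverman's rule-of-thumb bandwidth on a 512-point grid spanning the data
range ± 3 bandwidths (configurable), with the area under the curve scaled
to the number of cities so two groups' curves compare as city counts.

## The Kolm–Pollak index and EDE

Mean comparisons can mask hotspots. With convex heat damages, a group
facing a dispersed exposure distribution is worse off than one facing the
same mean uniformly. For exposures $x_n$ with person weights $w_n$, total
$W$ and weighted mean $\bar x$, the Kolm–Pollak inequality index with
aversion parameter $\kappa < 0$ (units 1/°C) is

$$I(\mathbf x) = -\frac{1}{\kappa}\,
  \ln \sum_n \frac{w_n}{W}\, e^{\kappa(\bar x - x_n)},$$

the weighted generalization of the equal-weight form (individuals within a
tract share one exposure, so $w_n/W$ replaces $1/N$). The equally
distributed equivalent is $\mathrm{EDE} = \bar x + I$: the uniform exposure
an impartial agent would accept in place of the actual distribution. The
index is translation invariant, nonnegative, zero exactly when all
weighted exposures are equal, nondecreasing in $|\kappa|$, and approaches
$|\kappa| \cdot \mathrm{Var}_w(x)/2$ as $\kappa \to 0^-$ — all properties
the test suite checks numerically.

The sum is evaluated as a max-shifted log-sum-exp, so exposures spanning
$10^6$ °C with $\kappa = -1$ neither overflow nor lose the result to
cancellation (a stress test asserts this). Tiny negative values from
roundoff (the index is nonnegative by Jensen) are clamped to zero below
1e-12.

The default $\kappa = -0.5$ is labeled *moderate* aversion; because the
appropriate aversion is application-specific, $\kappa$ is mandatory in all
outputs and sweeps over a $\kappa$ list are first-class
(`kpSweep()`, the `kappa_list` pipeline key). City-level indices are
aggregated to zone and national scope as means weighted by the group's
city population, the reading of "population-weighted mean of city indexes"
consistent with the exposure estimand; the cross-group difference in mean
indices likewise weights cities by group population and uses HC1 errors
over cities.

## What the synthetic generator emulates

`generateCity()` builds a circular city: an urban core (disk, radius
0.30 × grid size) inside an urbanized area (radius 0.45 × grid size) whose
nonurban ring is the rural reference. LST is a rural base (30 °C) plus a
Gaussian urban-heat kernel (peak `suhiAmplitude`, default 4 °C) plus iid
cell noise (`noiseSd`, default 1 °C), with a small fraction of water cells
(2%) and missing pixels (1%). Tracts partition the urban core via a seeded
k-means on cell coordinates (roughly contiguous, roughly equal-area).

Demographics follow a multinomial logit: the share of group $g$ in tract
$t$ is the softmax of $\alpha_g + \beta_g s_t + \epsilon_{gt}$, where
$s_t$ is the tract's *deterministic* SUHI component,
$\epsilon_{gt} \sim N(0, \sigma_\epsilon^2)$ with
$\sigma_\epsilon = 0.5$, and counts are rounded by largest-remainder
apportionment so partitions sum exactly. The disparity slope $\beta$
(per °C) is the recoverable parameter. Defaults — two groups around a 40%
people-of-color baseline with slopes ±0.6 per °C, lognormal tract
populations around 4000 — were chosen to produce a medium segregation
strength with a group gap of order half a degree, the scale at which the
published national disparities sit; age is crossed with group at fixed
within-group shares (6% under 5, 16% over 65) independent of SUHI.

Linking shares to the deterministic component rather than the realized
(noisy) SUHI is deliberate: it keeps weights independent of measurement
noise, so the generator's truth records are exact estimands. Three truth
levels are exposed:

* `truthDisparity()` — the realized gap from the stored tract table, an
  independent-arithmetic cross-check that must equal the
  regression estimate to 1e-9 °C;
* `truthExpectedGap()` — the same gap on the noise-free SUHI component,
  the conditional estimand for a given panel;
* `populationGap()` — the analytic super-population gap of the tract-level
  model, with the logit share noise integrated out numerically; the fixed
  truth for bias and coverage studies.

Panels derive per-city seeds from the master seed by a counter-based
scheme (reproducible regardless of generation order) and assign climate
zone labels — arid, snow, temperate, equatorial — round-robin; zones are
labels here, not mechanisms.

**Tract-level mode.** `cellLevel = FALSE` simulates the identical
statistical model directly at tract level: the deterministic radial SUHI
profile with equal-area tract placement, per-tract noise scaled by the
implied cell counts, and a single shared rural-reference shock per city.
That shock is what makes errors correlate within a city and is precisely
the correlation the clustered standard errors must absorb. This mode is
orders of magnitude faster and drives the Monte-Carlo studies; the raster
path is validated against the generator's cell-level records separately.

What the generator does **not** emulate: realistic urban morphology,
spatially autocorrelated LST noise, within-tract demographic heterogeneity,
survey sampling error in the counts, or any mechanistic climate-zone
effect. Passing tests therefore demonstrate the statistical machinery is
correct under the stated model, not that real cities satisfy that model.

## Monte-Carlo study sizes

The calibration and recovery studies in the acceptance tests use 400 null
panels and 200 disparity panels of 40 tract-level cities with 25 tracts
each — large enough that the binomial error on a 5% rejection rate is
about ±1.1% and the coverage estimate about ±1.5%, while a full run stays
in the low minutes on one core. The clustered test's type-I error at 40
clusters sits slightly above nominal (the familiar small-$G$ behavior of
CR1), within the 5% ± 2% acceptance band; confidence-interval coverage
against the analytic population gap is likewise within 95% ± 3%.

## Pipeline conventions

`runPipeline()` writes CSVs with six significant digits so reruns under a
fixed config and seed are byte-identical (full-precision copies via
`precise: true`), echoes the configuration and all decision toggles into
`run.log`, aborts with a stage-named error and removes partial outputs on
any failure. `validateInputs()` checks grid alignment, land cover codes,
tract-to-urbanized-area consistency, duplicate tract ids, join coverage
between zone grids and demographics (listing the exact missing ids) and
partition conservation before any analysis runs.

## Known limitations

* Grids must share one shape and registration; no reprojection or
  resampling is performed, and zone maps are consumed as integer grids
  (polygon inputs must be rasterized upstream).
* Survey margins of error on the demographic counts are ignored; counts
  are treated as known weights.
* No spatial autocorrelation correction beyond clustering by urbanized
  area.
* The Kolm–Pollak index is the only inequality metric implemented;
  Atkinson or Gini alternatives are out of scope.
* Real-data reproduction requires externally obtained SUHI and census
  tables; the package itself builds and validates entirely on synthetic
  data.
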