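# heatEquity

Tools for quantifying how surface urban heat island (SUHI) intensity is
distributed across demographic groups — for environmental-health and
environmental-justice researchers working with gridded land surface
temperature (LST), land cover, and census-tract count tables.

## What it computes

**Tract-level SUHI** by the simplified urban extent method. For a census
tract *t* in urbanized area *u*,

    SUHI_t = LST_t − LST_r

where `LST_t` is the tract's mean LST over pixels inside the urbanized
area (water excluded by default) and `LST_r` is the mean LST of the
nonurban, nonwater pixels of that urbanized area.

**Population-weighted exposure comparisons.** Group means are weighted
means over tracts with person counts as weights; group gaps are estimated
by weighted least squares on stacked tract × group observations with
CR1 cluster-robust standard errors by urbanized area (t reference with
G − 1 degrees of freedom), plus per-city tests, direction/significance
tallies, threshold counts, and city-mean kernel densities scaled to city
counts.

**Kolm–Pollak inequality index and EDE.** For exposures x with person
weights w, weighted mean x̄ and aversion κ < 0 (units 1/°C),

    I(x) = −(1/κ) · ln Σ (wₙ/W) · exp(κ (x̄ − xₙ)),   EDE = x̄ + I(x)

evaluated by a numerically stable log-sum-exp; κ sweeps and cross-group
index comparisons included.

**A synthetic-city generator** with recoverable ground truth: raster
cities (urban core, rural ring, water, missing pixels) whose tract
demographics follow a logit in the deterministic SUHI gradient, so the
disparity slope is a known, recoverable parameter. Every analysis stage is
validated end-to-end against it.

## Worked example

Generate a small 8-city synthetic panel, recompute tract SUHI from the
rasters, and compare people-of-color and non-Hispanic-white exposure:

```r
library(heatEquity)
cfg <- syntheticConfig(nCities = 8)
panel <- generatePanel(cfg, seed = 2026)
suhi <- do.call(rbind, lapply(panelCities(panel), function(ct)
  computeSuhi(cityRasterOf(ct))))
demo <- panelDemographics(panel)

groupMeanDifference(suhi, demo, "poc", "nh_white")
#>      scope     unit group_a  group_b      diff         se df        t
#> 1 national national     poc nh_white 0.3981587 0.02990397  7 13.31458
#>        p_value stars n_clusters
#> 1 3.156012e-06   ***          8
```

The average person of color in this panel lives in a tract 0.40 °C hotter
(SUHI) than the average non-Hispanic white person; the clustered test
(8 urbanized areas, so 7 df) rejects equality at the 1% level. The
generator's own arithmetic confirms the estimand:

```r
truthDisparity(panel, "poc", "nh_white")
#> [1] 0.3981587
```

Inequality within the whole population's exposure distribution:

```r
kpIndex(suhi$suhi, demographicCounts(demo)$total, kappa = -0.5)
#>   kappa     index      ede    mean total_weight   n
#> 1  -0.5 0.1222561 1.823547 1.70129       829710 200
```

At moderate aversion (κ = −0.5 per °C) the equally distributed equivalent
exposure is 1.82 °C against a mean of 1.70 °C: an impartial agent would
accept a uniform exposure 0.12 °C above the mean to be rid of the
dispersion. An end-to-end run producing all output tables:

```r
runPipeline(list(seed = 1, out = "run1", synth = list(nCities = 8)))
```

writes `table1_means.csv`, `table1_diffs.csv`, `table2_kp.csv`,
`table3_age.csv`, `city_tests.csv`, `densities.csv` and `run.log` under
`run1/`. A thin CLI with the same capabilities is installed at
`inst/scripts/heat-equity` (`synth`, `run`, `validate` subcommands).

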