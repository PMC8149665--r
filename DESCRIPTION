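Package: heatEquity
Title: Demographic Disparities in Surface Urban Heat Island Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how surface urban heat island (SUHI)
    intensity is distributed across demographic groups. Computes census
    tract level SUHI from aligned land surface temperature and land cover
    grids using the simplified urban extent method, builds demographic
    groups from tract count tables, estimates population-weighted exposure
    means and cluster-robust difference-in-means tests, computes the
    Kolm-Pollak inequality index and equally distributed equivalent
    exposure, and generates synthetic segregated cities with known
    disparity structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
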