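# Synthetic-city generator: determinism, degenerate configurations, and
# agreement between generator truth and the analysis modules.

smallCfg <- function(...) syntheticConfig(gridSize = 24, nTracts = 8, ...)

test_that("generation is deterministic and leaves the caller RNG alone", {
  cfg <- smallCfg()
  set.seed(99); before <- rnorm(1)
  a <- generateCity(cfg, seed = 5, cityId = 1)
  b <- generateCity(cfg, seed = 5, cityId = 1)
  expect_identical(cityTracts(a), cityTracts(b))
  expect_identical(demographicCounts(cityDemographics(a)),
                   demographicCounts(cityDemographics(b)))
  expect_identical(lstGrid(cityRasterOf(a)), lstGrid(cityRasterOf(b)))
  set.seed(99); after <- rnorm(1)
  expect_identical(before, after)
  # different seeds differ
  c <- generateCity(cfg, seed = 6, cityId = 1)
  expect_false(identical(cityTracts(a)$suhi, cityTracts(c)$suhi))
})

test_that("flat city (zero amplitude, zero noise) has zero SUHI", {
  cfg <- smallCfg(suhiAmplitude = 0, noiseSd = 0, missingRate = 0,
                  waterFrac = 0)
  ct <- generateCity(cfg, seed = 3, cityId = 1)
  recs <- computeCitySuhi(cityRasterOf(ct), 1L)
  expect_true(all(abs(recs$suhi) < 1e-12))
  expect_true(all(abs(cityTracts(ct)$suhi) < 1e-12))
})

test_that("no-disparity null with exact halves gives identical group means", {
  cfg <- smallCfg(noiseSd = 0, shareNoiseSd = 0, popSdLog = 0,
                  meanTractPop = 4000,
                  groups = list(a = list(alpha = 0, beta = 0),
                                b = list(alpha = 0, beta = 0)))
  ct <- generateCity(cfg, seed = 4, cityId = 1)
  expect_equal(truthDisparity(ct, "a", "b"), 0, tolerance = 1e-12)
  dm <- demographicCounts(cityDemographics(ct))
  expect_true(all(dm$a == dm$b))
})

test_that("raster-path SUHI equals the generator's cell-level records", {
  cfg <- smallCfg()
  ct <- generateCity(cfg, seed = 11, cityId = 3)
  recs <- suppressMessages(computeCitySuhi(cityRasterOf(ct), 3L))
  tr <- cityTracts(ct)
  m <- merge(recs, tr, by = "tract_id")
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$suhi.x, m$suhi.y, tolerance = 1e-12)
  expect_equal(m$n_cells.x, m$n_cells.y)
})

test_that("generator truth matches the exposure-stats estimand to 1e-9", {
  for (cellLevel in c(TRUE, FALSE)) {
    cfg <- smallCfg()
    p <- generatePanel(cfg, seed = 21, nCities = 3, cellLevel = cellLevel)
    est <- groupMeanDifference(panelSuhiTable(p), panelDemographics(p),
                               "poc", "nh_white")
    expect_equal(est$diff, truthDisparity(p, "poc", "nh_white"),
                 tolerance = 1e-9)
  }
  # two-tract handmade check of the truth arithmetic itself
  cfg <- syntheticConfig(gridSize = 24, nTracts = 2)
  ct <- generateCity(cfg, seed = 8, cellLevel = FALSE)
  tr <- cityTracts(ct)
  dm <- demographicCounts(cityDemographics(ct))
  byHand <- with(list(), {
    (dm$poc[1] * tr$suhi[1] + dm$poc[2] * tr$suhi[2]) / sum(dm$poc) -
      (dm$nh_white[1] * tr$suhi[1] + dm$nh_white[2] * tr$suhi[2]) /
        sum(dm$nh_white)
  })
  expect_equal(truthDisparity(ct, "poc", "nh_white"), byHand,
               tolerance = 1e-12)
})

test_that("stored truth summaries are recomputable from the tract table", {
  cfg <- smallCfg()
  ct <- generateCity(cfg, seed = 31)
  tr <- cityTracts(ct)
  dm <- demographicCounts(cityDemographics(ct))
  tru <- cityTruth(ct)
  for (g in c("nh_white", "poc")) {
    expect_equal(tru$groupMean[[g]], sum(dm[[g]] * tr$suhi) / sum(dm[[g]]),
                 tolerance = 1e-12)
    expect_equal(tru$groupKP[[g]],
                 kpIndex(tr$suhi, dm[[g]], tru$kappa)$index,
                 tolerance = 1e-9)
  }
})

test_that("panels derive city seeds deterministically and label zones
           round-robin", {
  cfg <- smallCfg(nCities = 5)
  p1 <- generatePanel(cfg, seed = 77, cellLevel = FALSE)
  p2 <- generatePanel(cfg, seed = 77, cellLevel = FALSE)
  expect_identical(panelSuhiTable(p1), panelSuhiTable(p2))
  expect_identical(panelZones(p1)$zone,
                   c("arid", "snow", "temperate", "equatorial", "arid"))
  single <- generatePanel(cfg, seed = 77, nCities = 1, cellLevel = FALSE)
  lone <- generateCity(cfg, heatEquity:::deriveSeed(77, 1), cityId = 1,
                       cellLevel = FALSE)
  expect_identical(cityTracts(panelCities(single)[[1]]), cityTracts(lone))
})

test_that("demographic partitions hold exactly by construction", {
  cfg <- smallCfg()
  ct <- generateCity(cfg, seed = 41, cellLevel = FALSE)
  expect_true(isTRUE(checkPartitions(cityDemographics(ct))))
  dm <- demographicCounts(cityDemographics(ct))
  expect_true(all(dm$nh_white + dm$poc == dm$total))
})

test_that("exposure inequality grows with temperature noise", {
  # averaged over seeds: larger measurement noise spreads the realized
  # exposure distribution and raises the index at fixed mean structure
  meanIdx <- vapply(c(0.25, 0.5, 1, 2), function(sd) {
    cfg <- smallCfg(noiseSd = sd)
    mean(vapply(1:20, function(s) {
      tr <- cityTracts(generateCity(cfg, seed = 600 + s, cellLevel = FALSE))
      kpIndex(tr$suhi, tr$population, kappa = -0.5)$index
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanIdx) > 0))
})

test_that("infeasible tract partitions are rejected", {
  expect_error(syntheticConfig(gridSize = 10, nTracts = 500),
               "infeasible partition")
})

test_that("analytic population gap sits near the panel-realized gaps", {
  cfg <- smallCfg()
  gapInf <- populationGap(cfg, "poc", "nh_white")
  expect_gt(gapInf, 0)
  gaps <- vapply(1:30, function(s) {
    p <- generatePanel(cfg, seed = 500 + s, nCities = 10, cellLevel = FALSE)
    truthExpectedGap(p, "poc", "nh_white")
  }, numeric(1))
  expect_lt(abs(mean(gaps) - gapInf), 3 * sd(gaps) / sqrt(30) + 0.01)
  # zero disparity slope and equal baselines give a zero analytic gap
  cfgNull <- smallCfg(groups = list(a = list(alpha = 0, beta = 0),
                                    b = list(alpha = 0, beta = 0)))
  expect_equal(populationGap(cfgNull, "a", "b"), 0, tolerance = 1e-9)
})
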