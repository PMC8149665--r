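# Population-weighted exposure summaries and inference.

# Multi-city fixture: nCity cities x nTract tracts, two groups with an
# exposure gradient, returned as (suhi, demo, zones, counts-data.frame).
statsFixture <- function(seed, nCity = 6, nTract = 10) {
  set.seed(seed)
  suhi <- do.call(rbind, lapply(seq_len(nCity), function(u) {
    data.frame(tract_id = sprintf("%d-%d", u, seq_len(nTract)),
               urbanized_area_id = u,
               suhi = rnorm(nTract, 2, 1.2))
  }))
  counts <- data.frame(tract_id = suhi$tract_id,
                       a = rpois(nrow(suhi), 300) +
                         round(80 * pmax(suhi$suhi, 0)),
                       b = rpois(nrow(suhi), 400))
  counts$total <- counts$a + counts$b
  zones <- data.frame(urbanized_area_id = seq_len(nCity),
                      zone = rep(c("snow", "temperate"),
                                 length.out = nCity))
  list(suhi = suhi,
       demo = demographicTable(counts, scheme = "fixture",
                               partitions = list(total = c("a", "b"))),
       zones = zones, counts = counts)
}

test_that("weighted means reduce to the obvious answers", {
  suhi <- data.frame(tract_id = c("1", "2"), urbanized_area_id = 1L,
                     suhi = c(1, 3))
  demo <- demographicTable(data.frame(tract_id = c("1", "2"),
                                      g = c(100, 100),
                                      h = c(0, 100)), scheme = "toy")
  wm <- weightedGroupMean(suhi, demo, "g")
  expect_equal(wm$weighted_mean, 2)
  expect_equal(wm$weighted_sd, 1)
  expect_equal(wm$total_weight, 200)
  # all weight on one tract: degenerate sd
  wh <- weightedGroupMean(suhi, demo, "h")
  expect_equal(wh$weighted_mean, 3)
  expect_equal(wh$weighted_sd, 0)
  expect_error(weightedGroupMean(suhi, demographicTable(
    data.frame(tract_id = c("1", "2"), g = c(0, 0)), "toy"), "g"),
    "empty group")
})

test_that("weighted mean and sd match a brute-force loop on 200 tracts", {
  set.seed(21)
  suhi <- data.frame(tract_id = as.character(1:200),
                     urbanized_area_id = rep(1:4, each = 50),
                     suhi = rnorm(200, 2, 1.5))
  w <- runif(200, 0, 1000)
  demo <- demographicTable(data.frame(tract_id = as.character(1:200), g = w),
                           scheme = "loop")
  wm <- weightedGroupMean(suhi, demo, "g")
  num <- 0; den <- 0
  for (i in 1:200) { num <- num + w[i] * suhi$suhi[i]; den <- den + w[i] }
  m <- num / den
  v <- 0
  for (i in 1:200) v <- v + w[i] * (suhi$suhi[i] - m)^2
  expect_equal(wm$weighted_mean, m, tolerance = 1e-12)
  expect_equal(wm$weighted_sd, sqrt(v / den), tolerance = 1e-12)
})

test_that("partition-combining identity links total and group means", {
  fx <- statsFixture(22)
  tot <- weightedGroupMean(fx$suhi, fx$demo, "total")
  byGroup <- lapply(c("a", "b"), function(g)
    weightedGroupMean(fx$suhi, fx$demo, g))
  wsum <- sum(vapply(byGroup, function(d) d$total_weight, numeric(1)))
  combined <- sum(vapply(byGroup, function(d)
    d$total_weight * d$weighted_mean, numeric(1))) / wsum
  expect_equal(tot$weighted_mean, combined, tolerance = 1e-9)
  expect_equal(tot$total_weight, wsum)
})

test_that("regression difference equals the direct difference of weighted
           means", {
  for (seed in 23:25) {
    fx <- statsFixture(seed)
    d <- groupMeanDifference(fx$suhi, fx$demo, "a", "b")
    direct <- oracleWeightedDiff(fx$suhi, fx$counts, "a", "b")
    expect_equal(d$diff, direct, tolerance = 1e-9)
    # and per zone
    dz <- groupMeanDifference(fx$suhi, fx$demo, "a", "b", "zone", fx$zones)
    for (z in unique(fx$zones$zone)) {
      uas <- fx$zones$urbanized_area_id[fx$zones$zone == z]
      sub <- fx$suhi[fx$suhi$urbanized_area_id %in% uas, ]
      expect_equal(dz$diff[dz$unit == z],
                   oracleWeightedDiff(sub, fx$counts, "a", "b"),
                   tolerance = 1e-9)
    }
  }
})

test_that("clustered SE matches the hand-coded CR1 sandwich oracle", {
  fx <- statsFixture(26)
  d <- groupMeanDifference(fx$suhi, fx$demo, "a", "b")
  stacked <- rbind(
    data.frame(y = fx$suhi$suhi, g = 1, w = fx$counts$a,
               cl = fx$suhi$urbanized_area_id),
    data.frame(y = fx$suhi$suhi, g = 0, w = fx$counts$b,
               cl = fx$suhi$urbanized_area_id))
  stacked <- stacked[stacked$w > 0, ]
  orc <- oracleClusteredSE(stacked$y, stacked$g, stacked$w, stacked$cl)
  expect_equal(d$diff, orc$diff, tolerance = 1e-12)
  expect_equal(d$se, orc$se, tolerance = 1e-9)
  expect_equal(d$df, 5)  # G - 1 clusters
  expect_equal(d$p_value, 2 * pt(-abs(d$diff / d$se), 5), tolerance = 1e-12)
})

test_that("clustered SE is consistent with a cluster bootstrap", {
  fx <- statsFixture(27, nCity = 12, nTract = 10)
  d <- groupMeanDifference(fx$suhi, fx$demo, "a", "b")
  set.seed(999)
  boots <- replicate(1000, {
    uas <- sample(unique(fx$suhi$urbanized_area_id), replace = TRUE)
    sub <- do.call(rbind, lapply(uas, function(u)
      fx$suhi[fx$suhi$urbanized_area_id == u, ]))
    oracleWeightedDiff(sub, fx$counts, "a", "b")
  })
  expect_lt(abs(sd(boots) - d$se) / d$se, 0.15)
})

test_that("clustered SE equals robust SE when each cluster is one
           single-group tract", {
  # disjoint groups, one tract per urbanized area: every cluster holds
  # exactly one stacked observation, so CR1 and HC1 coincide
  set.seed(28)
  n <- 16
  suhi <- data.frame(tract_id = as.character(1:n),
                     urbanized_area_id = 1:n,
                     suhi = rnorm(n, 2, 1))
  counts <- data.frame(tract_id = as.character(1:n),
                       a = c(rpois(n / 2, 100), rep(0, n / 2)),
                       b = c(rep(0, n / 2), rpois(n / 2, 100)))
  demo <- demographicTable(counts, scheme = "disjoint")
  d <- groupMeanDifference(suhi, demo, "a", "b")
  keep <- c(counts$a[1:(n / 2)], counts$b[(n / 2 + 1):n])
  orc <- oracleRobustSE(suhi$suhi, c(rep(1, n / 2), rep(0, n / 2)), keep)
  expect_equal(d$se, orc$se, tolerance = 1e-9)
})

test_that("disjoint two-tract groups give the exact separation answer", {
  suhi <- data.frame(tract_id = c("1", "2"), urbanized_area_id = c(1L, 2L),
                     suhi = c(1, 3))
  demo <- demographicTable(data.frame(tract_id = c("1", "2"),
                                      a = c(0, 50), b = c(50, 0)),
                           scheme = "sep")
  d <- groupMeanDifference(suhi, demo, "a", "b")
  expect_equal(d$diff, 2)
  # identical distributions: difference zero, p ~ 1
  demo2 <- demographicTable(data.frame(tract_id = c("1", "2"),
                                       a = c(50, 50), b = c(50, 50)),
                            scheme = "same")
  d2 <- groupMeanDifference(suhi, demo2, "a", "b")
  expect_equal(d2$diff, 0, tolerance = 1e-12)
  expect_gt(d2$p_value, 0.99)
})

test_that("significance stars follow the 10/5/1 percent thresholds", {
  expect_identical(heatEquity:::starsFromP(c(0.005, 0.03, 0.07, 0.2, NA)),
                   c("***", "**", "*", "", NA))
})

test_that("single-cluster scopes fall back to robust SEs with a warning", {
  fx <- statsFixture(29, nCity = 1)
  expect_warning(d <- groupMeanDifference(fx$suhi, fx$demo, "a", "b"),
                 "single cluster")
  expect_true(is.finite(d$se) && d$se > 0)
})

test_that("per-city tests flag separation and incomparable cities", {
  # identical occupation: no difference
  suhi <- data.frame(tract_id = c("1", "2"), urbanized_area_id = 1L,
                     suhi = c(1, 3))
  demo <- demographicTable(data.frame(tract_id = c("1", "2"),
                                      a = c(40, 40), b = c(40, 40)),
                           scheme = "toy")
  ct <- cityLevelTest(suhi, demo, "a", "b")
  expect_equal(ct$diff, 0, tolerance = 1e-12)
  expect_false(ct$significant)
  # full separation with zero within-group variance: significant
  demo2 <- demographicTable(data.frame(tract_id = c("1", "2"),
                                       a = c(0, 40), b = c(40, 0)),
                            scheme = "toy2")
  ct2 <- suppressWarnings(cityLevelTest(suhi, demo2, "a", "b"))
  expect_equal(ct2$diff, 2)
  expect_true(ct2$significant)
  # absent group: marked not comparable
  demo3 <- demographicTable(data.frame(tract_id = c("1", "2"),
                                       a = c(0, 0), b = c(40, 40)),
                            scheme = "toy3")
  ct3 <- cityLevelTest(suhi, demo3, "a", "b")
  expect_false(ct3$comparable)
})

test_that("city-test sign tracks the generating disparity direction", {
  cfg <- syntheticConfig(nTracts = 50)
  hits <- vapply(1:100, function(s) {
    ct <- generateCity(cfg, seed = 3000 + s, cellLevel = FALSE)
    test <- cityLevelTest(cityTracts(ct), cityDemographics(ct),
                          "poc", "nh_white")
    sign(test$diff) == sign(truthExpectedGap(ct, "poc", "nh_white"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("tallies count directions and significance correctly", {
  tests <- data.frame(urbanized_area_id = as.character(1:10),
                      diff = rep(1, 10), se = 1, p_value = 0.2,
                      significant = FALSE, comparable = TRUE)
  tl <- tallyCityComparisons(tests)
  expect_equal(tl$prop_a_worse[tl$zone == "total"], 1)
  expect_equal(tl$prop_a_worse_sig[tl$zone == "total"], 0)

  tests2 <- data.frame(
    urbanized_area_id = as.character(1:6),
    diff = c(0.5, -0.2, 0.9, 0.3, -0.1, 0.4),
    se = 1,
    p_value = c(0.01, 0.2, 0.03, 0.5, 0.04, 0.2),
    significant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    comparable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  zones <- data.frame(urbanized_area_id = as.character(1:6),
                      zone = rep(c("snow", "arid"), 3))
  tl2 <- tallyCityComparisons(tests2, zones)
  tot <- tl2[tl2$zone == "total", ]
  # hand count over the 5 comparable cities: diffs 0.5, -0.2, 0.9, 0.3,
  # -0.1 with significance TRUE, FALSE, TRUE, FALSE, TRUE
  expect_equal(tot$n_comparable, 5)
  expect_equal(tot$prop_a_worse, 3 / 5)
  expect_equal(tot$prop_a_worse_sig, 2 / 5)
  expect_equal(tot$prop_b_worse, 2 / 5)
  expect_equal(tot$prop_b_worse_sig, 1 / 5)
})

test_that("threshold counting is strict", {
  expect_equal(citiesAboveThreshold(c(1.9, 2.1, 2.0), 2), 1)
  expect_equal(citiesAboveThreshold(numeric(0), 2), 0)
  set.seed(30)
  means <- rnorm(175, 2, 0.8)
  expect_equal(citiesAboveThreshold(means, 2), sum(means > 2))
})

test_that("kernel densities integrate to one and scale to the city count", {
  set.seed(31)
  means <- rnorm(175, 2, 0.9)
  d <- exposureDensity(means, nCities = 175)
  expect_lt(abs(trapezoid(d$x, d$density) - 1), 1e-3)
  expect_lt(abs(trapezoid(d$x, d$scaled) - 175), 0.2)
  expect_equal(attr(d, "bw"), stats::bw.nrd0(means))
  # Gaussian kernel decay: ten bandwidths beyond the data the density is a
  # negligible fraction of the peak
  dWide <- exposureDensity(means, cut = 10)
  peak <- max(dWide$density)
  expect_lt(dWide$density[1] / peak, 1e-6)
  expect_lt(dWide$density[512] / peak, 1e-6)
  expect_warning(exposureDensity(rep(2, 5)), "identical")
})
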