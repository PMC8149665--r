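# Synthetic segregated cities with recoverable ground truth. Each city is a
# circular urbanized area: an urban core (disk) inside a nonurban ring that
# serves as the rural reference, with a Gaussian urban-heat kernel on top of
# a rural base temperature, cell-level measurement noise, a few water
# patches and missing pixels. Tract demographic shares follow a multinomial
# logit in the tract's deterministic SUHI, so the disparity slope beta (per
# degree C) is the recoverable parameter. Shares respond to the persistent
# urban-form gradient (suhi_det), not to measurement noise, which keeps the
# generator's expected-gap truth exact.

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic-city generator
#'
#' Defaults describe a mid-sized study city: a 48 x 48 km grid at 1 km
#' resolution, an urbanized area of radius 0.45 x grid size whose urban core
#' (radius 0.30 x grid size) is split into 25 tracts of roughly 4000
#' residents, a 4 degree C urban-heat kernel over a 30 degree C rural base
#' with 1 degree C cell noise, and two demographic groups whose tract shares
#' follow a logit in tract SUHI with slopes of -0.6 and +0.6 per degree C
#' around a 40% people-of-color baseline.
#'
#' @param gridSize cells per side of the square grid.
#' @param nTracts tracts per city (must not exceed the urban-core cell
#'   count).
#' @param uaRadiusFrac,urbanRadiusFrac urbanized-area and urban-core radii
#'   as fractions of `gridSize`.
#' @param ruralBase rural base LST, degrees C.
#' @param suhiAmplitude peak of the urban-heat kernel, degrees C.
#' @param noiseSd cell-level LST noise SD, degrees C.
#' @param waterFrac fraction of cells labeled water.
#' @param missingRate fraction of LST cells flagged missing.
#' @param groups named list; per group a list with `alpha` (baseline logit
#'   score) and `beta` (disparity slope per degree C). Shares are the
#'   softmax of `alpha + beta * suhi_det + noise`.
#' @param shareNoiseSd SD of the per-tract, per-group logit-score noise.
#' @param meanTractPop mean tract population; tract populations are
#'   lognormal around it with log-SD `popSdLog`.
#' @param popSdLog log-scale SD of tract populations.
#' @param ageFractions named vector `c(under5 = , over65 = )` of within-group
#'   age shares (age is independent of SUHI in the generator).
#' @param nCities cities per panel.
#' @param zoneLabels climate-zone labels assigned round-robin across cities.
#' @param kappa aversion parameter used for the truth-side Kolm-Pollak
#'   index.
#' @return a list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(gridSize = 48, nTracts = 25,
                            uaRadiusFrac = 0.45, urbanRadiusFrac = 0.30,
                            ruralBase = 30, suhiAmplitude = 4, noiseSd = 1,
                            waterFrac = 0.02, missingRate = 0.01,
                            groups = list(
                              nh_white = list(alpha = 0.4, beta = -0.6),
                              poc = list(alpha = -0.4, beta = 0.6)),
                            shareNoiseSd = 0.5,
                            meanTractPop = 4000, popSdLog = 0.3,
                            ageFractions = c(under5 = 0.06, over65 = 0.16),
                            nCities = 40,
                            zoneLabels = c("arid", "snow", "temperate",
                                           "equatorial"),
                            kappa = -0.5) {
  cfg <- list(gridSize = gridSize, nTracts = nTracts,
              uaRadiusFrac = uaRadiusFrac, urbanRadiusFrac = urbanRadiusFrac,
              ruralBase = ruralBase, suhiAmplitude = suhiAmplitude,
              noiseSd = noiseSd, waterFrac = waterFrac,
              missingRate = missingRate, groups = groups,
              shareNoiseSd = shareNoiseSd, meanTractPop = meanTractPop,
              popSdLog = popSdLog, ageFractions = ageFractions,
              nCities = nCities, zoneLabels = zoneLabels, kappa = kappa)
  stopifnot(gridSize >= 8, nTracts >= 1, uaRadiusFrac > urbanRadiusFrac,
            uaRadiusFrac <= 0.5, noiseSd >= 0, meanTractPop > 0,
            length(groups) >= 2, nCities >= 1, kappa < 0)
  nUrban <- floor(pi * (urbanRadiusFrac * gridSize)^2)
  if (nTracts > nUrban)
    stop(sprintf("infeasible partition: %d tracts but only ~%d urban cells",
                 nTracts, nUrban))
  class(cfg) <- "syntheticConfig"
  cfg
}

# Demographic counts for one city given tract-level deterministic SUHI.
# Returns a data.frame: tract_id, total, one column per group, and
# group-by-age columns (<group>_u5, <group>_o65).
synthDemographics <- function(cfg, tractIds, suhiDet) {
  gnames <- names(cfg$groups)
  nT <- length(tractIds)
  pop <- pmax(1, round(cfg$meanTractPop *
                         exp(stats::rnorm(nT, 0, cfg$popSdLog))))
  scores <- sapply(gnames, function(g)
    cfg$groups[[g]]$alpha + cfg$groups[[g]]$beta * suhiDet +
      stats::rnorm(nT, 0, cfg$shareNoiseSd))
  scores <- matrix(scores, nrow = nT)
  shares <- exp(scores - apply(scores, 1, max))
  shares <- shares / rowSums(shares)
  counts <- t(vapply(seq_len(nT), function(i)
    largestRemainder(shares[i, ], pop[i]), integer(length(gnames))))
  colnames(counts) <- gnames
  out <- data.frame(tract_id = tractIds, total = as.integer(pop))
  for (g in gnames) out[[g]] <- counts[, g]
  af <- cfg$ageFractions
  for (g in gnames) {
    ages <- t(vapply(out[[g]], function(n)
      largestRemainder(c(af[["under5"]], af[["over65"]],
                         1 - sum(af)), n)[1:2], integer(2)))
    out[[paste0(g, "_u5")]] <- ages[, 1]
    out[[paste0(g, "_o65")]] <- ages[, 2]
  }
  out
}

# Truth-side Kolm-Pollak index: direct evaluation of the weighted sum,
# deliberately independent of the log-sum-exp implementation in kpIndex().
directKP <- function(x, w, kappa) {
  W <- sum(w)
  xbar <- sum(w * x) / W
  -log(sum(w / W * exp(kappa * (xbar - x)))) / kappa
}

#' Generate one synthetic city
#'
#' With `cellLevel = TRUE` the city is fully rasterized (LST, land cover,
#' UA and tract grids) and the tract table is computed cell by cell at
#' generation time, independently of the zonal-statistics module. With
#' `cellLevel = FALSE` the same statistical model is simulated directly at
#' tract level (radial-gradient deterministic SUHI, per-tract noise scaled
#' by cell counts, and a shared rural-reference shock that induces the
#' within-city error correlation the clustered tests must absorb), which is
#' orders of magnitude faster for Monte-Carlo work.
#'
#' @param config a [syntheticConfig()].
#' @param seed integer seed (mandatory; the generator is deterministic given
#'   it and restores the caller's RNG state).
#' @param cityId integer id, used for tract/UA identifiers.
#' @param cellLevel logical; rasterize the city (see above).
#' @return a [SyntheticCity-class].
#' @export
generateCity <- function(config, seed, cityId = 1L, cellLevel = TRUE) {
  stopifnot(inherits(config, "syntheticConfig"), is.numeric(seed))
  cityId <- as.integer(cityId)
  withSeed(seed, {
    if (cellLevel) generateCityCells(config, seed, cityId)
    else generateCityTracts(config, seed, cityId)
  })
}

generateCityCells <- function(cfg, seed, cityId) {
  G <- cfg$gridSize
  c0 <- (G + 1) / 2
  d <- sqrt(outer((seq_len(G) - c0)^2, (seq_len(G) - c0)^2, "+"))
  rU <- cfg$urbanRadiusFrac * G
  rUA <- cfg$uaRadiusFrac * G

  codes <- landCoverCodes()
  lc <- matrix(codes[["NONURBAN"]], G, G)
  lc[d <= rU] <- codes[["URBAN"]]
  nWater <- round(cfg$waterFrac * G * G)
  if (nWater > 0) lc[sample(G * G, nWater)] <- codes[["WATER"]]

  ua <- matrix(NA_integer_, G, G)
  ua[d <= rUA] <- cityId

  # tracts partition the urban-core cells of the UA (water cells included:
  # they belong to a tract but are excluded from LST averaging downstream)
  core <- which(d <= rU & !is.na(ua))
  km <- stats::kmeans(cbind(row(ua)[core], col(ua)[core]),
                      centers = min(cfg$nTracts, length(core)),
                      iter.max = 50, nstart = 1)
  tract <- matrix(NA_integer_, G, G)
  tract[core] <- cityId * 1000L + km$cluster

  lstDet <- cfg$ruralBase + cfg$suhiAmplitude * exp(-(d / rU)^2)
  lstDet[lc == codes[["WATER"]]] <- cfg$ruralBase - 3
  lst <- lstDet + stats::rnorm(G * G, 0, cfg$noiseSd)
  nMiss <- round(cfg$missingRate * G * G)
  if (nMiss > 0) lst[sample(G * G, nMiss)] <- NA

  # generator-side tract statistics: plain cell loops, independent of the
  # zonal-statistics module
  refSel <- !is.na(ua) & lc == codes[["NONURBAN"]] & !is.na(lst)
  stopifnot(any(refSel))
  lstR <- mean(lst[refSel])
  refDetSel <- !is.na(ua) & lc == codes[["NONURBAN"]]
  refDet <- mean(lstDet[refDetSel])

  ids <- sort(unique(tract[!is.na(tract)]))
  rows <- lapply(ids, function(t) {
    cells <- !is.na(tract) & tract == t & lc != codes[["WATER"]]
    valid <- cells & !is.na(lst)
    if (!any(valid)) return(NULL)
    data.frame(tract_id = as.character(t), urbanized_area_id = cityId,
               suhi = mean(lst[valid]) - lstR,
               suhi_det = mean(lstDet[cells]) - refDet,
               n_cells = sum(valid))
  })
  tracts <- do.call(rbind, rows)

  demo <- synthDemographics(cfg, tracts$tract_id, tracts$suhi_det)
  tracts$population <- demo$total
  finishCity(cfg, seed, cityId,
             raster = cityRaster(lst, lc, ua, tract),
             tracts = tracts, demo = demo,
             refInfo = list(lst_r = lstR, ref_det = refDet,
                            n_ref = sum(refSel)))
}

generateCityTracts <- function(cfg, seed, cityId) {
  G <- cfg$gridSize
  rU <- cfg$urbanRadiusFrac * G
  rUA <- cfg$uaRadiusFrac * G
  nT <- cfg$nTracts
  # equal-area radial tract placement; kernel minus the annulus mean
  suhiDet <- tractDetProfile(cfg)

  keepFrac <- (1 - cfg$waterFrac) * (1 - cfg$missingRate)
  cellsPerTract <- pi * rU^2 / nT * keepFrac
  nRef <- pi * (rUA^2 - rU^2) * keepFrac
  refShock <- stats::rnorm(1, 0, cfg$noiseSd / sqrt(nRef))
  eta <- stats::rnorm(nT, 0, cfg$noiseSd / sqrt(cellsPerTract))

  tracts <- data.frame(tract_id = as.character(cityId * 1000L + seq_len(nT)),
                       urbanized_area_id = cityId,
                       suhi = suhiDet + eta - refShock,
                       suhi_det = suhiDet,
                       n_cells = round(cellsPerTract))
  demo <- synthDemographics(cfg, tracts$tract_id, tracts$suhi_det)
  tracts$population <- demo$total
  finishCity(cfg, seed, cityId, raster = NULL, tracts = tracts, demo = demo,
             refInfo = list(n_ref = nRef))
}

finishCity <- function(cfg, seed, cityId, raster, tracts, demo, refInfo) {
  gnames <- names(cfg$groups)
  truth <- list(
    groupMeanDet = vapply(gnames, function(g)
      sum(demo[[g]] * tracts$suhi_det) / sum(demo[[g]]), numeric(1)),
    groupMean = vapply(gnames, function(g)
      sum(demo[[g]] * tracts$suhi) / sum(demo[[g]]), numeric(1)),
    groupKP = vapply(gnames, function(g)
      directKP(tracts$suhi, demo[[g]], cfg$kappa), numeric(1)),
    kappa = cfg$kappa,
    ref = refInfo)
  demoTab <- demographicTable(demo, scheme = "synthetic",
                              partitions = list(total = gnames))
  new("SyntheticCity", cityId = cityId, raster = raster, tracts = tracts,
      demographics = demoTab, truth = truth, config = unclass(cfg),
      seed = as.integer(seed))
}

#' Generate a panel of synthetic cities with climate-zone labels
#'
#' Per-city seeds are derived deterministically from the master seed by a
#' counter-based scheme, so the panel is reproducible regardless of
#' generation order. Climate-zone labels are assigned round-robin.
#'
#' @inheritParams generateCity
#' @param nCities number of cities (default `config$nCities`).
#' @return a [SyntheticPanel-class].
#' @export
generatePanel <- function(config, seed, nCities = config$nCities,
                          cellLevel = TRUE) {
  stopifnot(inherits(config, "syntheticConfig"), nCities >= 1)
  cities <- lapply(seq_len(nCities), function(i)
    generateCity(config, deriveSeed(seed, i), cityId = i,
                 cellLevel = cellLevel))
  zones <- data.frame(
    urbanized_area_id = seq_len(nCities),
    zone = config$zoneLabels[(seq_len(nCities) - 1L) %%
                               length(config$zoneLabels) + 1L])
  new("SyntheticPanel", cities = cities, zones = zones,
      config = unclass(config), seed = as.integer(seed))
}

#' Combined tract-level SUHI table of a panel or city
#'
#' Returns the generator's own tract records in the schema the exposure
#' functions consume (`tract_id`, `urbanized_area_id`, `suhi`, plus
#' `suhi_det`, `n_cells`, `population`).
#'
#' @param x a [SyntheticPanel-class] or [SyntheticCity-class].
#' @return data.frame of tract records.
#' @export
panelSuhiTable <- function(x) {
  if (is(x, "SyntheticCity")) return(x@tracts)
  stopifnot(is(x, "SyntheticPanel"))
  out <- do.call(rbind, lapply(x@cities, cityTracts))
  rownames(out) <- NULL
  out
}

#' Combined demographic table of a panel
#'
#' @param x a [SyntheticPanel-class] or [SyntheticCity-class].
#' @return a [DemographicTable-class] over all tracts.
#' @export
panelDemographics <- function(x) {
  if (is(x, "SyntheticCity")) return(x@demographics)
  stopifnot(is(x, "SyntheticPanel"))
  counts <- do.call(rbind, lapply(x@cities,
                                  function(ct) demographicCounts(ct@demographics)))
  rownames(counts) <- NULL
  first <- x@cities[[1]]@demographics
  demographicTable(counts, scheme = schemeName(first),
                   partitions = first@partitions)
}

#' Ground-truth weighted-mean exposure gap (realized)
#'
#' Computes the gap in population-weighted mean SUHI between two groups
#' directly from the generator's stored tract records — the same estimand as
#' [groupMeanDifference()] but through an independent code path (plain
#' arithmetic, no join or regression).
#'
#' @param x a [SyntheticCity-class] or [SyntheticPanel-class].
#' @param groupA,groupB group names from the generator config.
#' @return numeric gap, mean(A) - mean(B), degrees C.
#' @export
truthDisparity <- function(x, groupA, groupB) {
  truthGap(x, groupA, groupB, column = "suhi")
}

#' Ground-truth expected exposure gap (noise-free)
#'
#' As [truthDisparity()] but on the deterministic SUHI component, i.e. the
#' gap an estimator would recover with noise-free temperature data. This is
#' the estimand used for bias and coverage checks of the clustered
#' difference-in-means test.
#'
#' @inheritParams truthDisparity
#' @return numeric gap, degrees C.
#' @export
truthExpectedGap <- function(x, groupA, groupB) {
  truthGap(x, groupA, groupB, column = "suhi_det")
}

#' Analytic super-population exposure gap of the generating model
#'
#' For the tract-level generating model (deterministic radial SUHI profile,
#' iid lognormal tract populations, two-group logit shares with iid logit
#' noise), computes the gap in group-weighted mean SUHI that the estimator
#' converges to as the number of cities grows: tract populations and the
#' share noise integrate out, leaving
#' \deqn{\Delta = \frac{\sum_t \bar p_t s_t}{\sum_t \bar p_t}
#'             - \frac{\sum_t (1-\bar p_t) s_t}{\sum_t (1-\bar p_t)}}
#' with \eqn{\bar p_t = E[\mathrm{logit}^{-1}(\Delta\alpha + \Delta\beta
#' s_t + u)]}, \eqn{u \sim N(0, 2\sigma_\epsilon^2)}, evaluated by numeric
#' integration. This is the fixed truth against which bias and confidence
#' interval coverage of the clustered difference-in-means estimator are
#' judged. Exposure noise has mean zero and drops out.
#'
#' @param config a two-group [syntheticConfig()].
#' @param groupA,groupB the two group names; gap is mean(A) - mean(B).
#' @return numeric gap in degrees C.
#' @export
populationGap <- function(config, groupA, groupB) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (length(config$groups) != 2L)
    stop("analytic gap implemented for two-group configurations")
  stopifnot(all(c(groupA, groupB) %in% names(config$groups)))
  s <- tractDetProfile(config)
  dA <- config$groups[[groupA]]$alpha - config$groups[[groupB]]$alpha
  dB <- config$groups[[groupA]]$beta - config$groups[[groupB]]$beta
  sdU <- sqrt(2) * config$shareNoiseSd
  pbar <- vapply(s, function(st) {
    if (sdU == 0) return(stats::plogis(dA + dB * st))
    stats::integrate(function(u) stats::plogis(dA + dB * st + u) *
                       stats::dnorm(u, 0, sdU),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  sum(pbar * s) / sum(pbar) - sum((1 - pbar) * s) / sum(1 - pbar)
}

# Deterministic tract-level SUHI profile shared by the tract-level generator
# and the analytic truth.
tractDetProfile <- function(cfg) {
  G <- cfg$gridSize
  rU <- cfg$urbanRadiusFrac * G
  rUA <- cfg$uaRadiusFrac * G
  rT <- rU * sqrt((seq_len(cfg$nTracts) - 0.5) / cfg$nTracts)
  kernel <- cfg$suhiAmplitude * exp(-(rT / rU)^2)
  refDet <- cfg$suhiAmplitude * rU^2 *
    (exp(-(rU / rU)^2) - exp(-(rUA / rU)^2)) / (rUA^2 - rU^2)
  kernel - refDet
}

truthGap <- function(x, groupA, groupB, column) {
  cities <- if (is(x, "SyntheticPanel")) x@cities else list(x)
  num <- c(0, 0); den <- c(0, 0)
  for (ct in cities) {
    tr <- ct@tracts
    dm <- demographicCounts(ct@demographics)
    stopifnot(identical(tr$tract_id, dm$tract_id))
    for (k in 1:2) {
      g <- c(groupA, groupB)[k]
      if (!g %in% names(dm)) stop("unknown group: ", g)
      num[k] <- num[k] + sum(dm[[g]] * tr[[column]])
      den[k] <- den[k] + sum(dm[[g]])
    }
  }
  num[1] / den[1] - num[2] / den[2]
}

#' Write a synthetic city as a pipeline-consumable bundle
#'
#' Emits the exact formats the pipeline reads: the four ASCII grids (for
#' raster cities), `demographics.csv` and `zones.csv`.
#'
#' @param city a [SyntheticCity-class] generated with `cellLevel = TRUE`.
#' @param dir output directory.
#' @param zone climate-zone label recorded for the city.
#' @return `dir`, invisibly.
#' @export
writeCityBundle <- function(city, dir, zone = "temperate") {
  stopifnot(is(city, "SyntheticCity"))
  if (is.null(city@raster))
    stop("city was generated without a raster (cellLevel = FALSE)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeCityRaster(city@raster, dir)
  writeDemographics(city@demographics, file.path(dir, "demographics.csv"))
  utils::write.csv(data.frame(urbanized_area_id = city@cityId, zone = zone),
                   file.path(dir, "zones.csv"), row.names = FALSE)
  invisible(dir)
}
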