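# Population-weighted exposure summaries and inference. The estimand
# throughout is the mean SUHI intensity experienced by the average member of
# a group: every resident of a tract is assigned the tract's SUHI, so group
# means are weighted means over tracts with person counts as weights.

# Join a SUHI table to a demographic table on tract_id; unmatched ids on
# either side are logged and excluded from both.
joinSuhiDemo <- function(suhi, demo, quiet = FALSE) {
  counts <- demographicCounts(demo)
  common <- intersect(suhi$tract_id, counts$tract_id)
  lostS <- setdiff(suhi$tract_id, common)
  lostD <- setdiff(counts$tract_id, common)
  if (!quiet && (length(lostS) || length(lostD)))
    message(sprintf(
      "tract join: %d SUHI and %d demographic tract(s) unmatched, excluded",
      length(lostS), length(lostD)))
  m <- merge(suhi, counts, by = "tract_id")
  attr(m, "unmatched_suhi") <- lostS
  attr(m, "unmatched_demo") <- lostD
  m
}

# Restrict a joined table to one scope unit. zones maps urbanized_area_id to
# climate zone; scope is "national", "zone" or "city".
scopeUnits <- function(joined, scope, zones = NULL) {
  scope <- match.arg(scope, c("national", "zone", "city"))
  if (scope == "national")
    return(list(national = joined))
  if (scope == "city")
    return(split(joined, joined$urbanized_area_id))
  if (is.null(zones)) stop("zone scope requires a zones table")
  z <- zones$zone[match(joined$urbanized_area_id, zones$urbanized_area_id)]
  if (anyNA(z)) stop("unlabeled urbanized area(s) in zone scope")
  split(joined, z)
}

#' Population-weighted group mean and SD of SUHI exposure
#'
#' Computes, at the requested scope, the weighted mean
#' \eqn{\sum_t w_t x_t / \sum_t w_t} of tract SUHI \eqn{x_t} with weights
#' \eqn{w_t} equal to the group's person count in tract \eqn{t}, and the
#' population-form weighted standard deviation. Tracts where the group count
#' is zero contribute zero weight (not dropped).
#'
#' @param suhi data.frame of tract SUHI records (from [computeCitySuhi()] or
#'   [panelSuhiTable()]).
#' @param demo a [DemographicTable-class].
#' @param group group column name in `demo`.
#' @param scope `"national"`, `"zone"` or `"city"`.
#' @param zones data.frame (`urbanized_area_id`, `zone`), required for zone
#'   scope.
#' @return data.frame with one row per scope unit: `scope`, `unit`, `group`,
#'   `weighted_mean`, `weighted_sd`, `total_weight`, `n_tracts`.
#' @export
weightedGroupMean <- function(suhi, demo, group, scope = "national",
                              zones = NULL) {
  joined <- joinSuhiDemo(suhi, demo, quiet = TRUE)
  if (!group %in% names(joined)) stop("unknown group: ", group)
  units <- scopeUnits(joined, scope, zones)
  rows <- lapply(names(units), function(u) {
    d <- units[[u]]
    w <- d[[group]]
    W <- sum(w)
    if (W <= 0)
      stop(sprintf("empty group '%s' at %s scope '%s'", group, scope, u))
    data.frame(scope = scope, unit = u, group = group,
               weighted_mean = sum(w * d$suhi) / W,
               weighted_sd = weightedSD(d$suhi, w),
               total_weight = W, n_tracts = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Core weighted difference-in-means via WLS on stacked (tract x group)
# observations; vcovFun returns the variance matrix of the fit. The slope on
# the group-A indicator equals mean(A) - mean(B) exactly.
wlsDifference <- function(d, groupA, groupB, vcovFun, df) {
  stacked <- rbind(
    data.frame(suhi = d$suhi, g = 1, w = d[[groupA]],
               cluster = d$urbanized_area_id),
    data.frame(suhi = d$suhi, g = 0, w = d[[groupB]],
               cluster = d$urbanized_area_id))
  stacked <- stacked[stacked$w > 0, ]
  fit <- stats::lm(suhi ~ g, data = stacked, weights = w)
  V <- vcovFun(fit, stacked)
  est <- unname(stats::coef(fit)["g"])
  se <- sqrt(V["g", "g"])
  if (abs(est) < 1e-12) {
    # numerically zero gap is never evidence of a difference
    tval <- 0
    p <- 1
    if (!is.finite(se)) se <- 0
  } else if (!is.finite(se) || se <= 0) {
    # perfect fit (zero residuals): the gap is measured without error
    se <- 0
    tval <- sign(est) * Inf
    p <- 0
  } else {
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df = df)
  }
  list(diff = est, se = se, t = tval, df = df, p_value = p)
}

#' Weighted difference in group means with cluster-robust inference
#'
#' Estimates the gap in population-weighted mean SUHI between two groups by
#' weighted least squares on stacked (tract x group) observations of SUHI on
#' a group indicator, weights equal to group person counts. Standard errors
#' are cluster-robust (CR1 sandwich) by urbanized area, with a t reference
#' distribution on G - 1 degrees of freedom (G = number of urbanized areas in
#' the scope unit). With a single cluster the function falls back to
#' heteroskedasticity-robust (HC1) standard errors with a warning. Stars:
#' `*` p < 0.10, `**` p < 0.05, `***` p < 0.01.
#'
#' @inheritParams weightedGroupMean
#' @param groupA,groupB group column names; the reported difference is
#'   mean(A) - mean(B).
#' @return data.frame, one row per scope unit: `scope`, `unit`, `group_a`,
#'   `group_b`, `diff`, `se`, `df`, `t`, `p_value`, `stars`, `n_clusters`.
#' @export
groupMeanDifference <- function(suhi, demo, groupA, groupB,
                                scope = "national", zones = NULL) {
  joined <- joinSuhiDemo(suhi, demo, quiet = TRUE)
  for (g in c(groupA, groupB))
    if (!g %in% names(joined)) stop("unknown group: ", g)
  units <- scopeUnits(joined, scope, zones)
  rows <- lapply(names(units), function(u) {
    d <- units[[u]]
    G <- length(unique(d$urbanized_area_id))
    if (G >= 2) {
      res <- wlsDifference(d, groupA, groupB,
        vcovFun = function(fit, st)
          sandwich::vcovCL(fit, cluster = st$cluster, type = "HC1"),
        df = G - 1)
    } else {
      warning("single cluster at ", scope, " scope '", u,
              "': using heteroskedasticity-robust SE")
      res <- wlsDifference(d, groupA, groupB,
        vcovFun = function(fit, st) sandwich::vcovHC(fit, type = "HC1"),
        df = sum(d[[groupA]] > 0) + sum(d[[groupB]] > 0) - 2)
    }
    data.frame(scope = scope, unit = u, group_a = groupA, group_b = groupB,
               diff = res$diff, se = res$se, df = res$df, t = res$t,
               p_value = res$p_value, stars = starsFromP(res$p_value),
               n_clusters = G)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-city group means
#'
#' Convenience wrapper returning one population-weighted mean per city for a
#' group, skipping cities where the group is absent (the inputs to
#' [citiesAboveThreshold()] and [exposureDensity()]).
#'
#' @inheritParams weightedGroupMean
#' @return data.frame: `urbanized_area_id`, `weighted_mean`, `total_weight`,
#'   `n_tracts`.
#' @export
cityGroupMeans <- function(suhi, demo, group) {
  joined <- joinSuhiDemo(suhi, demo, quiet = TRUE)
  if (!group %in% names(joined)) stop("unknown group: ", group)
  units <- split(joined, joined$urbanized_area_id)
  rows <- lapply(names(units), function(u) {
    d <- units[[u]]
    W <- sum(d[[group]])
    if (W <= 0) return(NULL)
    data.frame(urbanized_area_id = u,
               weighted_mean = sum(d[[group]] * d$suhi) / W,
               total_weight = W, n_tracts = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-city difference-in-means tests
#'
#' Within one city the tracts are the sampling units and no clustering is
#' possible, so each city's weighted gap uses heteroskedasticity-robust
#' (HC1) standard errors; significance is flagged at p < 0.05. Cities where
#' either group is entirely absent are marked not comparable.
#'
#' @inheritParams groupMeanDifference
#' @param cities optional subset of urbanized-area ids.
#' @return data.frame, one row per city: `urbanized_area_id`, `diff`, `se`,
#'   `p_value`, `significant`, `comparable`.
#' @export
cityLevelTest <- function(suhi, demo, groupA, groupB, cities = NULL) {
  joined <- joinSuhiDemo(suhi, demo, quiet = TRUE)
  units <- split(joined, joined$urbanized_area_id)
  if (!is.null(cities)) units <- units[as.character(cities)]
  rows <- lapply(names(units), function(u) {
    d <- units[[u]]
    if (sum(d[[groupA]]) <= 0 || sum(d[[groupB]]) <= 0)
      return(data.frame(urbanized_area_id = u, diff = NA_real_,
                        se = NA_real_, p_value = NA_real_,
                        significant = NA, comparable = FALSE))
    n <- sum(d[[groupA]] > 0) + sum(d[[groupB]] > 0)
    res <- wlsDifference(d, groupA, groupB,
      vcovFun = function(fit, st) sandwich::vcovHC(fit, type = "HC1"),
      df = max(n - 2, 1))
    data.frame(urbanized_area_id = u, diff = res$diff, se = res$se,
               p_value = res$p_value,
               significant = is.finite(res$p_value) && res$p_value < 0.05,
               comparable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally per-city comparisons overall and by climate zone
#'
#' Counts and proportions of comparable cities in which group A has the
#' higher mean exposure (diff > 0), the significant subsets (p < 0.05 each
#' way), overall and by climate zone. Non-comparable cities are excluded
#' from denominators.
#'
#' @param tests output of [cityLevelTest()].
#' @param zones optional data.frame (`urbanized_area_id`, `zone`).
#' @return data.frame with one row per zone plus `"total"`: `zone`,
#'   `n_cities`, `n_comparable`, `prop_a_worse`, `prop_a_worse_sig`,
#'   `prop_b_worse`, `prop_b_worse_sig`.
#' @export
tallyCityComparisons <- function(tests, zones = NULL) {
  if (!any(tests$comparable)) stop("no comparable city to tally")
  z <- if (is.null(zones)) rep("all", nrow(tests)) else
    zones$zone[match(tests$urbanized_area_id, zones$urbanized_area_id)]
  tallyOne <- function(d, label) {
    cc <- d[d$comparable, ]
    n <- nrow(cc)
    data.frame(zone = label, n_cities = nrow(d), n_comparable = n,
               prop_a_worse = mean(cc$diff > 0),
               prop_a_worse_sig = mean(cc$diff > 0 & cc$significant),
               prop_b_worse = mean(cc$diff < 0),
               prop_b_worse_sig = mean(cc$diff < 0 & cc$significant))
  }
  parts <- lapply(sort(unique(z)), function(zz) tallyOne(tests[z == zz, ], zz))
  out <- rbind(do.call(rbind, parts), tallyOne(tests, "total"))
  rownames(out) <- NULL
  out
}

#' Count cities whose group mean exceeds a threshold
#'
#' Strict inequality: ties count as not above.
#'
#' @param means numeric vector of per-city group means (degrees C).
#' @param threshold threshold in degrees C (default 2).
#' @return integer count.
#' @export
citiesAboveThreshold <- function(means, threshold = 2) {
  sum(means > threshold)
}

#' Kernel density of city-level group means
#'
#' Gaussian-kernel density of per-city means (Silverman's rule-of-thumb
#' bandwidth by default), evaluated on a 512-point grid spanning the data
#' range plus three bandwidths on either side, with the area under the curve
#' scaled to `nCities` so curves for different groups are comparable as
#' city counts.
#'
#' @param means numeric vector of per-city means.
#' @param nCities area under the scaled curve (default `length(means)`).
#' @param bw bandwidth rule or numeric bandwidth, passed to
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @param cut grid extension beyond the data range, in bandwidths
#'   (default 3).
#' @return data.frame (`x`, `density`, `scaled`) with attributes `bw` and
#'   `n_cities`.
#' @export
exposureDensity <- function(means, nCities = length(means), bw = "nrd0",
                            cut = 3) {
  if (length(means) < 2) stop("need at least two city means")
  if (stats::sd(means) == 0) {
    warning("all city means identical: density degenerates to a spike")
    bw <- max(abs(means[1]) * 1e-8, 1e-8)
  }
  den <- stats::density(means, bw = bw, kernel = "gaussian", n = 512,
                        cut = cut)
  out <- data.frame(x = den$x, density = den$y, scaled = den$y * nCities)
  attr(out, "bw") <- den$bw
  attr(out, "n_cities") <- nCities
  out
}
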