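# Kolm-Pollak inequality index and equally distributed equivalent (EDE) for
# weighted exposure distributions of a "bad" (here SUHI intensity in degrees
# C). For exposures x_n with person weights w_n, total W and weighted mean
# xbar, the index with inequality-aversion parameter kappa < 0 (units 1/C) is
#
#   I(x) = -(1/kappa) * log( sum_n (w_n / W) * exp(kappa * (xbar - x_n)) )
#
# the weighted generalization of the equal-weight form (every individual in
# a tract shares that tract's exposure, so w_n/W replaces 1/N). The EDE is
# xbar + I(x): the uniform exposure an impartial agent would accept in place
# of the unequal distribution. I(x) >= 0 with equality iff all exposures
# carrying weight are equal; larger |kappa| penalizes above-mean exposures
# more strongly and increases the index.

#' Kolm-Pollak inequality index and EDE
#'
#' Evaluates the weighted Kolm-Pollak index via a max-shifted log-sum-exp,
#' so exposures spanning many orders of magnitude neither overflow nor lose
#' the result to cancellation. The index is an absolute (translation
#' invariant) inequality measure in the same units as the exposures.
#'
#' @param x numeric vector of exposures (degrees C), one per tract or
#'   individual.
#' @param weights nonnegative person weights, recycled to `length(x)`;
#'   default equal weights.
#' @param kappa inequality-aversion parameter, must be negative (units
#'   1/degree C so `kappa * (xbar - x)` is dimensionless).
#' @return one-row data.frame: `kappa`, `index` (>= 0, degrees C), `ede`
#'   (`mean + index`), `mean`, `total_weight`, `n`.
#' @seealso [kpSweep()], [groupCityIndices()]
#' @export
#' @examples
#' kpIndex(c(1, 3), kappa = -1)      # index = log(cosh(1)) ~ 0.4338
#' kpIndex(c(2, 2, 2), kappa = -0.5) # perfectly equal: index = 0
kpIndex <- function(x, weights = NULL, kappa = -0.5) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa >= 0)
    stop("kappa must be a single negative number (inequality aversion)")
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- rep_len(weights, length(x))
  if (any(weights < 0)) stop("weights must be nonnegative")
  keep <- weights > 0
  x <- x[keep]; weights <- weights[keep]
  W <- sum(weights)
  if (length(x) == 0L || W <= 0) stop("empty distribution: total weight is 0")
  xbar <- sum(weights * x) / W
  if (all(x == x[1]))
    return(data.frame(kappa = kappa, index = 0, ede = xbar, mean = xbar,
                      total_weight = W, n = length(x)))
  lse <- logSumExp(log(weights / W) + kappa * (xbar - x))
  idx <- -lse / kappa
  # Jensen guarantees idx >= 0; clamp roundoff-scale negatives to zero.
  if (idx < 0 && idx > -1e-12 * max(1, abs(xbar))) idx <- 0
  data.frame(kappa = kappa, index = idx, ede = xbar + idx, mean = xbar,
             total_weight = W, n = length(x))
}

#' Kolm-Pollak index over a sweep of aversion parameters
#'
#' @inheritParams kpIndex
#' @param kappas numeric vector of negative aversion parameters.
#' @return data.frame with one [kpIndex()] row per kappa. The index is
#'   nondecreasing in `|kappa|`.
#' @export
kpSweep <- function(x, weights = NULL, kappas = c(-0.25, -0.5, -1)) {
  out <- do.call(rbind, lapply(kappas, function(k)
    kpIndex(x, weights = weights, kappa = k)))
  rownames(out) <- NULL
  out
}

#' Per-city Kolm-Pollak indices for a demographic group
#'
#' For each urbanized area, treats the group's tract-level exposure
#' distribution (weights = group person counts) as the lottery faced by the
#' average group member and computes its Kolm-Pollak index and EDE. Cities
#' where the group is absent are excluded and logged.
#'
#' @inheritParams weightedGroupMean
#' @param kappa negative aversion parameter.
#' @return data.frame, one row per city: `urbanized_area_id`, `group`,
#'   `kappa`, `index`, `ede`, `mean`, `total_weight`, `n_tracts`.
#' @export
groupCityIndices <- function(suhi, demo, group, kappa = -0.5) {
  joined <- joinSuhiDemo(suhi, demo, quiet = TRUE)
  if (!group %in% names(joined)) stop("unknown group: ", group)
  units <- split(joined, joined$urbanized_area_id)
  rows <- lapply(names(units), function(u) {
    d <- units[[u]]
    if (sum(d[[group]]) <= 0) {
      message("group '", group, "' absent from urbanized area ", u,
              ": excluded")
      return(NULL)
    }
    r <- kpIndex(d$suhi, weights = d[[group]], kappa = kappa)
    data.frame(urbanized_area_id = u, group = group, kappa = kappa,
               index = r$index, ede = r$ede, mean = r$mean,
               total_weight = r$total_weight, n_tracts = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-weighted summary of per-city indices
#'
#' Aggregates city-level Kolm-Pollak indices to zone and national scope as
#' weighted means (and population-form SDs), weighting each city by the
#' group's city population.
#'
#' @param perCity output of [groupCityIndices()].
#' @param zones optional data.frame (`urbanized_area_id`, `zone`).
#' @return data.frame, one row per zone plus `"total"`: `unit`, `group`,
#'   `kappa`, `index_mean`, `index_sd`, `total_weight`, `n_cities`.
#' @export
kpSummary <- function(perCity, zones = NULL) {
  z <- if (is.null(zones)) rep("total", nrow(perCity)) else
    zones$zone[match(perCity$urbanized_area_id, zones$urbanized_area_id)]
  summarise <- function(d, label) {
    W <- sum(d$total_weight)
    data.frame(unit = label, group = d$group[1], kappa = d$kappa[1],
               index_mean = sum(d$total_weight * d$index) / W,
               index_sd = weightedSD(d$index, d$total_weight),
               total_weight = W, n_cities = nrow(d))
  }
  parts <- lapply(sort(unique(z)), function(zz) summarise(perCity[z == zz, ], zz))
  out <- do.call(rbind, parts)
  if (!is.null(zones)) out <- rbind(out, summarise(perCity, "total"))
  rownames(out) <- NULL
  out
}

#' Difference in mean city indices between two groups
#'
#' Tests whether the population-weighted mean of city-level Kolm-Pollak
#' indices differs between two groups, by weighted least squares of the
#' stacked per-city indices on a group indicator (weights = the group's city
#' population) with heteroskedasticity-robust (HC1) standard errors over
#' cities. Requires at least two cities carrying both groups.
#'
#' @param perCityA,perCityB outputs of [groupCityIndices()] for the two
#'   groups (matched on `urbanized_area_id`).
#' @return one-row data.frame: `group_a`, `group_b`, `kappa`, `diff`, `se`,
#'   `df`, `t`, `p_value`, `stars`, `n_cities`.
#' @export
indexDifference <- function(perCityA, perCityB) {
  common <- intersect(perCityA$urbanized_area_id, perCityB$urbanized_area_id)
  if (length(common) < 2)
    stop("no inference possible: fewer than two cities carry both groups")
  a <- perCityA[match(common, perCityA$urbanized_area_id), ]
  b <- perCityB[match(common, perCityB$urbanized_area_id), ]
  stacked <- rbind(
    data.frame(y = a$index, g = 1, w = a$total_weight),
    data.frame(y = b$index, g = 0, w = b$total_weight))
  fit <- stats::lm(y ~ g, data = stacked, weights = w)
  V <- sandwich::vcovHC(fit, type = "HC1")
  est <- unname(stats::coef(fit)["g"])
  se <- sqrt(V["g", "g"])
  df <- nrow(stacked) - 2
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  data.frame(group_a = a$group[1], group_b = b$group[1], kappa = a$kappa[1],
             diff = est, se = se, df = df, t = tval, p_value = p,
             stars = starsFromP(p), n_cities = length(common))
}
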