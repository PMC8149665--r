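# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized/stacked-regression code paths.

# Cell-by-cell double-loop SUHI: recomputes every rural reference and tract
# mean with explicit loops over all grid cells.
oracleSuhi <- function(x, includeWater = FALSE) {
  lst <- lstGrid(x); lc <- landCoverGrid(x)
  ua <- uaGrid(x); tract <- tractGrid(x)
  nr <- nrow(lst); nc <- ncol(lst)
  out <- NULL
  for (u in sort(unique(ua[!is.na(ua)]))) {
    rsum <- 0; rn <- 0L
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!is.na(ua[i, j]) && ua[i, j] == u && lc[i, j] == 2L &&
          !is.na(lst[i, j])) {
        rsum <- rsum + lst[i, j]; rn <- rn + 1L
      }
    }
    if (rn == 0L) next
    lstR <- rsum / rn
    tractsHere <- integer(0)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!is.na(ua[i, j]) && ua[i, j] == u && !is.na(tract[i, j]))
        tractsHere <- union(tractsHere, tract[i, j])
    }
    for (t in sort(tractsHere)) {
      tsum <- 0; tn <- 0L
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        okWater <- includeWater || lc[i, j] != 3L
        if (!is.na(tract[i, j]) && tract[i, j] == t &&
            !is.na(ua[i, j]) && ua[i, j] == u &&
            !is.na(lst[i, j]) && okWater) {
          tsum <- tsum + lst[i, j]; tn <- tn + 1L
        }
      }
      if (tn == 0L) next
      out <- rbind(out, data.frame(
        tract_id = as.character(t), urbanized_area_id = as.integer(u),
        lst_t = tsum / tn, lst_r = lstR, suhi = tsum / tn - lstR,
        n_cells = tn))
    }
  }
  out
}

# Random valid CityRaster with 1-2 urbanized areas, missing LST cells and
# all three land cover classes.
randomCityRaster <- function(seed, nr = 20, nc = 20, nUa = 2, tractsPerUa = 4) {
  set.seed(seed)
  lc <- matrix(sample(1:3, nr * nc, replace = TRUE, prob = c(.4, .5, .1)),
               nr, nc)
  lst <- matrix(round(rnorm(nr * nc, 28, 3), 3), nr, nc)
  lst[sample(nr * nc, round(0.05 * nr * nc))] <- NA
  ua <- matrix(NA_integer_, nr, nc)
  half <- floor(nc / nUa)
  for (u in seq_len(nUa)) {
    cols <- ((u - 1) * half + 1):(if (u == nUa) nc else u * half)
    ua[, cols] <- ifelse(matrix(runif(nr * length(cols)) < .8, nr), u, NA)
  }
  tract <- matrix(NA_integer_, nr, nc)
  for (u in seq_len(nUa)) {
    cells <- which(!is.na(ua) & ua == u)
    if (!length(cells)) next
    tract[cells] <- u * 100L + sample.int(tractsPerUa, length(cells),
                                          replace = TRUE)
  }
  cityRaster(lst, lc, ua, tract)
}

# Hand-coded CR1 cluster sandwich for WLS of y on an intercept and a single
# regressor g with weights w: bread (X'WX)^-1, meat from cluster-summed
# scores w*e*x, scale G/(G-1)*(N-1)/(N-K).
oracleClusteredSE <- function(y, g, w, cluster) {
  X <- cbind(1, g)
  WX <- X * w
  bread <- solve(t(X) %*% WX)
  beta <- bread %*% (t(WX) %*% y)
  e <- y - X %*% beta
  S <- X * as.vector(w * e)
  Sg <- rowsum(S, cluster)
  G <- nrow(Sg); N <- length(y); K <- 2
  V <- G / (G - 1) * (N - 1) / (N - K) * bread %*% crossprod(Sg) %*% bread
  list(diff = beta[2], se = sqrt(V[2, 2]))
}

# Hand-coded HC1 sandwich for the same model (each row its own "cluster",
# scale N/(N-K)).
oracleRobustSE <- function(y, g, w) {
  X <- cbind(1, g)
  WX <- X * w
  bread <- solve(t(X) %*% WX)
  beta <- bread %*% (t(WX) %*% y)
  e <- y - X %*% beta
  S <- X * as.vector(w * e)
  N <- length(y); K <- 2
  V <- N / (N - K) * bread %*% crossprod(S) %*% bread
  list(diff = beta[2], se = sqrt(V[2, 2]))
}

# Direct weighted difference in group means from a suhi table + demographic
# data.frame (no merge/regression machinery).
oracleWeightedDiff <- function(suhi, counts, groupA, groupB) {
  idx <- match(suhi$tract_id, counts$tract_id)
  wa <- counts[[groupA]][idx]; wb <- counts[[groupB]][idx]
  sum(wa * suhi$suhi) / sum(wa) - sum(wb * suhi$suhi) / sum(wb)
}

# Trapezoid integral of a density curve.
trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Direct (non-log-sum-exp) Kolm-Pollak evaluation.
oracleKP <- function(x, w, kappa) {
  W <- sum(w)
  xbar <- sum(w * x) / W
  -log(sum(w / W * exp(kappa * (xbar - x)))) / kappa
}
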