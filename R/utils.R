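# Internal numeric helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' Computes log(sum(exp(x))) with the usual max-shift so that terms spanning
#' hundreds of log-units neither overflow nor underflow to -Inf.
#'
#' @param x numeric vector of log-scale terms (may contain -Inf).
#' @return scalar log(sum(exp(x))).
#' @keywords internal
#' @noRd
logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Population-form weighted standard deviation: sqrt(sum w (x - m)^2 / sum w).
weightedSD <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  sqrt(sum(w * (x - m)^2) / W)
}

#' Largest-remainder apportionment
#'
#' Rounds `shares * total` to nonnegative integers that sum exactly to
#' `total`: each entry gets its floor, and the remaining units go to the
#' entries with the largest fractional parts (ties broken by index order).
#'
#' @param shares nonnegative numeric vector; normalised internally.
#' @param total nonnegative integer to apportion.
#' @return integer vector, same length as `shares`, summing to `total`.
#' @keywords internal
#' @noRd
largestRemainder <- function(shares, total) {
  stopifnot(all(shares >= 0), total >= 0)
  total <- as.integer(round(total))
  if (sum(shares) == 0) shares <- rep(1, length(shares))
  q <- shares / sum(shares) * total
  fl <- floor(q)
  rem <- total - sum(fl)
  if (rem > 0L) {
    ord <- order(q - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# Significance stars at the thresholds used throughout the exposure tables:
# * p < 0.10, ** p < 0.05, *** p < 0.01.
starsFromP <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.01) "***" else if (pi < 0.05) "**" else if (pi < 0.10) "*" else ""
  }, character(1))
}

# Deterministic derivation of a per-city seed from a master seed, keeping the
# result a valid 32-bit integer. Counter-based so it is independent of the
# order in which cities are generated.
deriveSeed <- function(masterSeed, counter) {
  v <- (as.numeric(masterSeed) %% 2147483647) * 48271 + counter * 16807
  as.integer(v %% 2147483646) + 1L
}
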