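#' @include AllClasses.R
NULL

#' Wilson score interval for a binomial proportion
#'
#' The confidence interval obtained by inverting the score test: with
#' `z` the standard normal quantile,
#' `(phat + z^2/2n +/- z * sqrt(phat(1-phat)/n + z^2/4n^2)) / (1 + z^2/n)`,
#' clamped to `[0, 1]`. Unlike the Wald interval it behaves sensibly at 0
#' and n successes.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials, `n >= 1`.
#' @param confidence Confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' wilsonInterval(71, 93)
wilsonInterval <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    sdStop("need 0 <= successes <= n and n >= 1", "scatdiet_config_error")
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Exact and normal-approximation Wilcoxon signed-rank test
#'
#' Two-sided paired test. Zero differences are removed (if all are zero the
#' statistic is 0 and p = 1, with a warning); ties in the absolute
#' differences get midranks. The statistic `V` is the sum of ranks of the
#' positive differences. Exact mode computes the null distribution of `V`
#' over all `2^m` sign assignments (by convolution over the doubled,
#' integer-valued ranks) and reports
#' `p = P(|V - mu| >= |v_obs - mu|)` with `mu = m(m+1)/4`, which equals
#' full enumeration. Normal mode uses the tie-corrected variance
#' `sum(r_i^2)/4` with a 0.5 continuity correction toward the mean.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"exact"` or `"normal"`.
#' @return List with `statistic` (V), `z` (normal mode, else NA), `n`
#'   (pairs after zero removal), `p` and `mode`.
#' @export
wilcoxonSignedRank <- function(x, y, mode = c("exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    sdStop("paired vectors must have equal length", "scatdiet_config_error")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all differences are zero")
    return(list(statistic = 0, z = NA_real_, n = 0L, p = 1, mode = mode))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (mode == "exact") {
    R2 <- as.integer(round(2 * r))
    # distribution of 2V by convolution over sign assignments
    f <- c(1, rep(0, sum(R2)))
    for (ri in R2) {
      g <- f
      g[(ri + 1):length(f)] <- g[(ri + 1):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    w2 <- 2 * V
    mu2 <- sum(R2) / 2
    dev <- abs(w2 - mu2)
    sup <- seq_along(f) - 1
    p <- sum(f[abs(sup - mu2) >= dev - 1e-9]) / 2^m
    list(statistic = V, z = NA_real_, n = m, p = min(1, p), mode = mode)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- if (V == mu) 0 else (V - mu - 0.5 * sign(V - mu)) / sigma
    list(statistic = V, z = z, n = m, p = min(1, 2 * pnorm(-abs(z))),
         mode = mode)
  }
}

logProbTable <- function(cells, logK) {
  logK - sum(lfactorial(cells))
}

#' Exact Fisher test for an r x c contingency table
#'
#' Conditional on the margins, enumerates every table and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (relative tie tolerance 1e-12), giving the exact two-sided
#' p-value. Enumeration is pruned by the margin bounds; when the table
#' space exceeds `maxTables` an explicit resource error advises Monte
#' Carlo mode, which samples tables with [stats::r2dtable].
#'
#' @param tab Non-negative integer matrix with positive margins.
#' @param mode `"exact"` or `"montecarlo"`.
#' @param maxTables Enumeration budget for exact mode.
#' @param nSim Number of sampled tables in Monte Carlo mode.
#' @param seed Seed for Monte Carlo mode.
#' @return List with `p`, `mode` and `nTables` (enumerated or sampled).
#' @export
#' @examples
#' fisherExactRxC(matrix(c(3, 1, 1, 3), 2))$p
fisherExactRxC <- function(tab, mode = c("exact", "montecarlo"),
                           maxTables = 5e6, nSim = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    sdStop("table must contain non-negative integers",
           "scatdiet_config_error")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    sdStop("all margins must be positive", "scatdiet_config_error")
  N <- sum(tab)
  logK <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logObs <- logProbTable(as.vector(tab), logK)
  tol <- 1e-12
  if (mode == "montecarlo") {
    hit <- withSeed(seed, {
      sims <- stats::r2dtable(nSim, rs, cs)
      sum(vapply(sims, function(tt)
        logProbTable(as.vector(tt), logK) <= logObs + tol, logical(1)))
    })
    return(list(p = (hit + 1) / (nSim + 1), mode = mode, nTables = nSim))
  }
  nr <- length(rs); nc <- length(cs)
  env <- new.env()
  env$p <- 0
  env$count <- 0
  recurseRow <- function(rowIdx, colRemaining, logAcc) {
    if (rowIdx == nr) {
      # last row fully determined by the column remainders
      env$count <- env$count + 1
      if (env$count > maxTables)
        sdStop(sprintf(
          "more than %g tables to enumerate; use mode = 'montecarlo'",
          maxTables), "scatdiet_resource_error")
      lp <- logAcc - sum(lfactorial(colRemaining))
      if (lp <= logObs + tol) env$p <- env$p + exp(lp)
      return(invisible())
    }
    rTot <- rs[rowIdx]
    cells <- integer(nc)
    fillCol <- function(colIdx, left) {
      if (colIdx == nc) {
        if (left > colRemaining[nc]) return(invisible())
        cells[nc] <<- left
        recurseRow(rowIdx + 1L, colRemaining - cells,
                   logAcc - sum(lfactorial(cells)))
        return(invisible())
      }
      # upper bound: column remainder; lower bound: what later columns
      # cannot absorb
      lo <- max(0L, left - sum(colRemaining[(colIdx + 1L):nc]))
      hi <- min(left, colRemaining[colIdx])
      if (lo > hi) return(invisible())
      for (v in lo:hi) {
        cells[colIdx] <<- v
        fillCol(colIdx + 1L, left - v)
      }
      invisible()
    }
    fillCol(1L, rTot)
  }
  recurseRow(1L, cs, logK)
  list(p = min(1, env$p), mode = mode, nTables = env$count)
}
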