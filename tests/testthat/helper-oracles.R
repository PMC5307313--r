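# Independent brute-force oracles used to pin expected values.
# These deliberately re-derive results by a different route than the
# package implementation (full scans, naive DP, full enumeration, adist).

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

mutateSeq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  at <- sample(length(v), k)
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

rcSeq <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exhaustive-offset merge oracle: max score, ties -> larger overlap, then
# leftmost offset; consensus takes mate1's base at disagreements (all-equal
# qualities assumed)
oracleMerge <- function(a, b, minOverlap = 10L) {
  L1 <- nchar(a); L2 <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, ov = -1L, d = 0L)
  for (d in (-(L2 - minOverlap)):(L1 - minOverlap)) {
    lo <- max(0L, d); hi <- min(L1, d + L2)
    ov <- hi - lo
    if (ov < minOverlap) next
    i <- (lo + 1L):hi
    sc <- sum(av[i] == bv[i - d]) - sum(av[i] != bv[i - d])
    if (sc > best$score || (sc == best$score &&
        (ov > best$ov || (ov == best$ov && d < best$d))))
      best <- list(score = sc, ov = ov, d = d)
  }
  d <- best$d
  span <- (min(0L, d) + 1L):max(L1, d + L2)
  merged <- vapply(span - 1L, function(p) {
    in1 <- p >= 0L && p < L1
    in2 <- p >= d && p < d + L2
    if (in1) av[p + 1L] else bv[p - d + 1L]
  }, character(1))
  list(sequence = paste(merged, collapse = ""),
       score = max(0, best$score), d = d)
}

# quadratic DP identity oracle: maximize matches, then minimize columns
oracleIdentity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0L, n + 1L, m + 1L)
  C <- matrix(0L, n + 1L, m + 1L)
  C[1, ] <- 0:m; C[, 1] <- 0:n
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cand <- rbind(
      c(M[i, j] + (av[i] == bv[j]), C[i, j] + 1L),
      c(M[i, j + 1L], C[i, j + 1L] + 1L),
      c(M[i + 1L, j], C[i + 1L, j] + 1L))
    best <- which(cand[, 1] == max(cand[, 1]))
    best <- best[which.min(cand[best, 2])]
    M[i + 1L, j + 1L] <- cand[best, 1]
    C[i + 1L, j + 1L] <- cand[best, 2]
  }
  M[n + 1L, m + 1L] / C[n + 1L, m + 1L]
}

# full 2^m enumeration oracle for the exact signed-rank test
oracleWilcoxExact <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Vs <- as.vector(signs %*% r)
  list(statistic = V,
       p = mean(abs(Vs - mu) >= abs(V - mu) - 1e-9))
}

# full-table enumeration oracle for Fisher's exact r x c test, via
# expand.grid over the free (r-1) x (c-1) cells
oracleFisherEnum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  nr <- nrow(tab); nc <- ncol(tab)
  logK <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  free <- expand.grid(rep(list(0:max(rs)), (nr - 1L) * (nc - 1L)))
  lp <- apply(free, 1L, function(v) {
    tt <- matrix(0L, nr, nc)
    tt[seq_len(nr - 1L), seq_len(nc - 1L)] <- matrix(v, nr - 1L, nc - 1L)
    tt[nr, seq_len(nc - 1L)] <- cs[seq_len(nc - 1L)] -
      colSums(tt[seq_len(nr - 1L), seq_len(nc - 1L), drop = FALSE])
    tt[, nc] <- rs - rowSums(tt[, seq_len(nc - 1L), drop = FALSE])
    if (any(tt < 0)) return(NA_real_)
    logK - sum(lfactorial(tt))
  })
  lp <- lp[!is.na(lp)]
  lobs <- logK - sum(lfactorial(tab))
  sum(exp(lp[lp <= lobs + 1e-12]))
}

# single-PCR denoiser classification oracle using utils::adist
oracleDenoiseSingle <- function(sq, counts, ratio = 0.5) {
  dmat <- utils::adist(sq)
  n <- length(sq)
  isVariant <- hasVariant <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && dmat[i, j] == 1 && counts[j] / counts[i] < ratio) {
      isVariant[j] <- TRUE
      hasVariant[i] <- TRUE
    }
  }
  ifelse(isVariant, "internal", ifelse(hasVariant, "head", "singleton"))
}

# position-by-position scanning oracle for in-silico PCR
oracleScanPcr <- function(template, fwd, rev, maxMM = 3L,
                          insertLen = c(50L, 150L)) {
  rcrev <- rcSeq(rev)
  tv <- strsplit(template, "")[[1]]
  mm <- function(pat, at) {
    pv <- strsplit(pat, "")[[1]]
    sum(tv[at:(at + length(pv) - 1L)] != pv)
  }
  lf <- nchar(fwd); lr <- nchar(rcrev); L <- nchar(template)
  fAt <- Filter(function(p) mm(fwd, p) <= maxMM, seq_len(L - lf + 1L))
  rAt <- Filter(function(p) mm(rcrev, p) <= maxMM, seq_len(L - lr + 1L))
  out <- character(0)
  for (f in fAt) for (r in rAt) {
    len <- r - (f + lf)
    if (len >= insertLen[1] && len <= insertLen[2])
      out <- c(out, substr(template, f + lf, r - 1L))
  }
  out
}
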