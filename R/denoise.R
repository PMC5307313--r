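#' @include AllClasses.R
NULL

# one-substitution-or-one-indel neighbour test, vectorised over pairs
oneDiffPairs <- function(sq) {
  n <- length(sq)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  len <- nchar(sq)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    js <- which(seq_len(n) > i & abs(len - len[i]) <= 1L)
    hit <- js[vapply(js, function(j) cpp_one_diff(sq[i], sq[j]), logical(1))]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 2L))))
}

#' Denoise unique sequences with a single-variant graph
#'
#' Within each PCR, a directed edge u -> v is drawn whenever u and v differ
#' by exactly one substitution or one indel and `count(v)/count(u) <
#' ratioThreshold`, marking v as a likely PCR/sequencing error derived from
#' u. Per PCR, a sequence that is a variant of another is `internal`; a
#' sequence that is no variant but has variants is a `head`; an isolated
#' sequence is a `singleton`. Statuses are aggregated across PCRs by
#' majority vote over the PCRs where the sequence occurs (ties resolved
#' toward retention). Sequences whose aggregate status is `internal` are
#' discarded; by default their counts are reported, not merged into the
#' head (`mergeVariants = TRUE` adds each discarded variant's per-PCR count
#' to its highest-count parent).
#'
#' @param uss A [UniqueSeqSet] with per-PCR counts.
#' @param ratioThreshold Count ratio below which the smaller sequence is
#'   considered a variant of the larger.
#' @param mergeVariants Merge variant counts into their parents instead of
#'   discarding them.
#' @return The retained [UniqueSeqSet] with `status` filled in; attributes
#'   `removed` (number of discarded variants) and `removedCounts` (their
#'   total read count).
#' @export
denoiseSeqs <- function(uss, ratioThreshold = 0.5, mergeVariants = FALSE) {
  sq <- as.character(seqs(uss))
  cnt <- seqCounts(uss)
  n <- length(sq)
  if (n == 0L) return(uss)
  nbr <- oneDiffPairs(sq)
  statusVotes <- matrix(0L, nrow = n, ncol = 3L,
                        dimnames = list(NULL, c("head", "internal",
                                                "singleton")))
  parents <- vector("list", n)  # per sequence: matrix (parent, pcr)
  for (pcr in colnames(cnt)) {
    cc <- cnt[, pcr]
    present <- which(cc > 0L)
    if (!length(present)) next
    isVariant <- rep(FALSE, n)
    hasVariant <- rep(FALSE, n)
    if (nrow(nbr)) {
      inPcr <- nbr[cc[nbr[, 1]] > 0L & cc[nbr[, 2]] > 0L, , drop = FALSE]
      for (r in seq_len(nrow(inPcr))) {
        i <- inPcr[r, 1]; j <- inPcr[r, 2]
        if (cc[j] / cc[i] < ratioThreshold) {        # i -> j
          isVariant[j] <- TRUE; hasVariant[i] <- TRUE
          parents[[j]] <- rbind(parents[[j]], c(i, match(pcr, colnames(cnt))))
        }
        if (cc[i] / cc[j] < ratioThreshold) {        # j -> i
          isVariant[i] <- TRUE; hasVariant[j] <- TRUE
          parents[[i]] <- rbind(parents[[i]], c(j, match(pcr, colnames(cnt))))
        }
      }
    }
    st <- ifelse(isVariant[present], "internal",
                 ifelse(hasVariant[present], "head", "singleton"))
    for (k in seq_along(present))
      statusVotes[present[k], st[k]] <- statusVotes[present[k], st[k]] + 1L
  }
  status <- apply(statusVotes, 1L, function(v) {
    best <- max(v)
    # ties resolved in retention-favouring order
    cand <- names(v)[v == best]
    for (s in c("head", "singleton", "internal")) if (s %in% cand) return(s)
  })
  keep <- status != "internal"
  cntOut <- cnt
  if (mergeVariants && any(!keep)) {
    tot <- rowSums(cnt)
    for (j in which(!keep)) {
      pm <- parents[[j]]
      if (is.null(pm)) next
      for (pcrIdx in unique(pm[, 2])) {
        pset <- pm[pm[, 2] == pcrIdx, 1]
        target <- pset[which.max(tot[pset])]
        cntOut[target, pcrIdx] <- cntOut[target, pcrIdx] + cnt[j, pcrIdx]
      }
    }
  }
  out <- UniqueSeqSet(seqs(uss)[keep], cntOut[keep, , drop = FALSE],
                      status[keep])
  attr(out, "removed") <- sum(!keep)
  attr(out, "removedCounts") <- sum(cnt[!keep, , drop = FALSE])
  out
}
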