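#' @include AllClasses.R
NULL

readFastqPair <- function(r1, r2) {
  x1 <- readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  x2 <- readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2))
    sdStop("mate files contain different numbers of reads",
           "scatdiet_input_error")
  list(s1 = as.character(x1), q1 = as.character(mcols(x1)$qualities),
       s2 = as.character(x2), q2 = as.character(mcols(x2)$qualities),
       ids = names(x1))
}

#' Merge read pairs by best overlap
#'
#' Aligns each forward mate against the reverse complement of its reverse
#' mate over every admissible overlap (>= `minOverlap` nt) and keeps the
#' highest-scoring one (ties broken toward the larger overlap, then the
#' leftmost offset); the score is the number of matching overlap
#' positions minus the number of mismatches, floored at zero. At a
#' disagreement the consensus takes the higher-quality base. Pairs whose
#' sequence and quality lengths disagree are rejected per read and counted
#' in the `rejected` attribute.
#'
#' @param r1,r2 FASTQ file paths, or character vectors of mate sequences.
#' @param q1,q2 Optional quality strings (Phred+33) when `r1`/`r2` are
#'   character vectors; default is uniform Q40.
#' @param minOverlap Minimum admissible overlap in nt.
#' @return A data.frame with columns `read_id`, `sequence`, `score`;
#'   attribute `rejected` counts per-read rejections.
#' @export
mergePairs <- function(r1, r2, q1 = NULL, q2 = NULL, minOverlap = 10L) {
  if (length(r1) == 1L && file.exists(r1[1])) {
    fq <- readFastqPair(r1, r2)
    s1 <- fq$s1; q1 <- fq$q1; s2 <- fq$s2; q2 <- fq$q2; ids <- fq$ids
  } else {
    s1 <- as.character(r1); s2 <- as.character(r2)
    if (is.null(q1)) q1 <- strrep("I", nchar(s1))
    if (is.null(q2)) q2 <- strrep("I", nchar(s2))
    ids <- names(s1)
    if (is.null(ids)) ids <- sprintf("read%07d", seq_along(s1))
  }
  ok <- nchar(q1) == nchar(s1) & nchar(q2) == nchar(s2) &
    nzchar(s1) & nzchar(s2)
  nRejected <- sum(!ok)
  if (nRejected > 0)
    message(sprintf("mergePairs: rejected %d read(s) with mismatched ",
                    nRejected), "sequence/quality lengths")
  s1 <- s1[ok]; q1 <- q1[ok]; s2 <- s2[ok]; q2 <- q2[ok]; ids <- ids[ok]
  s2rc <- revcomp(s2)
  q2r <- vapply(strsplit(q2, ""), function(z)
    paste(rev(z), collapse = ""), character(1))
  m <- cpp_merge_pairs(s1, q1, s2rc, q2r, as.integer(minOverlap))
  out <- data.frame(read_id = ids, sequence = m$sequence,
                    score = m$score, stringsAsFactors = FALSE)
  attr(out, "rejected") <- nRejected
  out
}

#' Filter merged reads on alignment quality score
#'
#' Retains merged reads whose overlap alignment score is at least
#' `minScore`; the threshold is strict on removal (score < `minScore` goes,
#' the boundary value stays).
#'
#' @param merged Output of [mergePairs()].
#' @param minScore Minimum retained alignment score.
#' @return The retained rows; attribute `removed` counts the casualties.
#' @export
filterQuality <- function(merged, minScore = 40) {
  keep <- merged$score >= minScore
  out <- merged[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  rownames(out) <- NULL
  out
}

primerMismatches <- function(region, primer) {
  cpp_mismatch_count(region, primer)
}

demuxOneOrientation <- function(seqsC, scheme, primers, maxPrimerMismatch) {
  p <- tagPairs(scheme)
  key <- paste(p$forward, p$reverse)
  n <- nchar(seqsC)
  fTag <- substr(seqsC, 1L, 9L)
  rTag <- revcomp(substr(seqsC, n - 8L, n))
  rTag[n < 18L] <- ""
  idx <- match(paste(fTag, rTag), key)
  lf <- nchar(primers[["forward"]])
  lr <- nchar(primers[["reverse"]])
  fRegion <- substr(seqsC, 10L, 9L + lf)
  rRegion <- substr(seqsC, n - 9L - lr + 1L, n - 9L)
  fmm <- primerMismatches(fRegion, primers[["forward"]])
  rmm <- primerMismatches(rRegion, revcomp(primers[["reverse"]]))
  ok <- !is.na(idx) & fmm <= maxPrimerMismatch & rmm <= maxPrimerMismatch &
    n >= (18L + lf + lr)
  list(ok = ok, pcr = ifelse(ok, p$pcr_id[idx], NA_character_),
       insert = substr(seqsC, 10L + lf, n - 9L - lr))
}

#' Demultiplex merged reads by tag pair and primer sites
#'
#' A read is assigned to a PCR iff both 9-nt tags match a registered tag
#' pair exactly (any N disqualifies) and both primer sites align with at
#' most `maxPrimerMismatch` mismatches each (an N counts as a mismatch).
#' Both orientations of the merged sequence are tried, since merge
#' orientation is arbitrary. Tags and primers are trimmed from the retained
#' insert.
#'
#' @param merged Output of [mergePairs()] (possibly filtered).
#' @param scheme A [TagScheme].
#' @param primers Primer pair as from [v5Primers()].
#' @param maxPrimerMismatch Maximum mismatches tolerated per primer site.
#' @return List with `assigned` (read_id, pcr_id, insert) and `unassigned`
#'   (read_id, sequence) data frames; every input read lands in exactly one.
#' @export
demultiplex <- function(merged, scheme, primers = v5Primers(),
                        maxPrimerMismatch = 2L) {
  validObject(scheme)
  seqsC <- merged$sequence
  fwd <- demuxOneOrientation(seqsC, scheme, primers, maxPrimerMismatch)
  res <- fwd
  retry <- which(!fwd$ok)
  if (length(retry)) {
    rev <- demuxOneOrientation(revcomp(seqsC[retry]), scheme, primers,
                               maxPrimerMismatch)
    res$ok[retry] <- rev$ok
    res$pcr[retry] <- rev$pcr
    res$insert[retry] <- rev$insert
  }
  assigned <- data.frame(read_id = merged$read_id[res$ok],
                         pcr_id = res$pcr[res$ok],
                         insert = res$insert[res$ok],
                         stringsAsFactors = FALSE)
  unassigned <- data.frame(read_id = merged$read_id[!res$ok],
                           sequence = seqsC[!res$ok],
                           stringsAsFactors = FALSE)
  rownames(assigned) <- rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}

#' Dereplicate assigned reads into unique sequences
#'
#' Collapses identical insert strings into one record per distinct
#' sequence, tallying per-PCR counts. The total count over the output
#' equals the number of input reads exactly.
#'
#' @param assigned The `assigned` data.frame from [demultiplex()].
#' @param pcrIds Optional full set of PCR ids to appear as count columns
#'   (e.g. to keep zero-read negative controls in the matrix).
#' @return A [UniqueSeqSet], ordered by decreasing total count (ties by
#'   sequence).
#' @export
dereplicate <- function(assigned, pcrIds = NULL) {
  if (is.null(pcrIds)) pcrIds <- sort(unique(assigned$pcr_id))
  useq <- sort(unique(assigned$insert))
  cnt <- table(factor(assigned$insert, levels = useq),
               factor(assigned$pcr_id, levels = pcrIds))
  cnt <- matrix(as.integer(cnt), nrow = length(useq),
                dimnames = list(NULL, pcrIds))
  ord <- order(-rowSums(cnt), useq)
  cnt <- cnt[ord, , drop = FALSE]
  useq <- useq[ord]
  ids <- sprintf("u%06d", seq_along(useq))
  rownames(cnt) <- ids
  UniqueSeqSet(setNames(DNAStringSet(useq), ids), cnt)
}

#' Filter unique sequences on length and total abundance
#'
#' Retains sequences of length at least `minLen` whose total count over the
#' whole dataset is at least `minTotal`; both thresholds are strict on
#' removal (shorter-than / fewer-than go, the boundary values stay).
#'
#' @param uss A [UniqueSeqSet].
#' @param minLen Minimum retained insert length (nt).
#' @param minTotal Minimum retained dataset-wide count.
#' @return The filtered [UniqueSeqSet]; attribute `removed` counts the
#'   discarded sequences.
#' @export
filterLengthCount <- function(uss, minLen = 80L, minTotal = 1000L) {
  keep <- width(seqs(uss)) >= minLen & rowSums(seqCounts(uss)) >= minTotal
  out <- uss[keep]
  attr(out, "removed") <- sum(!keep)
  out
}
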