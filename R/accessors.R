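#' @include AllGenerics.R
NULL

#' Accessors for scatdiet classes
#'
#' `seqs()` returns the [Biostrings::DNAStringSet] of a `UniqueSeqSet` or
#' `ReferenceDb`; `seqCounts()` the sequences x PCRs count matrix;
#' `seqStatus()` the denoising status vector; `refTaxonomy()` the lineage
#' table of a `ReferenceDb`; `tagPairs()` the tag-pair table of a
#' `TagScheme`; `occurrenceMatrix()` the binary taxa x samples matrix of a
#' `DietOccurrence`.
#'
#' @param x An object of the documented class.
#' @return See the per-function descriptions above.
#' @name accessors
#' @aliases seqs seqCounts seqStatus refTaxonomy tagPairs occurrenceMatrix
NULL

#' @rdname accessors
#' @export
setMethod("seqs", "UniqueSeqSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("seqs", "ReferenceDb", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("seqCounts", "UniqueSeqSet", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("seqStatus", "UniqueSeqSet", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("refTaxonomy", "ReferenceDb", function(x) x@taxonomy)

#' @rdname accessors
#' @export
setMethod("tagPairs", "TagScheme", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("occurrenceMatrix", "DietOccurrence",
          function(x) assay(x, "occurrence"))

#' Subset a UniqueSeqSet by sequence index
#'
#' @param x A `UniqueSeqSet`.
#' @param i Logical, integer or character index over sequences.
#' @param j,...,drop Ignored.
#' @return A `UniqueSeqSet` restricted to the selected sequences.
#' @export
setMethod("[", "UniqueSeqSet", function(x, i, j, ..., drop = FALSE) {
  UniqueSeqSet(x@sequences[i], x@counts[i, , drop = FALSE], x@status[i])
})

setMethod("show", "TagScheme", function(object) {
  p <- object@pairs
  cat(sprintf("TagScheme: %d PCRs (%d samples, %d negative controls)\n",
              nrow(p), sum(!p$is_control), sum(p$is_control)))
  cat(sprintf("  tags: 9 nt, CC prefix, pairwise Hamming distance >= 3\n"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d samples x %d reads, %d negative controls\n",
    "  predator %s (pre-blocking share %.2f, blocking efficiency %.2f)\n",
    "  prey pool %d taxa, %d-%d taxa/sample, Dirichlet skew %.2f\n",
    "  per-base error %.4g, tag jumps %.4g, contaminant %.4g, seed %d\n"),
    object@nSamples, object@readsPerSample, object@nNegControls,
    object@predator, object@predatorShare, object@blockingEfficiency,
    nrow(object@taxaPool), object@taxaPerSample[1], object@taxaPerSample[2],
    object@abundanceSkew, object@perBaseErrorRate, object@tagJumpRate,
    object@contaminantRate, object@seed))
})

setMethod("show", "ReferenceDb", function(object) {
  cat(sprintf("ReferenceDb (%s): %d records, %d species, %d orders\n",
              object@type, length(object@sequences),
              length(unique(object@taxonomy$species)),
              length(unique(object@taxonomy$order))))
})

setMethod("show", "UniqueSeqSet", function(object) {
  st <- table(factor(object@status,
                     levels = c("head", "internal", "singleton")))
  cat(sprintf("UniqueSeqSet: %d sequences x %d PCRs, %d reads total\n",
              length(object@sequences), ncol(object@counts),
              sum(object@counts)))
  if (any(!is.na(object@status)))
    cat(sprintf("  status: %d head, %d internal, %d singleton\n",
                st["head"], st["internal"], st["singleton"]))
})

setMethod("show", "DietOccurrence", function(object) {
  occ <- assay(object, "occurrence")
  cat(sprintf("DietOccurrence: %d prey taxa x %d samples (%d occurrences)\n",
              nrow(occ), ncol(occ), sum(occ)))
  nf <- metadata(object)$no_food
  if (length(nf)) cat(sprintf("  %d sample(s) with no food detected\n",
                              length(nf)))
})
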