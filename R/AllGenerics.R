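#' @include AllClasses.R
NULL

#' @export
setGeneric("seqs", function(x) standardGeneric("seqs"))

#' @export
setGeneric("seqCounts", function(x) standardGeneric("seqCounts"))

#' @export
setGeneric("seqStatus", function(x) standardGeneric("seqStatus"))

#' @export
setGeneric("refTaxonomy", function(x) standardGeneric("refTaxonomy"))

#' @export
setGeneric("tagPairs", function(x) standardGeneric("tagPairs"))

#' @export
setGeneric("occurrenceMatrix", function(x) standardGeneric("occurrenceMatrix"))

#' @export
setGeneric("percentFC", function(x, ...) standardGeneric("percentFC"))

#' @export
setGeneric("percentTX", function(x, ...) standardGeneric("percentTX"))

#' @export
setGeneric("stratifyDiet", function(x, ...) standardGeneric("stratifyDiet"))
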