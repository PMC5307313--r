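#' @include scatdiet-package.R
NULL

TAX_RANKS <- c("species", "genus", "family", "order", "class")

hammingPairsOk <- function(tags, minDist = 3L) {
  n <- length(tags)
  if (n < 2L) return(TRUE)
  m <- do.call(rbind, strsplit(tags, ""))
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], nrow = n - i, ncol = ncol(m), byrow = TRUE))
    if (any(d < minDist)) return(FALSE)
  }
  TRUE
}

# ---------------------------------------------------------------------------
# TagScheme: one 9-nt tag pair per PCR (samples and negative controls)
# ---------------------------------------------------------------------------

#' @rdname TagScheme
#' @export
setClass("TagScheme", representation(pairs = "data.frame"))

setValidity("TagScheme", function(object) {
  p <- object@pairs
  need <- c("forward", "reverse", "pcr_id", "is_control")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  tags <- unique(c(p$forward, p$reverse))
  if (any(nchar(tags) != 9L)) return("all tags must be 9 nt")
  if (!all(grepl("^CC[ACGT]{7}$", tags)))
    return("tags must start with CC followed by seven A/C/G/T bases")
  if (!hammingPairsOk(tags)) return("tags must differ by >= 3 nucleotides")
  if (anyDuplicated(p$pcr_id)) return("pcr ids must be unique")
  if (anyDuplicated(paste(p$forward, p$reverse)))
    return("tag pairs must map to a single PCR")
  TRUE
})

#' Tag scheme for multiplexed PCRs
#'
#' One 9-nt tag pair per PCR. Tags start with `CC` followed by seven variable
#' nucleotides and differ pairwise by at least three nucleotides, so a single
#' sequencing error cannot convert one valid tag into another.
#'
#' @param forward,reverse Character vectors of 9-nt tags (5'-3').
#' @param pcr_id Character vector of unique PCR identifiers.
#' @param is_control Logical vector marking negative-control PCRs.
#' @return A `TagScheme` object.
#' @seealso [generateTagScheme()]
#' @export
TagScheme <- function(forward, reverse, pcr_id,
                      is_control = rep(FALSE, length(pcr_id))) {
  new("TagScheme", pairs = data.frame(
    forward = as.character(forward), reverse = as.character(reverse),
    pcr_id = as.character(pcr_id), is_control = as.logical(is_control),
    stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# SimConfig: study conditions for the synthetic sequencing run
# ---------------------------------------------------------------------------

#' @rdname SimConfig
#' @export
setClass("SimConfig", representation(
  nSamples = "integer", predator = "character", taxaPool = "data.frame",
  taxaPerSample = "integer", abundanceSkew = "numeric",
  minProportion = "numeric", perBaseErrorRate = "numeric",
  tagJumpRate = "numeric", blockingEfficiency = "numeric",
  predatorShare = "numeric", contaminantRate = "numeric",
  readsPerSample = "integer", readLength = "integer",
  nNegControls = "integer", controlReads = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  pr <- c(perBaseErrorRate = object@perBaseErrorRate,
          tagJumpRate = object@tagJumpRate,
          blockingEfficiency = object@blockingEfficiency,
          predatorShare = object@predatorShare,
          contaminantRate = object@contaminantRate)
  if (any(pr < 0 | pr > 1))
    return("all rates/probabilities must lie in [0, 1]")
  if (object@readsPerSample <= 0L) return("readsPerSample must be > 0")
  if (object@nSamples <= 0L) return("nSamples must be > 0")
  npool <- sum(!(object@taxaPool$species %in%
                   c(object@predator, "Homo sapiens")))
  if (length(object@taxaPerSample) != 2L ||
      object@taxaPerSample[1] < 1L || object@taxaPerSample[2] > npool ||
      object@taxaPerSample[1] > object@taxaPerSample[2])
    return("taxaPerSample must be an increasing range within [1, #prey taxa]")
  if (object@abundanceSkew <= 0) return("abundanceSkew must be positive")
  if (object@predatorShare + object@contaminantRate > 1)
    return("predatorShare + contaminantRate must be <= 1")
  if (!all(TAX_RANKS %in% names(object@taxaPool)))
    return("taxaPool must carry a full species..class lineage")
  TRUE
})

#' Configuration of a synthetic metabarcoding run
#'
#' Holds the study conditions the simulator emulates: how many faecal samples
#' and negative controls, which taxa can occur in a diet (with full
#' species-to-class lineages), how skewed the within-sample template
#' proportions are, and the artefact rates (per-base sequencing error, tag
#' jumps, host suppression by the blocking oligo, human contamination).
#'
#' @param nSamples Number of faecal samples.
#' @param predator Predator species name; its reads are suppressed by the
#'   blocking oligonucleotide and removed by the per-sample filter.
#' @param taxaPool Data frame with columns `species`, `genus`, `family`,
#'   `order`, `class` (one row per reference taxon; may include the predator
#'   and *Homo sapiens* for host/contaminant templates).
#' @param taxaPerSample Integer range (length 2) of true prey taxa per sample.
#' @param abundanceSkew Symmetric Dirichlet concentration for the true
#'   within-sample prey proportions (small = skewed, large = even).
#' @param minProportion Lower floor on a true prey proportion; draws are
#'   rejected until every component exceeds it.
#' @param perBaseErrorRate Per-base substitution probability on each mate.
#' @param tagJumpRate Probability that a read carries the tag pair of a
#'   different PCR.
#' @param blockingEfficiency Fraction of predator template suppressed;
#'   predator reads appear at `predatorShare * (1 - blockingEfficiency)` of
#'   the pre-blocking template share.
#' @param predatorShare Pre-blocking share of host template in the extract.
#' @param contaminantRate Share of human contaminant template.
#' @param readsPerSample Reads sequenced per sample PCR.
#' @param readLength Bases sequenced on each end.
#' @param nNegControls Number of template-free control PCRs.
#' @param controlReads Mean (Poisson) read count of a negative control.
#' @param seed Integer seed; identical configurations give byte-identical
#'   FASTQ output.
#' @return A validated `SimConfig` object.
#' @export
SimConfig <- function(nSamples, predator, taxaPool,
                      taxaPerSample = c(1L, 7L), abundanceSkew = 2,
                      minProportion = 0.05, perBaseErrorRate = 0.001,
                      tagJumpRate = 0.005, blockingEfficiency = 0.95,
                      predatorShare = 0.9, contaminantRate = 0.005,
                      readsPerSample = 3000L, readLength = 100L,
                      nNegControls = 7L, controlReads = 20, seed = 1L) {
  new("SimConfig", nSamples = as.integer(nSamples), predator = predator,
      taxaPool = taxaPool, taxaPerSample = as.integer(taxaPerSample),
      abundanceSkew = abundanceSkew, minProportion = minProportion,
      perBaseErrorRate = perBaseErrorRate, tagJumpRate = tagJumpRate,
      blockingEfficiency = blockingEfficiency, predatorShare = predatorShare,
      contaminantRate = contaminantRate,
      readsPerSample = as.integer(readsPerSample),
      readLength = as.integer(readLength),
      nNegControls = as.integer(nNegControls), controlReads = controlReads,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# ReferenceDb: reference sequences with full taxonomic lineages
# ---------------------------------------------------------------------------

#' @rdname ReferenceDb
#' @export
setClass("ReferenceDb", representation(
  sequences = "DNAStringSet", taxonomy = "data.frame", type = "character"))

setValidity("ReferenceDb", function(object) {
  tx <- object@taxonomy
  need <- c("record_id", TAX_RANKS)
  if (!all(need %in% names(tx)))
    return(sprintf("taxonomy must have columns %s", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(tx))
    return("one taxonomy row per sequence required")
  if (!identical(names(object@sequences), tx$record_id))
    return("sequence names must equal taxonomy record_id, in order")
  # lineages must form a tree: a taxon has a single parent at the next rank
  for (i in seq_len(length(TAX_RANKS) - 1L)) {
    child <- tx[[TAX_RANKS[i]]]
    parent <- tx[[TAX_RANKS[i + 1L]]]
    nPar <- tapply(parent, child, function(z) length(unique(z)))
    if (any(nPar > 1L))
      return(sprintf("rank conflict: %s '%s' has multiple parents",
                     TAX_RANKS[i], names(nPar)[which(nPar > 1L)[1]]))
  }
  if (!object@type %in% c("source", "amplicon"))
    return("type must be 'source' or 'amplicon'")
  TRUE
})

#' Reference sequence database
#'
#' A set of reference sequences, each with a full `species`-to-`class`
#' lineage. `type = "source"` holds full records that still contain the
#' primer sites; `type = "amplicon"` holds the insert-only amplicons
#' produced by [inSilicoPcr()].
#'
#' @param sequences Named [Biostrings::DNAStringSet] (names = record ids).
#' @param taxonomy Data frame with `record_id`, `species`, `genus`,
#'   `family`, `order`, `class`.
#' @param type `"source"` or `"amplicon"`.
#' @return A validated `ReferenceDb` object.
#' @export
ReferenceDb <- function(sequences, taxonomy, type = "source") {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  new("ReferenceDb", sequences = sequences,
      taxonomy = as.data.frame(taxonomy), type = type)
}

# ---------------------------------------------------------------------------
# UniqueSeqSet: dereplicated sequences with per-PCR counts
# ---------------------------------------------------------------------------

#' @rdname UniqueSeqSet
#' @export
setClass("UniqueSeqSet", representation(
  sequences = "DNAStringSet", counts = "matrix", status = "character"))

setValidity("UniqueSeqSet", function(object) {
  n <- length(object@sequences)
  if (nrow(object@counts) != n) return("counts needs one row per sequence")
  if (!identical(rownames(object@counts), names(object@sequences)))
    return("counts rownames must equal sequence names")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (n > 0 && any(rowSums(object@counts) < 1))
    return("every unique sequence must have total count >= 1")
  if (length(object@status) != n) return("one status per sequence required")
  if (!all(object@status %in% c("head", "internal", "singleton", NA_character_)))
    return("status must be head, internal, singleton or NA")
  TRUE
})

#' Dereplicated unique sequences
#'
#' One row per distinct insert sequence with a per-PCR count matrix and,
#' after denoising, a variant-graph status (`head`, `internal` or
#' `singleton`).
#'
#' @param sequences Named [Biostrings::DNAStringSet].
#' @param counts Integer matrix, sequences x PCRs, rownames matching
#'   `names(sequences)`.
#' @param status Character vector of denoising statuses (NA before
#'   denoising).
#' @return A validated `UniqueSeqSet`.
#' @export
UniqueSeqSet <- function(sequences, counts,
                         status = rep(NA_character_, length(sequences))) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  new("UniqueSeqSet", sequences = sequences, counts = counts, status = status)
}

# ---------------------------------------------------------------------------
# DietOccurrence: samples x prey taxa presence with metadata
# ---------------------------------------------------------------------------

#' @rdname DietOccurrence
#' @export
setClass("DietOccurrence", contains = "SummarizedExperiment")

setValidity("DietOccurrence", function(object) {
  if (!"occurrence" %in% SummarizedExperiment::assayNames(object))
    return("an 'occurrence' assay is required")
  occ <- assay(object, "occurrence")
  if (!all(occ %in% c(0, 1))) return("occurrence entries must be 0/1")
  TRUE
})

#' Prey occurrence matrix with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a binary
#' taxa x samples occurrence assay, taxon metadata (`rank`, `taxon_order`)
#' as rowData, and sample metadata (predator, season, altitude) as colData.
#' Samples containing no food taxon are dropped at construction (they carry
#' no dietary information and would corrupt the occurrence denominators);
#' their ids are kept in `metadata(x)$no_food`.
#'
#' @param occurrence Binary matrix, taxa (rows) x samples (columns).
#' @param taxonData Data frame of per-taxon metadata (e.g. `rank`,
#'   `taxon_order`), one row per taxon.
#' @param sampleData Data frame of per-sample metadata (e.g. `predator`,
#'   `season`, `altitude_m`), one row per sample.
#' @return A validated `DietOccurrence` object.
#' @export
DietOccurrence <- function(occurrence, taxonData = NULL, sampleData = NULL) {
  occurrence <- as.matrix(occurrence)
  mode(occurrence) <- "numeric"
  occurrence[occurrence > 0] <- 1
  keep <- colSums(occurrence) >= 1
  dropped <- colnames(occurrence)[!keep]
  occurrence <- occurrence[, keep, drop = FALSE]
  if (!is.null(sampleData)) sampleData <- sampleData[keep, , drop = FALSE]
  args <- list(assays = list(occurrence = occurrence))
  if (!is.null(taxonData)) args$rowData <- DataFrame(taxonData)
  if (!is.null(sampleData)) args$colData <- DataFrame(sampleData)
  se <- do.call(SummarizedExperiment, args)
  obj <- new("DietOccurrence", se)
  metadata(obj)$no_food <- dropped
  obj
}
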