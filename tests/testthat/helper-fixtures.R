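# shared in-code fixtures

# small taxonomy spanning two classes / three orders / four genera
tinyTaxonomy <- function() {
  data.frame(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    species = c("Apodemus draco", "Apodemus chevrieri",
                "Niviventer confucianus", "Eothenomys chinensis",
                "Tragopan temminckii", "Gallus gallus"),
    genus = c("Apodemus", "Apodemus", "Niviventer", "Eothenomys",
              "Tragopan", "Gallus"),
    family = c("Muridae", "Muridae", "Muridae", "Cricetidae",
               "Phasianidae", "Phasianidae"),
    order = c("Rodentia", "Rodentia", "Rodentia", "Rodentia",
              "Galliformes", "Galliformes"),
    class = c("Mammalia", "Mammalia", "Mammalia", "Mammalia",
              "Aves", "Aves"),
    stringsAsFactors = FALSE)
}

# amplicon ReferenceDb with given insert sequences, one per tinyTaxonomy row
tinyAmpliconDb <- function(inserts) {
  tx <- tinyTaxonomy()[seq_along(inserts), , drop = FALSE]
  ReferenceDb(stats::setNames(Biostrings::DNAStringSet(inserts),
                              tx$record_id),
              tx, type = "amplicon")
}

# UniqueSeqSet from sequences and a counts matrix
makeUss <- function(sq, counts, status = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L,
                                             dimnames = list(NULL, "S001"))
  ids <- sprintf("u%06d", seq_along(sq))
  rownames(counts) <- ids
  if (is.null(status)) status <- rep(NA_character_, length(sq))
  UniqueSeqSet(stats::setNames(Biostrings::DNAStringSet(sq), ids),
               counts, status)
}

# small noise-free study configuration used by several pipeline tests
tinySimConfig <- function(...) {
  args <- list(nSamples = 6, predator = "Prionailurus bengalensis",
               taxaPool = felidTaxaPool()[c(1:10, 41, 43), ],
               taxaPerSample = c(1, 5), perBaseErrorRate = 0,
               tagJumpRate = 0, blockingEfficiency = 1, contaminantRate = 0,
               readsPerSample = 500, nNegControls = 2, seed = 42)
  do.call(SimConfig, utils::modifyList(args, list(...)))
}

# build a DietOccurrence from a 0/1 matrix written taxa x samples
makeOcc <- function(m, orders = NULL, sampleData = NULL) {
  td <- data.frame(taxon = rownames(m),
                   rank = rep("species", nrow(m)),
                   taxon_order = if (is.null(orders))
                     rep("Rodentia", nrow(m)) else orders,
                   stringsAsFactors = FALSE)
  DietOccurrence(m, taxonData = td, sampleData = sampleData)
}
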