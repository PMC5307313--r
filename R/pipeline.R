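#' @include AllClasses.R
NULL

#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage threshold in one place, with the workflow's
#' standard values as defaults: merge alignment score at least 40, insert
#' length at least 80 nt, dataset-wide count at least 1000, denoiser count
#' ratio 0.5,
#' per-sample frequency 0.1% and 50 reads, species-level identity 0.98,
#' discard identity 0.94, and 2% divergence for the taxon collapse.
#'
#' @param simConfig A [SimConfig] describing the synthetic run.
#' @param outDir Output directory for the simulated run files.
#' @param localSpecies Locally occurring species used by the refinement
#'   rules; defaults to every prey species in the pool.
#' @param minScore,minLen,minTotal,ratioThreshold,maxPrimerMismatch Read
#'   cascade thresholds.
#' @param pcrMaxMismatch,pcrInsertLen In-silico PCR primer mismatch
#'   allowance and admissible insert range.
#' @param speciesMin,lowMin Identity cut-offs for the assignment rules.
#' @param minFrac,minReads Per-sample low-frequency thresholds.
#' @param divergence Taxon collapse divergence.
#' @return A validated configuration list of class `scatdiet_run_config`.
#' @export
pipelineConfig <- function(simConfig, outDir = tempfile("scatdiet_run_"),
                           localSpecies = NULL, minScore = 40, minLen = 80L,
                           minTotal = 1000L, ratioThreshold = 0.5,
                           maxPrimerMismatch = 2L, pcrMaxMismatch = 3L,
                           pcrInsertLen = c(50L, 150L), speciesMin = 0.98,
                           lowMin = 0.94, minFrac = 0.001, minReads = 50L,
                           divergence = 0.02) {
  stopifnot(is(simConfig, "SimConfig"))
  if (!(lowMin <= speciesMin))
    sdStop("identity cut-offs must be ordered lowMin <= speciesMin",
           "scatdiet_config_error")
  if (any(c(minScore, minLen, minTotal, minReads) <= 0) ||
      minFrac < 0 || divergence < 0 || ratioThreshold <= 0)
    sdStop("thresholds must be positive", "scatdiet_config_error")
  if (is.null(localSpecies))
    localSpecies <- setdiff(simConfig@taxaPool$species,
                            c(simConfig@predator, "Homo sapiens"))
  structure(list(
    simConfig = simConfig, outDir = outDir, localSpecies = localSpecies,
    minScore = minScore, minLen = minLen, minTotal = minTotal,
    ratioThreshold = ratioThreshold, maxPrimerMismatch = maxPrimerMismatch,
    pcrMaxMismatch = pcrMaxMismatch, pcrInsertLen = pcrInsertLen,
    speciesMin = speciesMin, lowMin = lowMin, minFrac = minFrac,
    minReads = minReads, divergence = divergence),
    class = "scatdiet_run_config")
}

#' Run the full simulate-filter-assign-summarize pipeline
#'
#' Orchestrates the synthetic run, the read filter cascade, reference
#' database construction, taxonomic assignment with local refinement,
#' per-sample contamination filtering, the collapse into discrete prey
#' taxa, and the dietary summary, keeping a ledger of every stage's
#' input/output sizes.
#'
#' @param config A [pipelineConfig()] object.
#' @return List with `occurrence` (a [DietOccurrence]), `summary` (a
#'   [dietSummary()] frame), `assignments`, `collapse`, `ledger`
#'   (stage-by-stage casualty counts), `noFood`, and `sim` (the simulation
#'   outputs, including the ground-truth read log and diet profiles).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "scatdiet_run_config"))
  sc <- config$simConfig
  ledger <- list()
  note <- function(stage, unit, n_in, n_out)
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, unit = unit, n_in = n_in, n_out = n_out,
      stringsAsFactors = FALSE)

  scheme <- generateTagScheme(sc@nSamples + sc@nNegControls,
                              seed = sc@seed, nControls = sc@nNegControls)
  refdb <- generateReferenceDb(sc@taxaPool, seed = sc@seed + 1L)
  sim <- simulateRun(sc, scheme, refdb, config$outDir)

  merged <- mergePairs(sim$r1, sim$r2)
  note("merge_pairs", "reads", sim$nReads, nrow(merged))
  fq <- filterQuality(merged, config$minScore)
  note("filter_quality", "reads", nrow(merged), nrow(fq))
  dm <- demultiplex(fq, scheme, maxPrimerMismatch = config$maxPrimerMismatch)
  note("demultiplex", "reads", nrow(fq), nrow(dm$assigned))
  uss <- dereplicate(dm$assigned, pcrIds = tagPairs(scheme)$pcr_id)
  note("dereplicate", "unique_sequences", nrow(dm$assigned),
       length(seqs(uss)))
  flc <- filterLengthCount(uss, config$minLen, config$minTotal)
  note("filter_length_count", "unique_sequences", length(seqs(uss)),
       length(seqs(flc)))
  dn <- denoiseSeqs(flc, config$ratioThreshold)
  note("denoise", "unique_sequences", length(seqs(flc)), length(seqs(dn)))

  ampDb <- inSilicoPcr(refdb, maxMismatch = config$pcrMaxMismatch,
                       insertLen = config$pcrInsertLen)
  asg <- assignTaxa(dn, ampDb)
  ref <- refineAssignments(asg, config$localSpecies, refTaxonomy(ampDb),
                           config$speciesMin, config$lowMin)
  kept <- ref$rule != "discarded_low_identity"
  note("identity_filter", "unique_sequences", length(kept), sum(kept))
  dnKept <- dn[kept]
  refKept <- ref[kept, , drop = FALSE]

  psf <- perSampleFilter(dnKept, refKept, controlIds = sim$controlIds,
                         predator = sc@predator, minFrac = config$minFrac,
                         minReads = config$minReads)
  note("per_sample_filter", "unique_sequences", sum(kept),
       length(seqs(psf$uss)))
  col <- collapseTaxa(psf$uss, psf$assignments, refTaxonomy(ampDb),
                      config$divergence)
  note("collapse_taxa", "taxa", length(seqs(psf$uss)), nrow(col$taxa))

  meta <- sim$metadata
  rownames(meta) <- meta$sample_id
  presentSamples <- colnames(col$presence)
  occ <- DietOccurrence(col$presence, taxonData = col$taxa,
                        sampleData = meta[presentSamples, , drop = FALSE])
  note("samples", "samples", sc@nSamples, ncol(occ))
  ledger <- do.call(rbind, ledger)
  list(occurrence = occ,
       summary = dietSummary(occ),
       assignments = ref, collapse = col, ledger = ledger,
       noFood = psf$noFood, scheme = scheme, refdb = refdb, sim = sim)
}

#' True occurrence matrix from simulated diet profiles
#'
#' @param profiles The `profiles` data frame of [simulateRun()].
#' @param taxa Optional fixed taxon universe for the rows.
#' @return Binary taxa x samples matrix.
#' @export
truthOccurrence <- function(profiles, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(profiles$taxon))
  samples <- unique(profiles$sample_id)
  m <- matrix(0, nrow = length(taxa), ncol = length(samples),
              dimnames = list(taxa, samples))
  m[cbind(match(profiles$taxon, taxa),
          match(profiles$sample_id, samples))] <- 1
  m
}

#' Per-sample Jaccard similarity between recovered and true taxon sets
#'
#' @param occ A recovered [DietOccurrence] whose rowData `taxon` column
#'   holds species names comparable to the simulated profiles.
#' @param profiles The `profiles` data frame of [simulateRun()].
#' @return Named numeric vector, one Jaccard index per true sample (0 for
#'   samples the pipeline lost entirely).
#' @export
jaccardRecovery <- function(occ, profiles) {
  recTaxa <- as.character(rowData(occ)$taxon)
  m <- occurrenceMatrix(occ)
  vapply(unique(profiles$sample_id), function(s) {
    truth <- profiles$taxon[profiles$sample_id == s]
    rec <- if (s %in% colnames(m)) unique(recTaxa[m[, s] > 0]) else character(0)
    length(intersect(truth, rec)) / length(union(truth, rec))
  }, numeric(1))
}
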