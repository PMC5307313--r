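# scatdiet

Faecal DNA metabarcoding diet analysis for vertebrate predators, in R.

Dietary studies of elusive carnivores increasingly rely on metabarcoding:
a short mitochondrial marker (here the ~100 bp 12S V5 fragment) is
PCR-amplified from faecal DNA with sample-specific 9-nt tags, sequenced as
paired-end reads, cleaned of PCR/sequencing artefacts, and assigned to
prey taxa against a reference database. `scatdiet` implements that
workflow end to end, together with the dietary composition and niche
statistics used to interpret the resulting occurrence data:

* **Simulation** — `SimConfig()` / `simulateRun()` generate tagged
  paired-end FASTQ runs with per-base errors, tag jumps, blocking-oligo
  suppression of the host, human contamination and negative-control PCRs,
  alongside the ground-truth diet profiles.
* **Read cascade** — `mergePairs()` (best-overlap merging, score =
  matches − mismatches), `filterQuality()` (score ≥ 40),
  `demultiplex()` (exact tags, ≤ 2 primer mismatches),
  `dereplicate()`, `filterLengthCount()` (≥ 80 bp, total ≥ 1000),
  `denoiseSeqs()` (single-variant graph, count ratio 0.5).
* **Assignment** — `inSilicoPcr()` builds the amplicon reference,
  `assignTaxa()` applies best-identity + lowest-common-ancestor logic,
  `refineAssignments()` the three local-occurrence rules
  (species at ≥ 98% to one local species; local disambiguation or lowest
  containing taxon at ≥ 98% ties; lowest local-containing taxon, with
  flagged congener substitution, at 94–98%; discard below 94%),
  `perSampleFilter()` the per-sample 0.1% / 50-read / negative-control /
  non-prey removals, and `collapseTaxa()` the 2%-divergence collapse into
  discrete taxa.
* **Diet statistics** — for occurrence counts `N_i` over `N`
  food-containing samples: frequency of occurrence `%FC_i = N_i / N`,
  proportion of occurrence `%TX_i = N_i / ΣN_j`, Levins' breadth
  `B = 1/Σp²` with standardized `B_A = (B−1)/(n−1)`, Shannon `H = −Σp ln p`,
  Pielou `J = H / ln n`, Pianka overlap
  `O_jk = Σp_j p_k / √(Σp_j² Σp_k²)` with a label-permutation test, Wilson
  score intervals, exact Wilcoxon signed-rank and Fisher r×c tests, and
  season/altitude stratification.
* **Pipeline** — `pipelineConfig()` / `runPipeline()` chain everything
  with a stage-by-stage filter ledger; `loadFelidDiet()` provides a
  packaged 40-taxon occurrence fixture from a two-felid montane-forest
  study (93 leopard cat and 10 Asiatic golden cat samples).

## Worked example

Dietary composition and niche breadth of the leopard cat from the packaged
occurrence fixture:

```r
library(scatdiet)
fx  <- loadFelidDiet()
lpc <- setNames(fx$lpc, fx$taxon)

round(100 * sort(percentFC(lpc, nSamples = attr(fx, "n_lpc")),
                 decreasing = TRUE)[1:4])
#>          Ochotona spp. Niviventer confucianus         Apodemus draco
#>                     76                     62                     44
#>   Eothenomys chinensis
#>                     38

nb <- levinsBA(lpc); sp <- shannonPielou(lpc)
c(B_A = round(nb$BA, 2), H = round(sp$H, 2), J = round(sp$J, 2))
#>  B_A    H    J
#> 0.27 2.78 0.77

round(100 * sort(tapply(fx$lpc, fx$taxon_order, sum) / sum(fx$lpc),
                 decreasing = TRUE)[1:3])
#>   Rodentia Lagomorpha  Carnivora
#>         51         19          7

wilsonInterval(71, 93)
#>     lower     upper
#> 0.6677083 0.8382734
```

Pikas occur in 76% of leopard cat samples and rodents contribute half of
all prey occurrences; the standardized niche breadth of 0.27 marks a diet
concentrated on a few small-mammal staples, while the golden cat's 0.64
(from `fx$agc`) reflects a broader, more even prey spectrum. The Wilson
interval brackets the pika frequency at roughly 67–84%.

A fully synthetic end-to-end run:

```r
cfg <- SimConfig(nSamples = 20, predator = "Prionailurus bengalensis",
                 taxaPool = felidTaxaPool()[c(1:10, 41, 43), ],
                 perBaseErrorRate = 0.005, tagJumpRate = 0.01, seed = 1)
res <- runPipeline(pipelineConfig(cfg))
res$ledger                                   # per-stage casualty counts
mean(jaccardRecovery(res$occurrence, res$sim$profiles))
```

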