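---
title: "Methods: faecal DNA metabarcoding diet analysis with scatdiet"
author: "scatdiet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: faecal DNA metabarcoding diet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

## The problem

Small and mid-sized carnivores are hard to observe hunting, and their scats
rarely contain identifiable hard remains. DNA metabarcoding solves this by
PCR-amplifying a short, taxonomically informative marker — here the ~100 bp
mitochondrial 12S V5 fragment, amplified with vertebrate-universal primers —
directly from faecal DNA, sequencing the amplicons at depth, and assigning
the resulting sequences to prey taxa. Three artefacts make the raw reads
unreliable: PCR/sequencing errors create spurious sequence variants,
cross-talk between multiplexed samples ("tag jumps") moves reads between
samples, and host (predator) DNA dominates the template unless it is
suppressed with a blocking oligonucleotide.

`scatdiet` implements the complete workflow: a synthetic-run generator that
emulates these artefacts, a read filter cascade, reference-based taxonomic
assignment refined by local species occurrence, per-sample contamination
filters, a collapse of sequences into discrete prey taxa, and dietary
composition and niche statistics. A packaged fixture of 40 prey taxa
recovered from 93 leopard cat and 10 Asiatic golden cat faecal samples in a
montane forest area of Southwest China anchors the numerical tests.

## The synthetic sequencing run

The generator (`SimConfig()`, `simulateRun()`) defines the study conditions
every downstream test runs under. Each sample draws 1–7 true prey taxa (the
range observed per faecal sample in the fixture study) from the taxon pool,
with within-sample proportions from a symmetric Dirichlet
(`abundanceSkew`, default 2 — moderately uneven diets). Proportions are
redrawn until every component exceeds `minProportion` (default 0.05): a prey
item contributing less than ~5% of the template is below what the
per-sample read filters are designed to detect, so the generator represents
detectable diet items only. Fragments carry the PCR's 9-nt tag (`CC` + 7
variable nucleotides, pairwise Hamming distance at least 3) on both ends
outside the primers; 100 nt are "sequenced" from each end, which fully
spans the insert, so mates overlap by roughly 45–65 nt.

Artefact model, one knob each:

* **Per-base error** (`perBaseErrorRate`): uniform substitutions on each
  mate; indels are excluded — the simplest model that exercises the
  denoiser. Qualities are two-level (Q40 everywhere, Q2 at error sites)
  rather than a learned platform profile.
* **Tag jumps** (`tagJumpRate`): a read's whole tag pair is replaced by
  that of a different PCR (including negative controls), the mechanism by
  which cross-sample contamination arises in multiplexed runs.
* **Host suppression** (`blockingEfficiency`): predator reads appear at
  `predatorShare * (1 - blockingEfficiency)` of the template;
  `predatorShare` defaults to 0.9 because host DNA dominates faecal
  extracts.
* **Contamination** (`contaminantRate`): human reads at a small share
  (default 0.005).
* **Negative controls**: template-free PCRs receiving only low-count
  background draws (Poisson, mean `controlReads = 20`, uniform over the
  pool) plus whatever tag jumps deliver — exactly what the
  negative-control filter is meant to subtract.

`readsPerSample` defaults to 3000. With the 5% proportion floor this puts
the rarest true diet item near 150 reads per sample, comfortably above the
50-read filter even after sequencing error halves the count of exact
template copies; real per-sample depths after demultiplexing are not
published for the fixture study, so this value is chosen for testability,
not fidelity. All randomness flows from a single seed; identical
configurations give byte-identical FASTQ output.

What the generator does **not** emulate: PCR chimeras, length-dependent
amplification bias, platform-specific quality profiles, degraded-DNA
fragmentation. Passing the recovery tests therefore shows the pipeline's
logic is correct under the stated noise model, not that it is robust to
every failure mode of real faecal data.

## The read filter cascade

`mergePairs()` aligns each forward mate against the reverse-complemented
reverse mate over every overlap of at least 10 nt and keeps the best
offset. The merge score is defined as *matches minus mismatches in the
overlap*, floored at zero (ties broken toward the larger overlap, then the
leftmost offset), so the downstream "score at least 40" cut requires a
substantial clean overlap; users recalibrating against other pairers
should note this definition. Consensus at a disagreement takes the
higher-quality base.

The cascade then applies, in order: alignment-score filtering
(`filterQuality()`, score < 40 removed), demultiplexing
(`demultiplex()`: both tags must match a registered pair exactly, both
primer sites with at most 2 mismatches; both orientations are tried; an N
in a tag disqualifies the exact match and an N in a primer site counts as
a mismatch), dereplication (`dereplicate()`), removal of sequences
shorter than 80 nt or with dataset-wide count below 1000
(`filterLengthCount()`), and denoising (`denoiseSeqs()`).

All removal thresholds are strict: a score of exactly 40, a length of
exactly 80 and a count of exactly 1000 are retained.

### Denoising

Within each PCR, a directed edge u → v is drawn when the two sequences
differ by exactly one substitution or one indel and
`count(v)/count(u) < 0.5`. A sequence that is a variant of another is
`internal`; a non-variant with variants is a `head`; an isolated sequence
is a `singleton`. Statuses are aggregated across PCRs by majority (ties
resolved toward retention) and internal sequences are discarded. Isolated
sequences are retained: a true template whose PCR produced no detectable
error variants must not be thrown away, as the noise-free recovery
invariant demands. Variant counts are reported, not merged into heads;
`mergeVariants = TRUE` enables one-step merging for users who prefer
abundance conservation.

## Reference database and taxonomic assignment

`inSilicoPcr()` extracts amplicons from source records wherever both
primer sites align with at most 3 mismatches and the insert falls in
[50, 150] nt — bounds chosen to admit the 12S V5 fragment family; the
mismatch allowance mirrors common in-silico PCR practice.

Sequence identity (`seqIdentity()`) is a global alignment maximizing
matches (match +1, mismatch 0, gaps free) with ties broken toward the
fewest alignment columns, and equals matches divided by alignment columns
including gap columns. Stating the denominator makes results reproducible
bit-for-bit; the tied best-hit set uses a 1e-9 identity tolerance.

`assignTaxa()` assigns the lowest common ancestor of the tied best hits.
`refineAssignments()` then applies three identity-threshold rules using
the local species list:

1. at least 98% identity to exactly one locally occurring species — that
   species;
2. at least 98% to several species — the single local member if exactly
   one, otherwise the lowest taxon containing **all local members** of the
   tied set (the reading that reproduces family-level outcomes such as
   babblers in the fixture);
3. maximum identity in [94%, 98%) — the lowest taxon containing all local
   top-identity species; when the single top hit is non-local, the most
   closely related local congener is substituted (always flagged in the
   output), several local congeners give the genus, and no congener walks
   up the top hit's lineage to the lowest rank containing any local
   species — which can terminate as high as an order, matching the
   "undetermined carnivore" fixture row.

Queries below 94% identity are discarded with a machine-readable reason.
Note that rule 2's single-local-member disambiguation intentionally
assigns below the provisional LCA's rank — that is the point of using
distribution knowledge — while rule 3's substitution is the only other
route below the LCA and is always flagged.

### Per-sample filtering and taxon collapse

`perSampleFilter()` zeroes a sequence's count in a sample when it is below
0.1% of the sample total **or** below 50 reads (the conservative OR
reading; an AND mode is available) **or** not above the maximum count of
that sequence across the negative controls ("not above" because exact
equality is treated as contamination-compatible, again the conservative
choice). Sequences assigned to the sample's predator or to human are
removed regardless of count. Samples left empty are flagged
`no_food` and excluded from all diet denominators.

`collapseTaxa()` single-links sequences at 2% divergence
(identity ≥ 0.98) — applied *after* the identity filter, since the
ordering is not otherwise determined — labels each cluster by its most
abundant member's assignment ("relative abundance" read as: the label
comes from the dominant sequence; an abundance-weighted consensus was
considered and not implemented), and splits clusters whose members carry
incompatible order-level assignments, with a warning.

## Dietary statistics

With `N_i` the number of food-containing samples holding taxon *i* and
`N` their total:

* `%FC_i = N_i / N` (sums can exceed 1);
* `%TX_i = N_i / sum_j N_j` (sums to 1); order-level `%TX` sums member
  taxon occurrences.

All niche indices use `p = %TX` at the discrete-taxon level — the choice is
validated by exact reproduction of the fixture's published index values
(B_A 0.27/0.64, H 2.78/2.80, J 0.77/0.93):

* Levins `B = 1 / sum(p^2)`, standardized `B_A = (B - 1)/(n - 1)`;
* Shannon `H = -sum(p log p)` (natural log), Pielou `J = H / log(n)`;
* Pianka `O_jk = sum(p_j p_k) / sqrt(sum(p_j^2) sum(p_k^2))`.

The Pianka permutation test shuffles sample group labels, recomputes the
group profiles and overlap, and reports
`p = (1 + #{O_perm >= O_obs}) / (nPerm + 1)`. A label-permutation null is
one defensible choice among several (EcoSim-style randomizations fix
different margins); the scheme and seed are recorded in the result.

`wilsonInterval()` inverts the binomial score test (equivalently
`prop.test(correct = FALSE)`), clamped to [0, 1]. The exact Wilcoxon
signed-rank test drops zero differences, midranks ties, and computes
`p = P(|V - mu| >= |v_obs - mu|)` over all `2^m` sign assignments via
convolution over doubled ranks — identical to full enumeration, which the
tests verify; normal mode uses the tie-corrected variance `sum(r^2)/4`
with a 0.5 continuity correction. `fisherExactRxC()` enumerates every
table with the observed margins (margin-bound pruning, relative tie
tolerance 1e-12) and falls over to an explicit resource error advising
the Monte Carlo mode (`r2dtable` sampling) beyond its enumeration budget.

Altitude classes follow the vegetation zones of the fixture study — low
(< 1500 m), lower-middle, higher-middle, high (> 2500 m) — with
left-closed intervals, so 1500 m itself is lower-middle; the published
wording leaves that boundary ambiguous. Seasons derive from collection
month (3–5 spring, 9–11 autumn); other months are excluded with a
warning. Reported percentages round to integers and indices to 2
decimals, matching the fixture's presentation; internal values keep full
precision.

## The packaged fixture

`loadFelidDiet()` returns the 40-taxon occurrence-count table (37 leopard
cat taxa summing to 381 occurrences; 20 golden cat taxa summing to 35; 17
shared; 29 species-rank assignments across 11 orders). Only **counts** are
stored — no per-sample matrix exists for this dataset — so statistics that
need per-sample data (mean taxa per faeces, seasonal or altitudinal
splits, overlap permutation tests) run only on synthetic or user data.
Two published percentages do not recompute from the stored counts
(a vole frequency printed as 40% where 35/93 gives 38%, and a pika-order
proportion printed as 18% where 71/381 gives 19%); they are presentation
discrepancies in the source material and are not used as reference values.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at 50 samples × 10 prey taxa ×
3000 reads per sample — large enough that every filter operates at its
design point, small enough for routine runs: noise-free runs must
reproduce the simulated diets *exactly*, and with 0.5% per-base error plus
1% tag jumps the mean per-sample Jaccard similarity between recovered and
true taxon sets over 20 independent runs must stay at or above 0.9.
Brute-force oracles (full offset scans, quadratic DP alignment, `2^m`
sign enumeration, full-table Fisher enumeration, pairwise edit-distance
classification) pin every exact computation on instances small enough to
enumerate.

Tie-breaking rules are stated everywhere a maximum is taken (merge
offsets, best-hit sets, cluster labels, denoiser majority votes) so that
results are platform-independent and reruns are bitwise reproducible.

## Known limitations

* The denoiser is single-linkage on one-difference edges; it does not
  model per-base error rates or chimeras, and long error chains can
  survive as separate heads when intermediate variants were filtered out
  earlier.
* Assignment quality is bounded by reference completeness: with a single
  reference per genus, congener substitution cannot distinguish sister
  species, mirroring the pika case in the fixture study.
* The Fisher enumeration is exponential in table size; the Monte Carlo
  mode is the intended path for large tables.
* The simulator's noise model is deliberately minimal (substitutions only,
  uniform rates); conclusions about real-data robustness require
  validation on real runs.
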