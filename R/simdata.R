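#' @include AllClasses.R
NULL

#' Generate a tag scheme for multiplexed PCRs
#'
#' Draws 9-nt tags of the form `CC` + seven variable nucleotides with
#' pairwise Hamming distance at least 3, one tag per PCR (used on both the
#' forward and the reverse primer of that PCR). Candidates are screened in a
#' seeded random order with a greedy distance filter.
#'
#' @param nPcrs Number of PCRs needing a unique tag (samples plus controls).
#' @param seed Integer seed; the scheme is deterministic given the seed.
#' @param nControls How many of the PCRs (the last ones) are negative
#'   controls; controls get ids `NC1`, `NC2`, ..., samples `S001`, ...
#' @return A [TagScheme].
#' @export
#' @examples
#' generateTagScheme(4, seed = 1, nControls = 1)
generateTagScheme <- function(nPcrs, seed = 1L, nControls = 0L) {
  nPcrs <- as.integer(nPcrs)
  if (nPcrs < 1L) sdStop("nPcrs must be >= 1", "scatdiet_config_error")
  bases <- c("A", "C", "G", "T")
  cand <- do.call(paste0, expand.grid(rep(list(bases), 7L),
                                      stringsAsFactors = FALSE))
  sel <- character(0)
  selMat <- NULL
  withSeed(seed, {
    cand <- sample(cand)
    for (tg in cand) {
      if (length(sel) >= nPcrs) break
      v <- strsplit(tg, "")[[1]]
      if (is.null(selMat)) {
        ok <- TRUE
      } else {
        d <- rowSums(selMat != matrix(v, nrow = nrow(selMat), ncol = 7L,
                                      byrow = TRUE))
        ok <- all(d >= 3L)
      }
      if (ok) {
        sel <- c(sel, tg)
        selMat <- rbind(selMat, v)
      }
    }
  })
  if (length(sel) < nPcrs)
    sdStop(sprintf(
      "only %d distance-3 tags with CC prefix available, %d requested",
      length(sel), nPcrs), "scatdiet_tag_capacity")
  tags <- paste0("CC", sel)
  nS <- nPcrs - nControls
  ids <- c(sprintf("S%03d", seq_len(nS)),
           if (nControls > 0L) paste0("NC", seq_len(nControls)))
  TagScheme(tags, tags, ids,
            is_control = c(rep(FALSE, nS), rep(TRUE, nControls)))
}

#' Generate a reference database from a taxon pool
#'
#' Builds one full-length reference record per pool species: the forward
#' primer site, a randomly drawn insert (unless a `sequence` column supplies
#' one), and the reverse-complemented reverse primer site. Deterministic
#' given `seed`.
#'
#' @param taxaPool Data frame with columns `species`, `genus`, `family`,
#'   `order`, `class` and optionally `sequence` (insert-only).
#' @param primers Named primer pair as from [v5Primers()].
#' @param insertLen Integer range of insert lengths for generated inserts.
#' @param seed Integer seed.
#' @return A `"source"`-type [ReferenceDb].
#' @export
generateReferenceDb <- function(taxaPool, primers = v5Primers(),
                                insertLen = c(80L, 100L), seed = 1L) {
  if (nrow(taxaPool) < 1L)
    sdStop("taxaPool must be nonempty", "scatdiet_config_error")
  if (anyDuplicated(taxaPool$species))
    sdStop(sprintf("duplicate species in taxa pool: %s",
                   taxaPool$species[duplicated(taxaPool$species)][1]),
           "scatdiet_duplicate_species")
  bases <- c("A", "C", "G", "T")
  inserts <- withSeed(seed, {
    vapply(seq_len(nrow(taxaPool)), function(i) {
      if ("sequence" %in% names(taxaPool) &&
          !is.na(taxaPool$sequence[i]) && nzchar(taxaPool$sequence[i]))
        return(taxaPool$sequence[i])
      len <- sample(insertLen[1]:insertLen[2], 1L)
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }, character(1))
  })
  recs <- paste0(primers["forward"], inserts, revcomp(primers["reverse"]))
  ids <- gsub(" ", "_", taxaPool$species)
  tx <- data.frame(record_id = ids,
                   taxaPool[, TAX_RANKS, drop = FALSE],
                   stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  ReferenceDb(setNames(DNAStringSet(recs), ids), tx, type = "source")
}

#' Prey taxon pool modelled on two sympatric montane felid diets
#'
#' Forty vertebrate taxa (rodents, pikas, carnivores, pheasants, passerines,
#' shrews, ungulates, primates, a duck, a skink and a carp; 11 orders across
#' mammals, birds, one reptile and one fish) representative of the prey
#' spectrum of leopard cat and Asiatic golden cat in the mountain forests of
#' Southwest China. Non-species-level diet categories are represented by a
#' single member species so that every pool entry carries a full lineage.
#'
#' @param includeExtras Also append the two host felids and *Homo sapiens*
#'   (needed to simulate host and contaminant reads).
#' @return Data frame with columns `species`, `genus`, `family`, `order`,
#'   `class`.
#' @export
felidTaxaPool <- function(includeExtras = TRUE) {
  sp <- function(species, genus, family, order, class)
    data.frame(species = species, genus = genus, family = family,
               order = order, class = class, stringsAsFactors = FALSE)
  pool <- rbind(
    sp("Niviventer confucianus", "Niviventer", "Muridae", "Rodentia", "Mammalia"),
    sp("Apodemus draco", "Apodemus", "Muridae", "Rodentia", "Mammalia"),
    sp("Eothenomys chinensis", "Eothenomys", "Cricetidae", "Rodentia", "Mammalia"),
    sp("Niviventer excelsior", "Niviventer", "Muridae", "Rodentia", "Mammalia"),
    sp("Eothenomys melanogaster", "Eothenomys", "Cricetidae", "Rodentia", "Mammalia"),
    sp("Apodemus chevrieri", "Apodemus", "Muridae", "Rodentia", "Mammalia"),
    sp("Leopoldamys edwardsi", "Leopoldamys", "Muridae", "Rodentia", "Mammalia"),
    sp("Trogopterus xanthipes", "Trogopterus", "Sciuridae", "Rodentia", "Mammalia"),
    sp("Rhizomys sinensis", "Rhizomys", "Spalacidae", "Rodentia", "Mammalia"),
    sp("Sciurotamias davidianus", "Sciurotamias", "Sciuridae", "Rodentia", "Mammalia"),
    sp("Apodemus peninsulae", "Apodemus", "Muridae", "Rodentia", "Mammalia"),
    sp("Hystrix brachyura", "Hystrix", "Hystricidae", "Rodentia", "Mammalia"),
    sp("Dremomys pernyi", "Dremomys", "Sciuridae", "Rodentia", "Mammalia"),
    sp("Ochotona curzoniae", "Ochotona", "Ochotonidae", "Lagomorpha", "Mammalia"),
    sp("Mustela sibirica", "Mustela", "Mustelidae", "Carnivora", "Mammalia"),
    sp("Panthera tigris", "Panthera", "Felidae", "Carnivora", "Mammalia"),
    sp("Tragopan temminckii", "Tragopan", "Phasianidae", "Galliformes", "Aves"),
    sp("Gallus gallus", "Gallus", "Phasianidae", "Galliformes", "Aves"),
    sp("Chrysolophus pictus", "Chrysolophus", "Phasianidae", "Galliformes", "Aves"),
    sp("Bambusicola thoracicus", "Bambusicola", "Phasianidae", "Galliformes", "Aves"),
    sp("Hirundo rustica", "Hirundo", "Hirundinidae", "Passeriformes", "Aves"),
    sp("Alcippe morrisonia", "Alcippe", "Timaliidae", "Passeriformes", "Aves"),
    sp("Prinia inornata", "Prinia", "Cisticolidae", "Passeriformes", "Aves"),
    sp("Turdus merula", "Turdus", "Turdidae", "Passeriformes", "Aves"),
    sp("Alcippe chrysotis", "Alcippe", "Timaliidae", "Passeriformes", "Aves"),
    sp("Yuhina nigrimenta", "Yuhina", "Timaliidae", "Passeriformes", "Aves"),
    sp("Episoriculus macrurus", "Episoriculus", "Soricidae", "Soricomorpha", "Mammalia"),
    sp("Sorex cylindricauda", "Sorex", "Soricidae", "Soricomorpha", "Mammalia"),
    sp("Scaptonyx fusicaudus", "Scaptonyx", "Talpidae", "Soricomorpha", "Mammalia"),
    sp("Uropsilus soricipes", "Uropsilus", "Talpidae", "Soricomorpha", "Mammalia"),
    sp("Blarina brevicauda", "Blarina", "Soricidae", "Soricomorpha", "Mammalia"),
    sp("Sus scrofa", "Sus", "Suidae", "Artiodactyla", "Mammalia"),
    sp("Budorcas taxicolor", "Budorcas", "Bovidae", "Artiodactyla", "Mammalia"),
    sp("Naemorhedus griseus", "Naemorhedus", "Bovidae", "Artiodactyla", "Mammalia"),
    sp("Moschus berezovskii", "Moschus", "Moschidae", "Artiodactyla", "Mammalia"),
    sp("Rhinopithecus roxellana", "Rhinopithecus", "Cercopithecidae", "Primates", "Mammalia"),
    sp("Macaca mulatta", "Macaca", "Cercopithecidae", "Primates", "Mammalia"),
    sp("Anas crecca", "Anas", "Anatidae", "Anseriformes", "Aves"),
    sp("Plestiodon capito", "Plestiodon", "Scincidae", "Lacertiformes", "Reptilia"),
    sp("Ctenopharyngodon idella", "Ctenopharyngodon", "Cyprinidae", "Cypriniformes", "Actinopterygii"))
  if (includeExtras) {
    pool <- rbind(pool,
      sp("Prionailurus bengalensis", "Prionailurus", "Felidae", "Carnivora", "Mammalia"),
      sp("Catopuma temminckii", "Catopuma", "Felidae", "Carnivora", "Mammalia"),
      sp("Homo sapiens", "Homo", "Hominidae", "Primates", "Mammalia"))
  }
  pool
}

#' Synthetic 16S diagnostic fragments for predator identification
#'
#' Deterministically generated stand-in fragments of the predator-diagnostic
#' mitochondrial 16S marker: a leopard cat fragment and an Asiatic golden cat
#' fragment differing from it at exactly 15 nucleotide positions. These are
#' synthetic sequences, not database records; they only support testing of
#' the identity-threshold assignment rule.
#'
#' @param length Fragment length in nt.
#' @return Named [Biostrings::DNAStringSet] with one fragment per felid.
#' @export
predatorRefs16S <- function(length = 150L) {
  bases <- c("A", "C", "G", "T")
  withSeed(20170214L, {
    lpc <- sample(bases, length, replace = TRUE)
    agc <- lpc
    at <- sample(length, 15L)
    for (i in at) {
      agc[i] <- sample(setdiff(bases, lpc[i]), 1L)
    }
    DNAStringSet(setNames(
      c(paste(lpc, collapse = ""), paste(agc, collapse = "")),
      c("Prionailurus bengalensis", "Catopuma temminckii")))
  })
}

dirichletWithFloor <- function(k, skew, floor) {
  if (k == 1L) return(1)
  for (i in seq_len(200L)) {
    g <- rgamma(k, shape = skew)
    p <- g / sum(g)
    if (all(p >= floor)) return(p)
  }
  p <- pmax(p, floor)
  p / sum(p)
}

# locate exact primer sites in a source record; returns tag-less amplicon
# (fwd primer .. revcomp(rev primer) inclusive)
extractTemplate <- function(record, primers, record_id) {
  f <- regexpr(primers[["forward"]], record, fixed = TRUE)
  rsite <- revcomp(primers[["reverse"]])
  r <- regexpr(rsite, record, fixed = TRUE)
  if (f < 0 || r < 0 || r <= f)
    sdStop(sprintf("reference record '%s' lacks a primer site", record_id),
           "scatdiet_missing_primer")
  substr(record, f, r + nchar(rsite) - 1L)
}

#' Simulate a tagged paired-end metabarcoding run
#'
#' Generates the full synthetic study: per-sample diet profiles (Dirichlet
#' proportions over a random subset of prey taxa), amplicon fragments
#' carrying the PCR's 9-nt tags and the 12S V5 primer sites, paired 100-nt
#' mates with per-base substitution errors, tag jumps that move a read's tag
#' pair to a different PCR, host (predator) reads attenuated by the blocking
#' oligonucleotide, human contaminant reads, and template-free negative
#' controls receiving only contaminant and tag-jumped reads. Mates are
#' written as Phred+33 FASTQ; qualities follow a two-level model (Q40
#' everywhere, Q2 at simulated error sites).
#'
#' @param config A [SimConfig].
#' @param scheme A [TagScheme] with at least `nSamples` sample PCRs and
#'   `nNegControls` control PCRs.
#' @param refdb A `"source"`-type [ReferenceDb] containing every pool
#'   species (including the predator and *Homo sapiens* when host or
#'   contaminant reads are simulated).
#' @param outDir Output directory (created if missing).
#' @param primers Primer pair used to locate the insert in each record.
#' @return Invisibly, a list with the FASTQ paths (`r1`, `r2`), the
#'   tag-map/metadata/diet-profile TSV paths, the ground-truth read log
#'   (`truth`: read id, true PCR, carried PCR, taxon), the per-sample
#'   `profiles`, the sample `metadata`, and per-PCR read totals.
#' @export
simulateRun <- function(config, scheme, refdb, outDir,
                        primers = v5Primers()) {
  validObject(config)
  validObject(scheme)
  p <- tagPairs(scheme)
  sampleRows <- which(!p$is_control)
  controlRows <- which(p$is_control)
  if (length(sampleRows) < config@nSamples ||
      length(controlRows) < config@nNegControls)
    sdStop("tag scheme does not cover all samples and negative controls",
           "scatdiet_config_error")
  sampleRows <- sampleRows[seq_len(config@nSamples)]
  controlRows <- controlRows[seq_len(config@nNegControls)]
  sampleIds <- p$pcr_id[sampleRows]
  controlIds <- p$pcr_id[controlRows]
  allIds <- c(sampleIds, controlIds)
  tagOf <- setNames(p$forward, p$pcr_id)

  tx <- refTaxonomy(refdb)
  poolSpecies <- config@taxaPool$species
  preySpecies <- setdiff(poolSpecies, c(config@predator, "Homo sapiens"))
  wPred <- config@predatorShare * (1 - config@blockingEfficiency)
  wCont <- config@contaminantRate
  needed <- unique(c(preySpecies,
                     if (config@predatorShare > 0) config@predator,
                     if (wCont > 0) "Homo sapiens",
                     # controls draw uniformly from the whole pool
                     if (config@nNegControls > 0 && config@controlReads > 0)
                       poolSpecies))
  missing <- setdiff(needed, tx$species)
  if (length(missing))
    sdStop(sprintf("species missing from reference db: %s",
                   paste(missing, collapse = ", ")),
           "scatdiet_config_error")
  recOf <- setNames(as.character(seqs(refdb)), tx$species)[needed]
  template <- vapply(needed, function(s)
    extractTemplate(recOf[[s]], primers, s), character(1))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  L <- config@readLength

  set.seed(config@seed)
  profiles <- list()
  meta <- list()
  taxonV <- character(0); trueV <- character(0)
  for (si in seq_along(sampleIds)) {
    sid <- sampleIds[si]
    k <- if (config@taxaPerSample[1] == config@taxaPerSample[2])
      config@taxaPerSample[1] else
        sample(config@taxaPerSample[1]:config@taxaPerSample[2], 1L)
    taxa <- sample(preySpecies, k)
    props <- dirichletWithFloor(k, config@abundanceSkew, config@minProportion)
    profiles[[sid]] <- data.frame(sample_id = sid, taxon = taxa,
                                  proportion = props,
                                  stringsAsFactors = FALSE)
    season <- sample(c("spring", "autumn"), 1L, prob = c(0.65, 0.35))
    meta[[sid]] <- data.frame(
      sample_id = sid, predator = config@predator, season = season,
      month = if (season == "spring") sample(3:5, 1L) else sample(9:11, 1L),
      altitude_m = round(runif(1, 1250, 3200)),
      latitude = round(runif(1, 32.43, 32.60), 5),
      longitude = round(runif(1, 104.55, 104.75), 5),
      stringsAsFactors = FALSE)
    cats <- c(taxa, "__predator__", "__contaminant__")
    w <- c((1 - config@predatorShare - wCont) * props, wPred, wCont)
    cnt <- as.vector(rmultinom(1, config@readsPerSample, w))
    catSpecies <- c(taxa, config@predator, "Homo sapiens")
    taxonV <- c(taxonV, rep(catSpecies, cnt))
    trueV <- c(trueV, rep(sid, sum(cnt)))
  }
  for (cid in controlIds) {
    nr <- rpois(1, config@controlReads)
    if (nr > 0) {
      taxonV <- c(taxonV, sample(poolSpecies, nr, replace = TRUE))
      trueV <- c(trueV, rep(cid, nr))
    }
  }
  nReads <- length(taxonV)
  carried <- trueV
  jumped <- runif(nReads) < config@tagJumpRate
  if (any(jumped) && length(allIds) > 1L) {
    carried[jumped] <- vapply(trueV[jumped], function(tp)
      sample(setdiff(allIds, tp), 1L), character(1))
  } else {
    jumped[] <- FALSE
  }

  tag <- tagOf[carried]
  frag <- paste0(tag, template[taxonV], revcomp(tag))
  m1 <- substr(frag, 1L, L)
  m2 <- substr(revcomp(frag), 1L, L)
  e1 <- cpp_add_errors(m1, config@perBaseErrorRate)
  e2 <- cpp_add_errors(m2, config@perBaseErrorRate)
  qualWithErrors <- function(seqsC, posList) {
    q <- strrep("I", nchar(seqsC))
    hit <- which(lengths(posList) > 0L)
    for (i in hit) for (j in posList[[i]]) substr(q[i], j, j) <- "#"
    q
  }
  q1 <- qualWithErrors(e1$sequence, e1$positions)
  q2 <- qualWithErrors(e2$sequence, e2$positions)
  ids <- sprintf("read%07d", seq_len(nReads))

  r1 <- file.path(outDir, "reads_R1.fastq")
  r2 <- file.path(outDir, "reads_R2.fastq")
  writeXStringSet(setNames(DNAStringSet(e1$sequence), ids), r1,
                  format = "fastq", qualities = BStringSet(q1))
  writeXStringSet(setNames(DNAStringSet(e2$sequence), ids), r2,
                  format = "fastq", qualities = BStringSet(q2))

  tagmap <- p[c(sampleRows, controlRows),
              c("forward", "reverse", "pcr_id", "is_control")]
  profiles <- do.call(rbind, profiles)
  meta <- do.call(rbind, meta)
  rownames(profiles) <- rownames(meta) <- rownames(tagmap) <- NULL
  tagmapFile <- file.path(outDir, "tagmap.tsv")
  metaFile <- file.path(outDir, "metadata.tsv")
  profFile <- file.path(outDir, "diet_profiles.tsv")
  write.table(tagmap, tagmapFile, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(meta, metaFile, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(profiles, profFile, sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(list(
    r1 = r1, r2 = r2, tagmap = tagmapFile, metadataFile = metaFile,
    profilesFile = profFile,
    truth = data.frame(read_id = ids, true_pcr = trueV,
                       carried_pcr = carried, taxon = taxonV,
                       jumped = jumped, stringsAsFactors = FALSE),
    profiles = profiles, metadata = meta,
    sampleIds = sampleIds, controlIds = controlIds, nReads = nReads))
}
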