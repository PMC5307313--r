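#' @include AllClasses.R
NULL

#' Extract reference amplicons by in-silico PCR
#'
#' Scans each source record for the forward primer and the
#' reverse-complemented reverse primer, each with at most `maxMismatch`
#' mismatches (no indels), and emits one amplicon record per site pair
#' whose insert length falls within `insertLen`. Primers are excluded from
#' the stored amplicon. Records with no amplifiable site pair are skipped
#' and counted in the `skipped` attribute.
#'
#' @param refdb A `"source"`-type [ReferenceDb] (or a named
#'   [Biostrings::DNAStringSet] plus a `taxonomy` data frame).
#' @param primers Primer pair as from [v5Primers()].
#' @param maxMismatch Maximum mismatches tolerated per primer site.
#' @param insertLen Admissible insert length range (nt), inclusive.
#' @param taxonomy Taxonomy table when `refdb` is a plain `DNAStringSet`.
#' @return An `"amplicon"`-type [ReferenceDb]; record ids are
#'   `<source id>_<k>` for the k-th amplicon of a source record.
#' @export
inSilicoPcr <- function(refdb, primers = v5Primers(), maxMismatch = 3L,
                        insertLen = c(50L, 150L), taxonomy = NULL) {
  if (is(refdb, "ReferenceDb")) {
    sq <- seqs(refdb)
    taxonomy <- refTaxonomy(refdb)
  } else {
    sq <- refdb
    if (is.null(taxonomy))
      sdStop("taxonomy required when refdb is not a ReferenceDb",
             "scatdiet_config_error")
  }
  fwd <- primers[["forward"]]
  rcRev <- revcomp(primers[["reverse"]])
  outSeq <- character(0)
  outId <- character(0)
  outRow <- integer(0)
  outSrcLen <- integer(0)
  skipped <- character(0)
  for (i in seq_along(sq)) {
    s <- sq[[i]]
    fHits <- matchPattern(fwd, s, max.mismatch = maxMismatch,
                          with.indels = FALSE)
    rHits <- matchPattern(rcRev, s, max.mismatch = maxMismatch,
                          with.indels = FALSE)
    k <- 0L
    for (fi in seq_along(fHits)) {
      for (ri in seq_along(rHits)) {
        insStart <- BiocGenerics::end(fHits)[fi] + 1L
        insEnd <- BiocGenerics::start(rHits)[ri] - 1L
        len <- insEnd - insStart + 1L
        if (len >= insertLen[1] && len <= insertLen[2]) {
          k <- k + 1L
          outSeq <- c(outSeq, as.character(s[insStart:insEnd]))
          outId <- c(outId, sprintf("%s_%d", names(sq)[i], k))
          outRow <- c(outRow, i)
          outSrcLen <- c(outSrcLen, length(s))
        }
      }
    }
    if (k == 0L) skipped <- c(skipped, names(sq)[i])
  }
  if (length(skipped))
    message(sprintf("inSilicoPcr: %d record(s) without amplifiable sites: %s",
                    length(skipped),
                    paste(head(skipped, 5L), collapse = ", ")))
  tx <- data.frame(record_id = outId,
                   taxonomy[outRow, TAX_RANKS, drop = FALSE],
                   source_length = outSrcLen,
                   stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  out <- ReferenceDb(setNames(DNAStringSet(outSeq), outId), tx,
                     type = "amplicon")
  attr(out, "skipped") <- skipped
  out
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch style global alignment maximizing the number of matches
#' (match +1, mismatch 0, gaps free), breaking score ties by the minimum
#' number of alignment columns so substitutions are preferred over paired
#' indels. Identity is matches divided by alignment columns (gap columns
#' included); the measure is symmetric.
#'
#' @param a,b Sequences (character or [Biostrings::DNAString]).
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' seqIdentity("ACGTACGT", "ACGTACGT")  # 1
#' seqIdentity("AAAA", "AAAT")          # 0.75
seqIdentity <- function(a, b) {
  cpp_identity(as.character(a), as.character(b))
}

# ranks above `rank` in the lineage hierarchy, inclusive
ranksFrom <- function(rank) {
  TAX_RANKS[seq(match(rank, TAX_RANKS), length(TAX_RANKS))]
}

# unique species-level lineage table
speciesLineages <- function(taxonomy) {
  unique(taxonomy[, TAX_RANKS, drop = FALSE])
}

# lowest common ancestor of a species set within a taxonomy table
lcaOfSpecies <- function(speciesSet, taxonomy) {
  lin <- speciesLineages(taxonomy)
  rows <- lin[lin$species %in% speciesSet, , drop = FALSE]
  if (nrow(rows) < length(unique(speciesSet)))
    sdStop(sprintf("species absent from taxonomy: %s",
                   paste(setdiff(speciesSet, lin$species), collapse = ", ")),
           "scatdiet_config_error")
  for (r in TAX_RANKS) {
    u <- unique(rows[[r]])
    if (length(u) == 1L) return(list(taxon = u, rank = r))
  }
  list(taxon = "Vertebrata", rank = "root")
}

# the order containing a taxon assigned at `rank`, NA when undefined
orderOfTaxon <- function(taxon, rank, taxonomy) {
  if (is.na(taxon) || is.na(rank)) return(NA_character_)
  if (rank == "order") return(taxon)
  if (!rank %in% TAX_RANKS || match(rank, TAX_RANKS) > match("order", TAX_RANKS))
    return(NA_character_)
  lin <- speciesLineages(taxonomy)
  hit <- lin$order[lin[[rank]] == taxon]
  if (length(hit)) hit[1] else NA_character_
}

#' Assign a provisional taxon to each query by identity and LCA
#'
#' Computes the global alignment identity of every query against every
#' amplicon record, takes the best-identity hit set (all species within a
#' `tieTol` tolerance of the maximum), and assigns the lowest common
#' ancestor of that set as the provisional taxon.
#'
#' @param queries Named character vector, [Biostrings::DNAStringSet], or
#'   [UniqueSeqSet] of query sequences.
#' @param refdb An `"amplicon"`-type [ReferenceDb]; must be nonempty.
#' @param tieTol Identity tolerance defining the tied best-hit set.
#' @return Data frame with `query_id`, `taxon`, `rank`, `identity`,
#'   `n_best` and a list-column `best_species`.
#' @export
assignTaxa <- function(queries, refdb, tieTol = 1e-9) {
  if (is(queries, "UniqueSeqSet"))
    queries <- setNames(as.character(seqs(queries)), names(seqs(queries)))
  else if (is(queries, "DNAStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  if (length(seqs(refdb)) == 0L)
    sdStop("reference database is empty", "scatdiet_config_error")
  if (is.null(names(queries)))
    names(queries) <- sprintf("q%04d", seq_along(queries))
  tx <- refTaxonomy(refdb)
  idm <- cpp_identity_matrix(unname(queries), as.character(seqs(refdb)))
  res <- lapply(seq_along(queries), function(i) {
    ids <- idm[i, ]
    best <- max(ids)
    bset <- sort(unique(tx$species[ids >= best - tieTol]))
    lca <- lcaOfSpecies(bset, tx)
    list(taxon = lca$taxon, rank = lca$rank, identity = best,
         best_species = bset)
  })
  data.frame(query_id = names(queries),
             taxon = vapply(res, `[[`, character(1), "taxon"),
             rank = vapply(res, `[[`, character(1), "rank"),
             identity = vapply(res, `[[`, numeric(1), "identity"),
             n_best = vapply(res, function(z) length(z$best_species),
                             integer(1)),
             best_species = I(lapply(res, `[[`, "best_species")),
             stringsAsFactors = FALSE)
}

# resolution when no best-hit species is locally occurring: substitute the
# closest local congener of a single top hit, otherwise ascend the top-hit
# lineage to the lowest rank containing a local species
resolveNonLocal <- function(bestSet, taxonomy, localSpecies) {
  lin <- speciesLineages(taxonomy)
  if (length(bestSet) == 1L) {
    g <- lin$genus[lin$species == bestSet][1]
    cong <- setdiff(lin$species[lin$genus == g & lin$species %in% localSpecies],
                    bestSet)
    if (length(cong) == 1L)
      return(list(taxon = cong, rank = "species", substituted = TRUE))
    if (length(cong) > 1L)
      return(list(taxon = g, rank = "genus", substituted = TRUE))
  }
  base <- lcaOfSpecies(bestSet, taxonomy)
  if (base$rank == "root")
    return(list(taxon = "Vertebrata", rank = "root", substituted = FALSE))
  chain <- lin[lin$species == bestSet[1], , drop = FALSE]
  localLin <- lin[lin$species %in% localSpecies, , drop = FALSE]
  for (r in ranksFrom(base$rank)) {
    taxonAtR <- chain[[r]][1]
    if (any(localLin[[r]] == taxonAtR))
      return(list(taxon = taxonAtR, rank = r, substituted = FALSE))
  }
  list(taxon = "Vertebrata", rank = "root", substituted = FALSE)
}

#' Refine provisional assignments with local species occurrence
#'
#' Applies the three identity-threshold assignment criteria:
#' \describe{
#'   \item{rule 1}{identity >= `speciesMin` to exactly one locally
#'     occurring species: that species is assigned.}
#'   \item{rule 2}{identity >= `speciesMin` to several species: the single
#'     local member if there is exactly one, otherwise the lowest taxon
#'     containing all local members of the tied set.}
#'   \item{rule 3}{maximum identity in `[lowMin, speciesMin)`: the lowest
#'     taxon containing all local species among the top-identity hits;
#'     when the single top hit is non-local, the most closely related
#'     local congener is substituted (flagged), otherwise the lowest
#'     containing taxon with any local species.}
#' }
#' Queries below `lowMin` identity are discarded
#' (`rule = "discarded_low_identity"`).
#'
#' @param assignments Output of [assignTaxa()].
#' @param localSpecies Character vector of locally occurring species.
#' @param taxonomy Taxonomy table (as from [refTaxonomy()]).
#' @param speciesMin Identity required for a species-level assignment.
#' @param lowMin Identity below which a query is discarded.
#' @return The input data frame with `taxon`, `rank` replaced by the
#'   refined assignment plus columns `rule` and `substituted`.
#' @export
refineAssignments <- function(assignments, localSpecies, taxonomy,
                              speciesMin = 0.98, lowMin = 0.94) {
  lin <- speciesLineages(taxonomy)
  bad <- setdiff(localSpecies, lin$species)
  if (length(bad))
    sdStop(sprintf("local species absent from taxonomy: %s",
                   paste(bad, collapse = ", ")),
           "scatdiet_config_error")
  out <- assignments
  out$rule <- NA_character_
  out$substituted <- FALSE
  for (i in seq_len(nrow(out))) {
    id <- out$identity[i]
    S <- out$best_species[[i]]
    if (id < lowMin) {
      out$taxon[i] <- NA_character_
      out$rank[i] <- NA_character_
      out$rule[i] <- "discarded_low_identity"
      next
    }
    L <- intersect(S, localSpecies)
    if (id >= speciesMin) {
      if (length(L) == 1L) {
        out$taxon[i] <- L
        out$rank[i] <- "species"
        out$rule[i] <- if (length(S) == 1L) "1" else "2"
      } else if (length(L) > 1L) {
        lca <- lcaOfSpecies(L, taxonomy)
        out$taxon[i] <- lca$taxon
        out$rank[i] <- lca$rank
        out$rule[i] <- "2"
      } else {
        r <- resolveNonLocal(S, taxonomy, localSpecies)
        out$taxon[i] <- r$taxon
        out$rank[i] <- r$rank
        out$rule[i] <- "2"
        out$substituted[i] <- r$substituted
      }
    } else {
      if (length(L) >= 1L) {
        lca <- lcaOfSpecies(L, taxonomy)
        out$taxon[i] <- lca$taxon
        out$rank[i] <- lca$rank
      } else {
        r <- resolveNonLocal(S, taxonomy, localSpecies)
        out$taxon[i] <- r$taxon
        out$rank[i] <- r$rank
        out$substituted[i] <- r$substituted
      }
      out$rule[i] <- "3"
    }
  }
  out
}

#' Per-sample low-frequency, negative-control and non-prey filtering
#'
#' Within each sample, a sequence's count is zeroed when it is below
#' `minFrac` of the sample total, below `minReads`, or not above the
#' maximum count of that sequence across the negative controls (likely
#' cross-contamination or tag jumps). Sequences assigned to the sample's
#' predator or to human are removed regardless of count. Samples with no
#' remaining reads are flagged `no_food` and excluded from diet
#' denominators downstream.
#'
#' @param uss A [UniqueSeqSet] whose count columns include the negative
#'   controls.
#' @param assignments Refined assignment table matching the sequences
#'   (`query_id` equal to the sequence names).
#' @param controlIds Count columns that are negative controls.
#' @param predator Predator species, either a single name or a vector
#'   named by sample id.
#' @param minFrac Minimum within-sample frequency retained.
#' @param minReads Minimum within-sample count retained.
#' @param combine `"or"` (default, conservative: either low-frequency
#'   condition removes) or `"and"` (both must hold).
#' @param humanSpecies Taxon name treated as human contamination.
#' @return List with `uss` (filtered sequences, control columns dropped),
#'   `noFood` (sample ids with nothing left), and `log` (per-stage removal
#'   tallies).
#' @export
perSampleFilter <- function(uss, assignments, controlIds, predator,
                            minFrac = 0.001, minReads = 50L,
                            combine = c("or", "and"),
                            humanSpecies = "Homo sapiens") {
  combine <- match.arg(combine)
  cnt <- seqCounts(uss)
  stopifnot(identical(rownames(cnt), assignments$query_id))
  sampleIds <- setdiff(colnames(cnt), controlIds)
  negMax <- if (length(intersect(controlIds, colnames(cnt))))
    apply(cnt[, intersect(controlIds, colnames(cnt)), drop = FALSE], 1L, max)
  else rep(0L, nrow(cnt))
  predOf <- if (is.null(names(predator)))
    setNames(rep(predator[1], length(sampleIds)), sampleIds)
  else predator[sampleIds]
  out <- cnt[, sampleIds, drop = FALSE]
  nLow <- 0L; nNeg <- 0L; nNonPrey <- 0L
  for (s in sampleIds) {
    v <- out[, s]
    tot <- sum(v)
    if (tot == 0) next
    lowFrac <- v < minFrac * tot
    lowReads <- v < minReads
    low <- if (combine == "or") (lowFrac | lowReads) else (lowFrac & lowReads)
    neg <- v <= negMax
    nonPrey <- assignments$taxon %in% c(predOf[[s]], humanSpecies)
    drop <- v > 0 & (low | neg | nonPrey)
    nLow <- nLow + sum(v > 0 & low)
    nNeg <- nNeg + sum(v > 0 & !low & neg)
    nNonPrey <- nNonPrey + sum(v > 0 & !low & !neg & nonPrey)
    v[drop] <- 0L
    out[, s] <- v
  }
  noFood <- sampleIds[colSums(out) == 0]
  keep <- rowSums(out) > 0
  ussOut <- UniqueSeqSet(seqs(uss)[keep], out[keep, , drop = FALSE],
                         seqStatus(uss)[keep])
  list(uss = ussOut, noFood = noFood,
       assignments = assignments[keep, , drop = FALSE],
       log = data.frame(
         reason = c("low_frequency", "negative_control", "non_prey",
                    "sequences_dropped"),
         n = c(nLow, nNeg, nNonPrey, sum(!keep))))
}

#' Collapse unique sequences into discrete prey taxa
#'
#' Single-linkage clusters over sequence pairs with identity at least
#' `1 - divergence`; each cluster becomes one discrete taxon labelled by
#' the assignment of its highest-total-count member, and a sample contains
#' the taxon when any member sequence is present in it. Clusters whose
#' members carry incompatible order-level assignments are split by
#' assignment with a warning.
#'
#' @param uss A filtered, assigned [UniqueSeqSet] (sample columns only).
#' @param assignments Refined assignment table matching the sequences.
#' @param taxonomy Taxonomy table used to resolve the order of each
#'   assigned taxon.
#' @param divergence Maximum sequence divergence within a taxon.
#' @return List with `taxa` (taxon, rank, taxon_order, n_seqs,
#'   total_count), `presence` (binary taxa x samples matrix), `counts`
#'   (summed member counts) and `membership` (cluster index per sequence).
#' @export
collapseTaxa <- function(uss, assignments, taxonomy, divergence = 0.02) {
  sq <- as.character(seqs(uss))
  cnt <- seqCounts(uss)
  n <- length(sq)
  if (n == 0L)
    return(list(taxa = data.frame(), presence = matrix(0, 0, ncol(cnt)),
                counts = matrix(0, 0, ncol(cnt)), membership = integer(0)))
  stopifnot(identical(rownames(cnt), assignments$query_id))
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    idm <- cpp_identity_matrix(sq, sq)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (idm[i, j] >= 1 - divergence) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  ord <- vapply(seq_len(n), function(i)
    orderOfTaxon(assignments$taxon[i], assignments$rank[i], taxonomy),
    character(1))
  # split clusters mixing distinct known orders
  cl <- paste0("c", match(root, unique(root)))
  for (r in unique(root)) {
    members <- which(root == r)
    os <- unique(na.omit(ord[members]))
    if (length(os) > 1L) {
      warning(sprintf(
        "cluster with incompatible orders (%s) split by assignment",
        paste(os, collapse = ", ")))
      topOrd <- ord[members[which.max(rowSums(cnt)[members])]]
      sub <- ifelse(is.na(ord[members]), topOrd, ord[members])
      cl[members] <- paste0(cl[members], "_", match(sub, os))
    }
  }
  clusters <- unique(cl)
  tot <- rowSums(cnt)
  taxa <- do.call(rbind, lapply(clusters, function(cc) {
    members <- which(cl == cc)
    topM <- members[which.max(tot[members])]
    data.frame(taxon = assignments$taxon[topM],
               rank = assignments$rank[topM],
               taxon_order = ord[topM],
               n_seqs = length(members),
               total_count = sum(cnt[members, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  counts <- do.call(rbind, lapply(clusters, function(cc)
    colSums(cnt[cl == cc, , drop = FALSE])))
  rownames(taxa) <- rownames(counts) <- make.unique(taxa$taxon)
  presence <- (counts > 0) + 0
  list(taxa = taxa, presence = presence, counts = counts,
       membership = match(cl, clusters))
}

#' Identify the predator species of a sample from its 16S consensus
#'
#' The best-identity predator reference at or above `minIdentity` gives
#' the predator call; below the threshold the call is `"unknown"`, and two
#' references tied within `tieTol` give `"ambiguous"` (with a warning).
#'
#' @param queries Character vector or [Biostrings::DNAStringSet] of one
#'   dominant 16S consensus sequence per sample.
#' @param refs Named [Biostrings::DNAStringSet] of predator reference
#'   fragments (e.g. [predatorRefs16S()]).
#' @param minIdentity Minimum identity for a species call.
#' @param tieTol Identity tolerance declaring a tie.
#' @return Character vector of predator species, `"unknown"` or
#'   `"ambiguous"`.
#' @export
identifyPredator <- function(queries, refs, minIdentity = 0.98,
                             tieTol = 1e-9) {
  queries <- as.character(queries)
  refsC <- as.character(refs)
  idm <- cpp_identity_matrix(queries, unname(refsC))
  vapply(seq_along(queries), function(i) {
    ids <- idm[i, ]
    best <- max(ids)
    if (best < minIdentity) return("unknown")
    tied <- names(refsC)[ids >= best - tieTol]
    if (length(unique(tied)) > 1L) {
      warning("query ", i, " matches several predator references equally")
      return("ambiguous")
    }
    tied[1]
  }, character(1))
}
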