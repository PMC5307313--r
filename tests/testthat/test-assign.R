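pr <- v5Primers()

test_that("in-silico PCR extracts exact-site inserts and rejects bad sites", {
  set.seed(20)
  insert <- randSeq(98)
  rec <- paste0(randSeq(30), pr[["forward"]], insert,
                rcSeq(pr[["reverse"]]), randSeq(25))
  db <- ReferenceDb(stats::setNames(Biostrings::DNAStringSet(rec), "r1"),
                    tinyTaxonomy()[1, ], type = "source")
  amp <- inSilicoPcr(db)
  expect_equal(length(seqs(amp)), 1L)
  expect_equal(as.character(seqs(amp)[[1]]), insert)
  # four mismatches in the forward site: no record
  fwdBad <- mutateSeq(pr[["forward"]], 4)
  recBad <- paste0(randSeq(30), fwdBad, insert, rcSeq(pr[["reverse"]]),
                   randSeq(25))
  dbBad <- ReferenceDb(stats::setNames(Biostrings::DNAStringSet(recBad),
                                       "r1"),
                       tinyTaxonomy()[1, ], type = "source")
  expect_message(ampBad <- inSilicoPcr(dbBad), "without amplifiable")
  expect_equal(length(seqs(ampBad)), 0L)
})

test_that("in-silico PCR agrees with a position-scanning oracle", {
  set.seed(21)
  for (i in 1:15) {
    insert <- randSeq(sample(60:120, 1))
    fwdMut <- mutateSeq(pr[["forward"]], sample(0:4, 1))
    revSiteMut <- mutateSeq(rcSeq(pr[["reverse"]]), sample(0:4, 1))
    rec <- paste0(randSeq(20), fwdMut, insert, revSiteMut, randSeq(20))
    db <- ReferenceDb(stats::setNames(Biostrings::DNAStringSet(rec), "r1"),
                      tinyTaxonomy()[1, ], type = "source")
    got <- suppressMessages(as.character(seqs(inSilicoPcr(db))))
    want <- oracleScanPcr(rec, pr[["forward"]], pr[["reverse"]])
    expect_setequal(unname(got), want)
  }
})

test_that("identity matches simple closed-form cases", {
  set.seed(22)
  s <- randSeq(100)
  expect_equal(seqIdentity(s, s), 1)
  expect_equal(seqIdentity(s, mutateSeq(s, 1)), 0.99)
  expect_equal(seqIdentity("AAAA", "AAAT"), 0.75)
  # symmetric
  a <- randSeq(40); b <- randSeq(35)
  expect_equal(seqIdentity(a, b), seqIdentity(b, a))
  expect_error(seqIdentity("", "ACGT"), "nonempty")
})

test_that("identity equals the quadratic DP oracle on random short pairs", {
  set.seed(23)
  for (i in 1:60) {
    a <- randSeq(sample(5:30, 1))
    b <- if (i %% 2 == 0) mutateSeq(a, sample(1:4, 1)) else
      randSeq(sample(5:30, 1))
    expect_equal(seqIdentity(a, b), oracleIdentity(a, b), tolerance = 1e-12)
  }
})

test_that("provisional assignment takes the LCA of the tied best hits", {
  set.seed(24)
  inserts <- replicate(6, randSeq(100))
  # make r2 nearly identical to r1 (same genus Apodemus)
  inserts[2] <- mutateSeq(inserts[1], 1)
  db <- tinyAmpliconDb(inserts)
  # single best species
  a1 <- assignTaxa(c(q1 = mutateSeq(inserts[3], 1)), db)
  expect_equal(a1$taxon, "Niviventer confucianus")
  expect_equal(a1$rank, "species")
  # tie between two congeners -> genus
  q <- inserts[1]
  a2 <- assignTaxa(stats::setNames(q, "q2"),
                   tinyAmpliconDb(c(inserts[1], inserts[1],
                                    inserts[3:6])))
  expect_equal(a2$taxon, "Apodemus")
  expect_equal(a2$rank, "genus")
  # tie across a rodent and a pheasant: no shared rank below the root
  mixed <- inserts
  mixed[5] <- inserts[1]  # Tragopan record shares the Apodemus sequence
  a3 <- assignTaxa(stats::setNames(inserts[1], "q3"), tinyAmpliconDb(mixed))
  expect_equal(a3$taxon, "Vertebrata")
  expect_equal(a3$rank, "root")
})

test_that("refinement applies the three local-occurrence rules", {
  set.seed(25)
  tx <- tinyTaxonomy()
  base <- randSeq(100)
  inserts <- c(base, mutateSeq(base, 30), randSeq(100), randSeq(100),
               randSeq(100), randSeq(100))
  db <- tinyAmpliconDb(inserts)
  local <- tx$species
  # rule 1: >= 0.98 to exactly one local species
  r1 <- refineAssignments(assignTaxa(c(q = mutateSeq(base, 1)), db),
                          local, tx)
  expect_equal(r1$rule, "1")
  expect_equal(r1$taxon, "Apodemus draco")
  expect_equal(r1$rank, "species")
  # rule 2: tie between two species, exactly one local
  dbTie <- tinyAmpliconDb(c(base, base, inserts[3:6]))
  r2 <- refineAssignments(assignTaxa(c(q = base), dbTie),
                          localSpecies = "Apodemus chevrieri", tx)
  expect_equal(r2$rule, "2")
  expect_equal(r2$taxon, "Apodemus chevrieri")
  # rule 2 with several local members -> lowest containing taxon
  r2b <- refineAssignments(assignTaxa(c(q = base), dbTie), local, tx)
  expect_equal(r2b$rule, "2")
  expect_equal(r2b$taxon, "Apodemus")
  expect_equal(r2b$rank, "genus")
  # rule 3: single local top hit at 96 percent -> that species
  r3 <- refineAssignments(assignTaxa(c(q = mutateSeq(base, 4)), db),
                          local, tx)
  expect_equal(r3$rule, "3")
  expect_equal(r3$taxon, "Apodemus draco")
  # rule 3: single non-local top hit with one local congener -> substituted
  r3b <- refineAssignments(assignTaxa(c(q = mutateSeq(base, 4)), db),
                           localSpecies = "Apodemus chevrieri", tx)
  expect_equal(r3b$rule, "3")
  expect_true(r3b$substituted)
  expect_equal(r3b$taxon, "Apodemus chevrieri")
  expect_equal(r3b$rank, "species")
  # rule 3: no local relative below order -> containing higher taxon
  r3c <- refineAssignments(assignTaxa(c(q = mutateSeq(base, 4)), db),
                           localSpecies = "Eothenomys chinensis", tx)
  expect_equal(r3c$rule, "3")
  expect_equal(r3c$taxon, "Rodentia")
  expect_equal(r3c$rank, "order")
  # below 94 percent: discarded with a machine-readable reason
  rLow <- refineAssignments(assignTaxa(c(q = mutateSeq(base, 7)), db),
                            local, tx)
  expect_equal(rLow$rule, "discarded_low_identity")
  expect_true(is.na(rLow$taxon))
  # unknown local species is a configuration error
  expect_error(refineAssignments(assignTaxa(c(q = base), db),
                                 "Felis silvestris", tx),
               class = "scatdiet_config_error")
})

test_that("per-sample filter removes low counts, control-level counts and non-prey", {
  set.seed(26)
  sq <- replicate(4, randSeq(90))
  counts <- cbind(S001 = c(9751L, 49L, 200L, 3000L),
                  S002 = c(500L, 600L, 700L, 800L),
                  NC1 = c(0L, 0L, 250L, 0L))
  asg <- data.frame(query_id = sprintf("u%06d", 1:4),
                    taxon = c("Apodemus draco", "Niviventer confucianus",
                              "Eothenomys chinensis",
                              "Prionailurus bengalensis"),
                    rank = "species", identity = 0.99, rule = "1",
                    stringsAsFactors = FALSE)
  u <- makeUss(sq, counts)
  out <- perSampleFilter(u, asg, controlIds = "NC1",
                         predator = "Prionailurus bengalensis")
  cc <- seqCounts(out$uss)
  # 49 reads in a ~10000-read sample: below the 50-read rule
  expect_false("u000002" %in% rownames(cc) && cc["u000002", "S001"] > 0)
  # 200 reads <= 250 in the negative control: removed everywhere it is lower
  expect_false("u000003" %in% rownames(cc) && cc["u000003", "S001"] > 0)
  # predator sequence removed despite 30 percent share
  expect_false("u000004" %in% rownames(cc))
  # S002: all four above thresholds except control-dominated + predator
  expect_true(cc["u000001", "S002"] > 0)
  expect_equal(ncol(cc), 2L)  # control column dropped
})

test_that("samples with nothing left are flagged as no-food", {
  set.seed(27)
  sq <- replicate(2, randSeq(90))
  counts <- cbind(S001 = c(30L, 10L), S002 = c(600L, 400L))
  asg <- data.frame(query_id = sprintf("u%06d", 1:2),
                    taxon = c("Apodemus draco", "Niviventer confucianus"),
                    rank = "species", identity = 0.99, rule = "1",
                    stringsAsFactors = FALSE)
  out <- perSampleFilter(makeUss(sq, counts), asg, controlIds = character(0),
                         predator = "Prionailurus bengalensis")
  expect_equal(out$noFood, "S001")
})

test_that("taxon collapse follows single linkage at 2 percent divergence", {
  set.seed(28)
  a <- randSeq(100)
  b <- mutateSeq(a, 1)    # a~b 0.99
  cSeq <- mutateSeq(b, 2) # b~c 0.98, a~c <= 0.97
  expect_lt(seqIdentity(a, cSeq), 0.98)
  far <- mutateSeq(a, 5)  # 0.95 to a
  tx <- tinyTaxonomy()
  asg <- data.frame(query_id = sprintf("u%06d", 1:4),
                    taxon = c("Apodemus draco", "Apodemus draco",
                              "Apodemus draco", "Apodemus chevrieri"),
                    rank = "species", identity = 0.99, rule = "1",
                    stringsAsFactors = FALSE)
  counts <- cbind(S001 = c(4000L, 200L, 100L, 900L),
                  S002 = c(0L, 300L, 0L, 0L))
  u <- makeUss(c(a, b, cSeq, far), counts)
  col <- collapseTaxa(u, asg, tx)
  # chain a~b~c collapses transitively; far stays apart
  expect_equal(nrow(col$taxa), 2L)
  expect_equal(col$membership[1], col$membership[2])
  expect_equal(col$membership[2], col$membership[3])
  expect_false(col$membership[4] == col$membership[1])
  # cluster label from the most abundant member
  expect_equal(col$taxa$taxon[col$membership[1]], "Apodemus draco")
  # presence: any member present in the sample
  expect_equal(col$presence[col$membership[1], "S002"], 1)
  # idempotence: collapsing the representatives changes nothing
  reps <- vapply(split(seq_len(4), col$membership), function(ix)
    ix[which.max(rowSums(counts)[ix])], integer(1))
  u2 <- makeUss(c(a, b, cSeq, far)[reps],
                counts[reps, , drop = FALSE])
  asg2 <- asg[reps, , drop = FALSE]
  asg2$query_id <- rownames(seqCounts(u2))
  col2 <- collapseTaxa(u2, asg2, tx)
  expect_equal(nrow(col2$taxa), nrow(col$taxa))
})

test_that("a 0.95-identity pair yields two discrete taxa", {
  set.seed(29)
  a <- randSeq(100)
  b <- mutateSeq(a, 5)
  asg <- data.frame(query_id = sprintf("u%06d", 1:2),
                    taxon = c("Apodemus draco", "Apodemus chevrieri"),
                    rank = "species", identity = 0.99, rule = "1",
                    stringsAsFactors = FALSE)
  u <- makeUss(c(a, b), cbind(S001 = c(100L, 50L)))
  col <- collapseTaxa(u, asg, tinyTaxonomy())
  expect_equal(nrow(col$taxa), 2L)
})

test_that("clusters mixing known orders are split with a warning", {
  set.seed(30)
  a <- randSeq(100)
  b <- mutateSeq(a, 1)
  asg <- data.frame(query_id = sprintf("u%06d", 1:2),
                    taxon = c("Apodemus draco", "Tragopan temminckii"),
                    rank = "species", identity = 0.99, rule = "1",
                    stringsAsFactors = FALSE)
  u <- makeUss(c(a, b), cbind(S001 = c(100L, 60L)))
  expect_warning(col <- collapseTaxa(u, asg, tinyTaxonomy()),
                 "incompatible orders")
  expect_equal(nrow(col$taxa), 2L)
})

test_that("predator identification applies the 98 percent identity rule", {
  refs <- predatorRefs16S()
  lpc <- as.character(refs[["Prionailurus bengalensis"]])
  agc <- as.character(refs[["Catopuma temminckii"]])
  expect_equal(identifyPredator(lpc, refs), "Prionailurus bengalensis")
  # the two references differ at 15 diagnostic positions
  expect_equal(sum(strsplit(lpc, "")[[1]] != strsplit(agc, "")[[1]]), 15L)
  expect_equal(identifyPredator(agc, refs), "Catopuma temminckii")
  # a sequence drifted below 98 percent is unknown
  set.seed(31)
  drift <- mutateSeq(lpc, 5)  # 145/150 < 0.98
  expect_equal(identifyPredator(drift, refs), "unknown")
  # equidistant query is ambiguous
  same <- Biostrings::DNAStringSet(c(A = lpc, B = lpc))
  expect_warning(out <- identifyPredator(lpc, same), "equally")
  expect_equal(out, "ambiguous")
})
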