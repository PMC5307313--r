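# the packaged felid occurrence fixture drives most numeric checks
fx <- loadFelidDiet()
nLpc <- attr(fx, "n_lpc")
nAgc <- attr(fx, "n_agc")

test_that("the packaged occurrence fixture has the expected structure", {
  expect_equal(nrow(fx), 40L)
  # checksums derived once by independent tally of the occurrence table
  expect_equal(sum(fx$lpc), 381L)
  expect_equal(sum(fx$agc), 35L)
  expect_equal(sum(fx$lpc > 0), 37L)
  expect_equal(sum(fx$agc > 0), 20L)
  expect_equal(sum(fx$lpc > 0 & fx$agc > 0), 17L)
  expect_equal(sum(fx$rank == "species"), 29L)
  expect_equal(length(unique(fx$taxon_order)), 11L)
  expect_equal(fx$lpc[fx$taxon == "Ochotona spp."], 71L)
  expect_equal(fx$agc[fx$taxon == "Ochotona spp."], 3L)
  expect_equal(fx$lpc[fx$taxon == "Rhizomys sinensis"], 1L)
  expect_equal(fx$agc[fx$taxon == "Rhizomys sinensis"], 4L)
})

test_that("frequency of occurrence reproduces the headline fixture values", {
  fc <- percentFC(stats::setNames(fx$lpc, fx$taxon), nSamples = nLpc)
  expect_equal(round(100 * fc[["Ochotona spp."]]), 76)
  expect_equal(round(100 * fc[["Niviventer confucianus"]]), 62)
  expect_equal(fc[["Dremomys pernyi"]], 0)
  fcA <- percentFC(stats::setNames(fx$agc, fx$taxon), nSamples = nAgc)
  expect_equal(round(100 * fcA[["Tragopan temminckii"]]), 60)
  expect_error(percentFC(c(5), nSamples = 0), class = "scatdiet_config_error")
  expect_error(percentFC(c(200), nSamples = 93),
               class = "scatdiet_config_error")
})

test_that("proportion of occurrence sums to one and matches order-level values", {
  tx <- percentTX(stats::setNames(fx$lpc, fx$taxon))
  expect_equal(sum(tx), 1, tolerance = 1e-9)
  byOrder <- tapply(fx$lpc, fx$taxon_order, sum) / sum(fx$lpc)
  expect_equal(round(100 * byOrder[["Rodentia"]]), 51)
  txA <- tapply(fx$agc, fx$taxon_order, sum) / sum(fx$agc)
  expect_equal(round(100 * txA[["Rodentia"]]), 31)
  expect_equal(round(100 * txA[["Galliformes"]]), 23)
  expect_equal(unname(percentTX(c(one = 7))), 1)
  expect_error(percentTX(c(0, 0)), class = "scatdiet_config_error")
})

test_that("Levins standardized breadth reproduces the fixture indices", {
  expect_equal(round(levinsBA(fx$lpc)$BA, 2), 0.27)
  expect_equal(round(levinsBA(fx$agc)$BA, 2), 0.64)
  expect_equal(levinsBA(fx$lpc)$n, 37L)
  # uniform profile maximizes breadth
  expect_equal(levinsBA(rep(4, 12))$BA, 1)
  expect_error(levinsBA(c(5)), class = "scatdiet_config_error")
})

test_that("Shannon and Pielou reproduce the fixture indices", {
  expect_equal(round(shannonPielou(fx$lpc)$H, 2), 2.78)
  expect_equal(round(shannonPielou(fx$agc)$H, 2), 2.80)
  expect_equal(round(shannonPielou(fx$lpc)$J, 2), 0.77)
  expect_equal(round(shannonPielou(fx$agc)$J, 2), 0.93)
  expect_equal(shannonPielou(c(9))$H, 0)
  expect_true(is.na(shannonPielou(c(9))$J))
})

test_that("niche index invariants hold on random profiles", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    x <- as.numeric(rmultinom(1, 200, runif(n) + 0.05))
    x <- x[x > 0]
    if (length(x) < 2) next
    nb <- levinsBA(x)
    sp <- shannonPielou(x)
    expect_gte(nb$B, 1); expect_lte(nb$B, nb$n)
    expect_gte(nb$BA, 0); expect_lte(nb$BA, 1)
    expect_gte(sp$H, 0); expect_lte(sp$H, log(nb$n) + 1e-12)
    expect_gte(sp$J, 0); expect_lte(sp$J, 1)
    # relabelling invariance
    perm <- sample(length(x))
    expect_equal(shannonPielou(x[perm])$J, sp$J)
    # merging two taxa never increases H
    if (length(x) >= 3) {
      xm <- c(x[1] + x[2], x[-(1:2)])
      expect_lte(shannonPielou(xm)$H, sp$H + 1e-12)
    }
  }
  # two-taxon concentration monotonically narrows the niche
  bas <- vapply(seq(0.5, 0.95, by = 0.05), function(p)
    levinsBA(c(p, 1 - p))$BA, numeric(1))
  expect_true(all(diff(bas) < 0))
})

test_that("Pianka overlap matches its formula and boundary cases", {
  p <- c(0.5, 0.3, 0.2, 0, 0)
  expect_equal(piankaOverlap(p, p), 1)
  expect_equal(piankaOverlap(c(1, 0, 0, 0, 0), c(0, 0, 0.4, 0.6, 0)), 0)
  # proportional profiles overlap completely
  expect_equal(piankaOverlap(p, 3 * p), 1)
  set.seed(41)
  for (i in 1:20) {
    a <- runif(5); b <- runif(5)
    direct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(piankaOverlap(a, b), direct, tolerance = 1e-12)
  }
  expect_error(piankaOverlap(c(0, 0), c(1, 0)),
               class = "scatdiet_config_error")
})

test_that("the Pianka permutation test is seeded and sane", {
  set.seed(42)
  m <- matrix(rbinom(8 * 30, 1, 0.4), nrow = 8,
              dimnames = list(paste0("t", 1:8), sprintf("S%03d", 1:30)))
  m[, colSums(m) == 0] <- 1
  occ <- makeOcc(m, sampleData = data.frame(
    season = rep(c("spring", "autumn"), length.out = 30),
    row.names = colnames(m)))
  r1 <- piankaPermTest(occ, "season", nPerm = 200, seed = 99)
  r2 <- piankaPermTest(occ, "season", nPerm = 200, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$Ojk, 0); expect_lte(r1$Ojk, 1)
  expect_gt(r1$p, 0); expect_lte(r1$p, 1)
})

test_that("Wilson intervals hit the boundary cases and the score equations", {
  expect_equal(wilsonInterval(0, 25)[["lower"]], 0)
  expect_equal(wilsonInterval(25, 25)[["upper"]], 1)
  # inversion of the score test (prop.test without continuity correction)
  for (case in list(c(71, 93), c(6, 10), c(3, 50), c(49, 50))) {
    got <- wilsonInterval(case[1], case[2])
    want <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
  }
  expect_error(wilsonInterval(5, 3), class = "scatdiet_config_error")
})

test_that("altitude classes follow the left-closed convention", {
  cl <- altitudeClass(c(1250, 1499, 1500, 1999, 2000, 2499, 2500, 3200))
  expect_equal(as.character(cl),
               c("low", "low", "lower-middle", "lower-middle",
                 "higher-middle", "higher-middle", "high", "high"))
})

test_that("stratification splits samples and handles empty strata", {
  set.seed(43)
  m <- matrix(rbinom(5 * 12, 1, 0.5), nrow = 5,
              dimnames = list(paste0("t", 1:5), sprintf("S%03d", 1:12)))
  m[1, ] <- 1  # keep every sample food-containing
  sd <- data.frame(
    season = rep(c("spring", "autumn"), each = 6),
    altitude_m = c(1250, 1300, 1600, 1700, 2100, 2200,
                   2600, 2700, 1400, 1800, 2300, 2900),
    predator = "Prionailurus bengalensis",
    row.names = colnames(m))
  occ <- makeOcc(m, sampleData = sd)
  bySeason <- stratifyDiet(occ, "season")
  expect_named(bySeason, c("autumn", "spring"))
  expect_equal(attr(bySeason$spring, "n_samples"), 6L)
  byAlt <- stratifyDiet(occ, "altitude_class")
  expect_equal(names(byAlt),
               c("low", "lower-middle", "higher-middle", "high"))
  expect_equal(attr(byAlt$low, "n_samples"), 3L)
  # order-level FC is at least the max member taxon FC
  s <- dietSummary(occ)
  ords <- attr(s, "orders")
  expect_gte(ords$FC[1], max(s$FC))
  # empty stratum: empty summary, not an error
  occ2 <- makeOcc(m[, 1:6], sampleData = sd[1:6, , drop = FALSE])
  byAlt2 <- stratifyDiet(occ2, "altitude_class")
  expect_equal(attr(byAlt2$high, "n_samples"), 0L)
})

test_that("seasons can be derived from months, with exclusions warned", {
  m <- matrix(1, nrow = 2, ncol = 4,
              dimnames = list(c("t1", "t2"), paste0("S", 1:4)))
  sd <- data.frame(month = c(3, 10, 7, 4), row.names = colnames(m))
  occ <- makeOcc(m, sampleData = sd)
  expect_warning(st <- stratifyDiet(occ, "season"), "excluded")
  expect_equal(attr(st$spring, "n_samples"), 2L)
  expect_equal(attr(st$autumn, "n_samples"), 1L)
})
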