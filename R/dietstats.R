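#' @include AllClasses.R
NULL

#' Frequency of occurrence (%FC)
#'
#' The fraction of food-containing faecal samples in which a food resource
#' occurs: `N_i / N`, where `N_i` counts samples containing the i-th taxon
#' and `N` is the total number of samples containing food. At the order
#' level a sample counts as containing the order when it contains at least
#' one member taxon, so order-level FC is at least the largest member
#' taxon's FC.
#'
#' @param x A [DietOccurrence], or a numeric vector of per-taxon occurrence
#'   counts `N_i`.
#' @param level `"taxon"` or `"order"` (DietOccurrence method; order-level
#'   needs a `taxon_order` rowData column).
#' @param nSamples Total number of food-containing samples (numeric
#'   method).
#' @param ... Unused.
#' @return Named numeric vector of occurrence frequencies in `[0, 1]`.
#' @export
#' @examples
#' percentFC(c(a = 71, b = 58), nSamples = 93)
setMethod("percentFC", "numeric", function(x, nSamples, ...) {
  if (nSamples < 1) sdStop("nSamples must be >= 1", "scatdiet_config_error")
  if (any(x > nSamples))
    sdStop("occurrence counts cannot exceed the number of samples",
           "scatdiet_config_error")
  x / nSamples
})

#' @rdname percentFC-numeric-method
#' @export
setMethod("percentFC", "DietOccurrence",
          function(x, level = c("taxon", "order"), ...) {
  level <- match.arg(level)
  occ <- occurrenceMatrix(x)
  if (ncol(occ) < 1) sdStop("no samples", "scatdiet_config_error")
  if (level == "taxon") return(rowSums(occ) / ncol(occ))
  ords <- rowData(x)$taxon_order
  ni <- vapply(unique(ords), function(o) {
    sub <- occ[ords %in% o, , drop = FALSE]
    sum(colSums(sub) > 0)
  }, numeric(1))
  ni / ncol(occ)
})

#' Proportion of occurrence (%TX)
#'
#' A taxon's share of all occurrences: `N_i / sum_j N_j`. Sums to one over
#' the food resources at the requested level; at the order level the
#' numerator is the summed taxon occurrences within the order.
#'
#' @param x A [DietOccurrence] or a numeric vector of occurrence counts.
#' @param level `"taxon"` or `"order"` (DietOccurrence method).
#' @param ... Unused.
#' @return Named numeric simplex vector.
#' @export
setMethod("percentTX", "numeric", function(x, ...) {
  if (sum(x) < 1) sdStop("total occurrences must be >= 1",
                         "scatdiet_config_error")
  x / sum(x)
})

#' @rdname percentTX-numeric-method
#' @export
setMethod("percentTX", "DietOccurrence",
          function(x, level = c("taxon", "order"), ...) {
  level <- match.arg(level)
  occ <- occurrenceMatrix(x)
  ni <- rowSums(occ)
  if (sum(ni) < 1) sdStop("empty occurrence matrix", "scatdiet_config_error")
  if (level == "taxon") return(ni / sum(ni))
  ords <- rowData(x)$taxon_order
  tapply(ni, ords, sum)[unique(ords)] / sum(ni)
})

#' Levins' niche breadth and its standardized form
#'
#' `B = 1 / sum(p_i^2)` over the proportions of occurrence and
#' `B_A = (B - 1) / (n - 1)`, rescaling breadth to `[0, 1]` (1 = perfectly
#' even use of all n resources). Zero-count taxa are dropped before
#' computing proportions.
#'
#' @param x Numeric vector of occurrence counts (or proportions), or a
#'   [DietOccurrence] (per-taxon occurrence counts are used).
#' @return List with `B`, `BA` and `n` (number of used resources).
#' @export
#' @examples
#' levinsBA(c(10, 10, 10))$BA  # 1: uniform use
levinsBA <- function(x) {
  if (is(x, "DietOccurrence")) x <- rowSums(occurrenceMatrix(x))
  x <- x[x > 0]
  n <- length(x)
  if (n < 2L)
    sdStop("standardized niche breadth needs >= 2 resources",
           "scatdiet_config_error")
  p <- x / sum(x)
  B <- 1 / sum(p^2)
  list(B = B, BA = (B - 1) / (n - 1), n = n)
}

#' Shannon diversity and Pielou evenness of a diet profile
#'
#' `H = -sum(p_i * log(p_i))` (natural log) over the proportions of
#' occurrence and `J = H / log(n)`. Zero-count taxa are dropped.
#'
#' @param x Numeric vector of occurrence counts, or a [DietOccurrence].
#' @return List with `H`, `J` (NA when n = 1) and `n`.
#' @export
shannonPielou <- function(x) {
  if (is(x, "DietOccurrence")) x <- rowSums(occurrenceMatrix(x))
  x <- x[x > 0]
  n <- length(x)
  if (n < 1L) sdStop("all counts are zero", "scatdiet_config_error")
  p <- x / sum(x)
  H <- -sum(p * log(p))
  list(H = H, J = if (n >= 2L) H / log(n) else NA_real_, n = n)
}

#' Pianka's niche overlap
#'
#' `O_jk = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))` over two
#' resource-use profiles on a shared taxon universe: 1 for proportional
#' profiles, 0 for disjoint supports.
#'
#' @param p,q Numeric resource-use vectors of equal length.
#' @return Overlap in `[0, 1]`.
#' @export
piankaOverlap <- function(p, q) {
  if (length(p) != length(q))
    sdStop("profiles must share a taxon universe", "scatdiet_config_error")
  np <- sqrt(sum(p^2)) * sqrt(sum(q^2))
  if (np == 0) sdStop("zero-norm profile", "scatdiet_config_error")
  sum(p * q) / np
}

#' Permutation test of Pianka overlap between two sample groups
#'
#' Computes the observed overlap of the two groups' proportion-of-occurrence
#' profiles, then permutes the group labels across samples `nPerm` times,
#' recomputing the overlap each time. The p-value is the fraction of
#' permutations with overlap at least the observed, with the usual
#' `+1/(nPerm+1)` correction. A high overlap with small p indicates the two
#' groups share prey use more than random relabelling would produce.
#'
#' @param occ A [DietOccurrence].
#' @param by Name of a two-level colData grouping column (e.g.
#'   `"season"`).
#' @param nPerm Number of label permutations.
#' @param seed Integer seed for the permutation stream.
#' @return List with `Ojk`, `p`, `nPerm`, `seed` and the group labels.
#' @export
piankaPermTest <- function(occ, by = "season", nPerm = 10000L, seed = 1L) {
  grp <- as.character(colData(occ)[[by]])
  if (is.null(grp) || length(unique(grp)) != 2L)
    sdStop(sprintf("'%s' must define exactly two groups", by),
           "scatdiet_config_error")
  m <- occurrenceMatrix(occ)
  lv <- unique(grp)
  profOf <- function(g) {
    ni <- rowSums(m[, g == lv[1], drop = FALSE])
    nj <- rowSums(m[, g == lv[2], drop = FALSE])
    list(p = ni / max(sum(ni), 1), q = nj / max(sum(nj), 1))
  }
  obs <- profOf(grp)
  Ojk <- piankaOverlap(obs$p, obs$q)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(i) {
      pg <- sample(grp)
      pr <- profOf(pg)
      piankaOverlap(pr$p, pr$q) >= Ojk - 1e-12
    }, logical(1)))
  })
  list(Ojk = Ojk, p = (exceed + 1) / (nPerm + 1), nPerm = nPerm,
       seed = seed, groups = lv)
}

#' Altitude class of a sample
#'
#' Maps altitudes to the four vegetation-based classes: low (< 1500 m),
#' lower-middle (1500-2000 m), higher-middle (2000-2500 m) and high
#' (> 2500 m). Intervals are left-closed, so 1500 m falls in lower-middle.
#'
#' @param altitude Numeric altitudes in metres.
#' @return Factor with levels `low`, `lower-middle`, `higher-middle`,
#'   `high`.
#' @export
#' @examples
#' altitudeClass(c(1250, 1500, 2499, 2600))
altitudeClass <- function(altitude) {
  cut(altitude, breaks = c(-Inf, 1500, 2000, 2500, Inf),
      labels = c("low", "lower-middle", "higher-middle", "high"),
      right = FALSE)
}

#' Per-stratum diet summary
#'
#' Occurrence count, frequency of occurrence and proportion of occurrence
#' per taxon for a subset of samples, with order-level aggregates as an
#' attribute.
#'
#' @param occ A [DietOccurrence].
#' @param samples Optional character/logical/integer sample selector.
#' @param group Label stored on the result.
#' @return Data frame (taxon, rank, taxon_order, N_i, FC, TX) with
#'   attributes `group`, `n_samples` and `orders`.
#' @export
dietSummary <- function(occ, samples = NULL, group = "all") {
  m <- occurrenceMatrix(occ)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  ni <- rowSums(m)
  n <- ncol(m)
  rd <- as.data.frame(rowData(occ))
  out <- data.frame(
    taxon = if ("taxon" %in% names(rd)) rd$taxon else rownames(m),
    rank = if ("rank" %in% names(rd)) rd$rank else NA_character_,
    taxon_order = if ("taxon_order" %in% names(rd)) rd$taxon_order
                  else NA_character_,
    N_i = ni,
    FC = if (n > 0) ni / n else NA_real_,
    TX = if (sum(ni) > 0) ni / sum(ni) else NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- rownames(m)
  if (!all(is.na(out$taxon_order))) {
    oni <- vapply(unique(out$taxon_order), function(o) {
      sub <- m[out$taxon_order %in% o, , drop = FALSE]
      sum(colSums(sub) > 0)
    }, numeric(1))
    attr(out, "orders") <- data.frame(
      taxon_order = unique(out$taxon_order), N_i = oni,
      FC = if (n > 0) oni / n else NA_real_,
      TX = tapply(ni, out$taxon_order, sum)[unique(out$taxon_order)] /
        max(sum(ni), 1),
      stringsAsFactors = FALSE)
  }
  attr(out, "group") <- group
  attr(out, "n_samples") <- n
  out
}

#' Stratify a diet by season, altitude class or predator
#'
#' Splits the samples by the requested key and returns one diet summary per
#' stratum. Seasons may be derived from a `month` column (3-5 spring, 9-11
#' autumn; other months are excluded with a warning); samples lacking an
#' altitude are excluded from altitude stratification.
#'
#' @param x A [DietOccurrence].
#' @param by `"season"`, `"altitude_class"` or `"predator"`.
#' @param ... Unused.
#' @return Named list of [dietSummary()] data frames.
#' @export
setMethod("stratifyDiet", "DietOccurrence",
          function(x, by = c("season", "altitude_class", "predator"), ...) {
  by <- match.arg(by)
  cd <- colData(x)
  key <- switch(by,
    season = {
      if ("season" %in% names(cd)) as.character(cd$season)
      else if ("month" %in% names(cd)) {
        mo <- cd$month
        s <- ifelse(mo %in% 3:5, "spring",
                    ifelse(mo %in% 9:11, "autumn", NA_character_))
        if (anyNA(s))
          warning(sum(is.na(s)), " sample(s) outside spring/autumn excluded")
        s
      } else sdStop("no season or month metadata", "scatdiet_config_error")
    },
    altitude_class = {
      if (!"altitude_m" %in% names(cd))
        sdStop("no altitude_m metadata", "scatdiet_config_error")
      alt <- cd$altitude_m
      if (anyNA(alt))
        warning(sum(is.na(alt)), " sample(s) without altitude excluded")
      as.character(altitudeClass(alt))
    },
    predator = {
      if (!"predator" %in% names(cd))
        sdStop("no predator metadata", "scatdiet_config_error")
      as.character(cd$predator)
    })
  strata <- if (by == "altitude_class")
    c("low", "lower-middle", "higher-middle", "high")
  else sort(unique(na.omit(key)))
  out <- lapply(strata, function(s)
    dietSummary(x, samples = which(!is.na(key) & key == s), group = s))
  names(out) <- strata
  out
})
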