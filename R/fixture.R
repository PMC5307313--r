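#' @include AllClasses.R
NULL

#' Packaged felid diet occurrence fixture
#'
#' Occurrence counts of the 40 discrete prey taxa recovered from leopard
#' cat (LPC; n = 93 food-containing faecal samples) and Asiatic golden cat
#' (AGC; n = 10) diets in a montane forest study area of Southwest China,
#' with each taxon's assignment rank and containing order. Only occurrence
#' counts are stored (no per-sample matrix exists for this dataset), so
#' statistics needing per-sample data run on synthetic or user data only.
#'
#' @return Data frame with columns `taxon`, `common_name`, `rank`,
#'   `taxon_order`, `lpc`, `agc`; attributes `n_lpc` (93) and `n_agc` (10)
#'   give the sample totals behind the counts.
#' @export
#' @examples
#' fx <- loadFelidDiet()
#' sum(fx$lpc)  # 381 occurrences over 37 LPC taxa
loadFelidDiet <- function() {
  path <- system.file("extdata", "felid_diet_occurrence.tsv",
                      package = "scatdiet", mustWork = TRUE)
  fx <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(fx, "n_lpc") <- 93L
  attr(fx, "n_agc") <- 10L
  fx
}
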