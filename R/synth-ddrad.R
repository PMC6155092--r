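#' In-silico double-digest RAD fragments
#'
#' Digests a genome with two restriction enzymes (defaults: EcoRI `GAATTC`
#' and HindIII `AAGCTT`), placing a cut at the first base of each
#' recognition site (a blunt abstraction: overhang chemistry is irrelevant
#' to downstream marker logic, and this keeps fragment arithmetic exact).
#' Retained fragments are those whose two ends carry sites of *different*
#' enzymes and whose length falls within the size-selection window
#' (defaults 300-500 bp). Both default sites are palindromic, so scanning
#' the forward strand finds every site.
#'
#' @param genome a [hap_seq] or character scalar.
#' @param enzymeA_site,enzymeB_site recognition sequences.
#' @param size_min,size_max size-selection window in bp (inclusive).
#' @param all if `TRUE`, return every digest fragment with a `retained`
#'   column instead of only the retained ones.
#' @return tibble with columns `start`, `end` (0-based half-open on the
#'   input genome), `length`, `enzyme_left`, `enzyme_right` (and `retained`
#'   when `all = TRUE`).
#' @export
digest_ddrad <- function(genome, enzymeA_site = "GAATTC",
                         enzymeB_site = "AAGCTT",
                         size_min = 300, size_max = 500, all = FALSE) {
  seq <- if (inherits(genome, "hap_seq")) genome$seq else genome
  stopifnot(size_min < size_max, nchar(enzymeA_site) > 0,
            nchar(enzymeB_site) > 0)
  locs <- function(site) {
    m <- stringi::stri_locate_all_fixed(seq, site)[[1]]
    if (all(is.na(m[, 1]))) integer(0) else as.integer(m[, 1] - 1)
  }
  cutA <- locs(enzymeA_site)
  cutB <- locs(enzymeB_site)
  cuts <- tibble::tibble(
    pos = c(cutA, cutB),
    enzyme = c(rep("A", length(cutA)), rep("B", length(cutB))))
  cuts <- dplyr::arrange(cuts, .data$pos)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          length = integer(), enzyme_left = character(),
                          enzyme_right = character())
  if (nrow(cuts) < 2) {
    if (all) empty$retained <- logical()
    return(empty)
  }
  n <- nrow(cuts)
  frags <- tibble::tibble(
    start = cuts$pos[-n], end = cuts$pos[-1],
    enzyme_left = cuts$enzyme[-n], enzyme_right = cuts$enzyme[-1])
  frags$length <- frags$end - frags$start
  frags$retained <- frags$enzyme_left != frags$enzyme_right &
    frags$length >= size_min & frags$length <= size_max
  frags <- frags[, c("start", "end", "length", "enzyme_left",
                     "enzyme_right", "retained")]
  if (all) frags else dplyr::select(dplyr::filter(frags, .data$retained),
                                    -"retained")
}
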