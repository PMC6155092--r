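#' Simulate a mapping cross over a diallelic locus region
#'
#' Simulates BC1 (F1 backcrossed to the `A` line) or F2 (F1 sibcross)
#' progeny over a genomic region carried by two parental alleles. Gametes
#' from heterozygous parents receive Poisson-distributed crossovers at
#' `recomb_rate` per bp per meiosis, placed uniformly *outside* the
#' recombination-suppressed interval (e.g. a large inversion) and never
#' inside it. Marker genotypes are read directly from the simulated
#' chromosomes; marker coordinates live on the shared parental coordinate
#' frame.
#'
#' The binary phenotype is determined by the genotype at the midpoint of
#' `causal_interval` under full penetrance:
#'
#' * F2, A-dominant: `AA`/`AB` -> 1, `BB` -> 0 (and mirrored for
#'   B-dominant). This reflects dominance of the black-pattern allele.
#' * BC1 (to the `A` line): `AA` -> 0, `AB` -> 1. The heterozygote is
#'   phenotypically distinguishable from the recurrent homozygote (mosaic
#'   dominance: the heterozygote displays the combined pattern), which is
#'   what makes a backcross informative here.
#'
#' @param design `"BC1"` or `"F2"`.
#' @param alleleA,alleleB [hap_seq] objects (used for their lengths; the
#'   genotype simulation is allelic, not sequence-level).
#' @param n number of progeny (>= 1).
#' @param marker_positions integer vector of marker coordinates (0-based)
#'   within the region.
#' @param recomb_rate crossover rate per bp per meiosis.
#' @param suppressed_interval length-2 vector `(start, end)` or `NULL`:
#'   interval with zero recombination.
#' @param causal_interval length-2 vector; defaults to
#'   `suppressed_interval`. Its midpoint genotype sets the phenotype.
#' @param dominance `"A-dominant"` or `"B-dominant"` (F2 phenotype rule).
#' @param seed integer seed.
#' @return object of class `cross_panel`: list with `design`, `markers`
#'   (tibble `marker`, `pos`), `data` (tibble: `individual`, `phenotype`,
#'   one column per marker with values `AA`/`AB`/`BB`), `causal_interval`,
#'   `suppressed_interval`.
#' @export
simulate_cross <- function(design = c("BC1", "F2"), alleleA, alleleB, n,
                           marker_positions, recomb_rate = 1e-5,
                           suppressed_interval = NULL,
                           causal_interval = suppressed_interval,
                           dominance = c("A-dominant", "B-dominant"),
                           seed = 1) {
  design <- match.arg(design)
  dominance <- match.arg(dominance)
  stopifnot(n >= 1)
  L <- if (inherits(alleleA, "hap_seq")) nchar(alleleA$seq) else
    as.integer(alleleA)
  if (any(marker_positions < 0) || any(marker_positions >= L))
    stop("marker positions outside genome")
  if (is.null(causal_interval))
    stop("a causal interval (or suppressed interval) is required")
  if (!is.null(suppressed_interval)) {
    stopifnot(length(suppressed_interval) == 2,
              suppressed_interval[1] >= 0, suppressed_interval[2] <= L,
              suppressed_interval[1] < suppressed_interval[2])
  }
  marker_positions <- sort(as.integer(marker_positions))
  causal_mid <- as.integer(mean(causal_interval))

  with_op_seed(seed, paste0("simulate_cross_", design), {
    qpos <- c(marker_positions, causal_mid)

    # one gamete from a heterozygous (A/B) parent: allele at each queried
    # position, given crossovers outside the suppressed interval
    het_gamete <- function() {
      s <- suppressed_interval
      allowed <- if (is.null(s)) L else L - (s[2] - s[1])
      nco <- rpois(1, recomb_rate * allowed)
      co <- sort(floor(runif(nco) * allowed))
      if (!is.null(s)) co <- ifelse(co >= s[1], co + (s[2] - s[1]), co)
      phase0 <- sample(c("A", "B"), 1)
      crossings <- vapply(qpos, function(p) sum(co <= p), integer(1))
      ifelse(crossings %% 2 == 0, phase0,
             ifelse(phase0 == "A", "B", "A"))
    }

    geno <- matrix("", nrow = n, ncol = length(qpos))
    for (i in seq_len(n)) {
      g1 <- het_gamete()
      g2 <- if (design == "BC1") rep("A", length(qpos)) else het_gamete()
      geno[i, ] <- paste0(pmin(g1, g2), pmax(g1, g2))
    }
    causal <- geno[, ncol(geno)]
    geno <- geno[, -ncol(geno), drop = FALSE]

    phenotype <- if (design == "BC1") {
      as.integer(causal == "AB")
    } else if (dominance == "A-dominant") {
      as.integer(causal != "BB")
    } else {
      as.integer(causal != "AA")
    }

    markers <- tibble::tibble(
      marker = sprintf("m%03d", seq_along(marker_positions)),
      pos = marker_positions)
    dat <- tibble::as_tibble(as.data.frame(geno,
                                           stringsAsFactors = FALSE))
    names(dat) <- markers$marker
    dat <- dplyr::bind_cols(
      tibble::tibble(individual = sprintf("ind%04d", seq_len(n)),
                     phenotype = phenotype), dat)
    structure(list(design = design, dominance = dominance,
                   markers = markers, data = dat,
                   causal_interval = as.numeric(causal_interval),
                   suppressed_interval =
                     if (is.null(suppressed_interval)) NULL
                     else as.numeric(suppressed_interval),
                   causal_genotype = causal),
              class = "cross_panel")
  })
}

#' @export
print.cross_panel <- function(x, ...) {
  cat(sprintf("<cross_panel> %s, %d individuals, %d markers\n", x$design,
              nrow(x$data), nrow(x$markers)))
  invisible(x)
}

#' Write a cross panel to TSV
#'
#' Header row: `individual`, `phenotype`, then one column per marker.
#'
#' @param panel a `cross_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  write.table(panel$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cross panel written by [write_panel_tsv()]
#'
#' @param path panel TSV path.
#' @param markers tibble with `marker`, `pos` (as in `panel$markers`).
#' @param design `"BC1"` or `"F2"`.
#' @param causal_interval optional causal interval.
#' @return a `cross_panel`.
#' @export
read_panel_tsv <- function(path, markers, design = "BC1",
                           causal_interval = NULL) {
  dat <- tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
  structure(list(design = design, dominance = "A-dominant",
                 markers = tibble::as_tibble(markers),
                 data = dat, causal_interval = causal_interval,
                 suppressed_interval = NULL, causal_genotype = NULL),
            class = "cross_panel")
}
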