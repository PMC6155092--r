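#' Build a bubble-preserving de Bruijn graph
#'
#' Constructs the canonical k-mer de Bruijn graph of the input reads,
#' keeping every k-mer seen at least `min_count` times. No tip clipping or
#' bubble popping is performed: bubble structures caused by heterozygosity
#' are preserved so that scaffold pairs in bubbles can later be phased into
#' haplotypes. Maximal non-branching paths (unitigs) and the junction
#' adjacency between unitig ends are extracted eagerly.
#'
#' @param reads character vector of reads, FASTQ path(s), a `read_pairs`
#'   object, or a list of any of these (all libraries together).
#' @param k odd k-mer size, 3-31 (default 31); must be smaller than the
#'   read length.
#' @param min_count minimum k-mer count to retain a node (default 2, which
#'   drops singleton error k-mers).
#' @return object of class `dbg`: list with `k`, `min_count`, `unitigs`
#'   (tibble `id`, `seq`, `length`, `n_kmers`, `coverage`), `edges`
#'   (tibble `u`, `u_end`, `v`, `v_end`; each row reads "leaving unitig `u`
#'   through end `u_end` enters `v` at end `v_end`"), `distinct_kmers`,
#'   `retained_count_total`.
#' @export
build_graph <- function(reads, k = 31, min_count = 2) {
  if (inherits(reads, "read_pairs"))
    reads <- c(unname(reads$read1), unname(reads$read2))
  reads <- as_reads(reads)
  if (length(reads) > 0 && k >= max(nchar(reads)))
    stop("k must be smaller than the read length")
  res <- cpp_build_unitigs(reads, as.integer(k), as.integer(min_count))
  unitigs <- tibble::tibble(
    id = seq_along(res$seq), seq = res$seq, length = nchar(res$seq),
    n_kmers = res$n_kmers, coverage = res$coverage)
  edges <- tibble::tibble(u = res$edge_u, u_end = res$edge_u_end,
                          v = res$edge_v, v_end = res$edge_v_end)
  structure(list(k = as.integer(k), min_count = as.integer(min_count),
                 unitigs = unitigs, edges = edges,
                 distinct_kmers = res$distinct_kmers,
                 retained_count_total = res$retained_count_total),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf(
    "<dbg> k=%d, %d unitig(s), %d junction edge(s), %.0f distinct k-mers\n",
    x$k, nrow(x$unitigs), nrow(x$edges), x$distinct_kmers))
  invisible(x)
}

#' Extract unitigs from a de Bruijn graph
#'
#' Unitigs are maximal non-branching paths; every retained k-mer belongs to
#' exactly one unitig and a unitig of `n` nodes spells `n + k - 1` bases.
#'
#' @param graph a [build_graph()] result.
#' @return tibble `id`, `seq`, `length`, `n_kmers`, `coverage`.
#' @export
extract_unitigs <- function(graph) {
  stopifnot(inherits(graph, "dbg"))
  graph$unitigs
}

# opposite end label
opp_end <- function(e) ifelse(e == "R", "L", "R")

#' Detect simple bubbles in the unitig graph
#'
#' A simple bubble is a source unitig end with exactly two outgoing arms —
#' each a single unitig no longer than `bubble_max_len` whose two ends
#' connect only the source and a common sink — reconverging at the same
#' sink end. These are the heterozygous haplotype pairs of the graph: for
#' an isolated SNP each arm has exactly k nodes (2k-1 bases) and the arms
#' differ at one base; clustered SNPs give longer arms, accepted up to
#' `bubble_max_len`.
#'
#' Arm `a` is the arm whose traversal-oriented sequence is
#' lexicographically smaller (a deterministic, haplotype-agnostic label).
#'
#' @param graph a [build_graph()] result.
#' @param bubble_max_len maximum arm length in bp (default `5 * k`).
#' @return tibble of class `bubble_set`: `bubble`, `source`, `source_end`,
#'   `sink`, `sink_end`, `arm_a`, `arm_b` (unitig ids), `arm_a_seq`,
#'   `arm_b_seq` (oriented source -> sink), `arm_a_cov`, `arm_b_cov`.
#' @export
detect_bubbles <- function(graph, bubble_max_len = 5 * graph$k) {
  stopifnot(inherits(graph, "dbg"))
  un <- graph$unitigs
  ed <- graph$edges
  empty <- tibble::tibble(
    bubble = integer(), source = integer(), source_end = character(),
    sink = integer(), sink_end = character(), arm_a = integer(),
    arm_b = integer(), arm_a_seq = character(), arm_b_seq = character(),
    arm_a_cov = numeric(), arm_b_cov = numeric())
  if (nrow(ed) == 0) return(structure(empty, class = c("bubble_set",
                                                       class(empty))))
  key <- paste(ed$u, ed$u_end)
  outdeg <- table(key)
  rows <- list()
  seen <- character(0)
  two_out <- names(outdeg)[outdeg == 2]
  for (kk in two_out) {
    idx <- which(key == kk)
    src <- ed$u[idx[1]]; src_end <- ed$u_end[idx[1]]
    arms <- ed$v[idx]; arm_ends <- ed$v_end[idx]
    if (arms[1] == arms[2]) next          # both edges into the same unitig
    if (any(arms == src)) next            # self-loop arm
    ok <- TRUE
    sink <- NA_integer_; sink_end <- NA_character_
    arm_seq <- character(2)
    for (j in 1:2) {
      a <- arms[j]; e_in <- arm_ends[j]
      if (un$length[a] > bubble_max_len) { ok <- FALSE; break }
      back <- which(ed$u == a & ed$u_end == e_in)
      fwd <- which(ed$u == a & ed$u_end == opp_end(e_in))
      if (length(back) != 1 || length(fwd) != 1) { ok <- FALSE; break }
      if (ed$v[back] != src) { ok <- FALSE; break }
      t_j <- ed$v[fwd]; t_end_j <- ed$v_end[fwd]
      if (j == 1) { sink <- t_j; sink_end <- t_end_j }
      else if (t_j != sink || t_end_j != sink_end) { ok <- FALSE; break }
      arm_seq[j] <- if (e_in == "L") un$seq[a] else revcomp(un$seq[a])
    }
    if (!ok || is.na(sink) || sink == src || sink %in% arms) next
    dk <- paste(sort(arms), collapse = "-")
    if (dk %in% seen) next
    seen <- c(seen, dk)
    ord <- order(arm_seq)
    rows[[length(rows) + 1]] <- tibble::tibble(
      source = src, source_end = src_end, sink = sink, sink_end = sink_end,
      arm_a = arms[ord[1]], arm_b = arms[ord[2]],
      arm_a_seq = arm_seq[ord[1]], arm_b_seq = arm_seq[ord[2]],
      arm_a_cov = un$coverage[arms[ord[1]]],
      arm_b_cov = un$coverage[arms[ord[2]]])
  }
  if (length(rows) == 0) return(structure(empty,
                                          class = c("bubble_set",
                                                    class(empty))))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$arm_a)
  out <- dplyr::bind_cols(tibble::tibble(bubble = seq_len(nrow(out))), out)
  structure(out, class = c("bubble_set", class(out)))
}
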