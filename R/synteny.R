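#' Anchor-based pairwise alignment into oriented blocks
#'
#' Finds exact anchor matches of length `min_anchor` that are unique in
#' both sequences (a MUM-like criterion, reproducing the behaviour class
#' of anchor-chaining whole-genome aligners), on both strands of the
#' subject, merges anchors on a common diagonal into maximal runs, and
#' chains co-linear runs (diagonal drift at most `band`, gaps at most
#' `max_gap`) into oriented blocks. Chains with fewer than `min_cluster`
#' matched bases are discarded.
#'
#' Coordinates are 0-based half-open on each sequence's forward strand;
#' reverse blocks store ascending subject coordinates plus the
#' `"reverse"` orientation flag. A self-comparison returns the full-length
#' forward block first (blocks are ordered by matched bases, then query
#' position).
#'
#' @param seqA,seqB character scalars or [hap_seq] (query, subject).
#' @param min_anchor minimum exact anchor length (default 12).
#' @param min_cluster minimum matched bases per retained block
#'   (default 65).
#' @param band maximum diagonal drift within a chain, bp (default 100).
#' @param max_gap maximum anchor gap within a chain, bp (default 5000).
#' @return tibble of class `alignment_blocks`: `q_start`, `q_end`,
#'   `s_start`, `s_end`, `orientation` (`"forward"`/`"reverse"`),
#'   `matched_bases`; attributes `query_len`, `subject_len`.
#' @export
anchor_align <- function(seqA, seqB, min_anchor = 12, min_cluster = 65,
                         band = 100, max_gap = 5000) {
  if (inherits(seqA, "hap_seq")) seqA <- seqA$seq
  if (inherits(seqB, "hap_seq")) seqB <- seqB$seq
  stopifnot(nchar(seqA) > 0, nchar(seqB) > 0)
  L <- as.integer(min_anchor)
  lenB <- nchar(seqB)
  m <- tibble::as_tibble(cpp_unique_matches(seqA, seqB, L))

  blocks <- list()
  for (str in c(1L, -1L)) {
    mm <- m[m$strand == str, , drop = FALSE]
    if (nrow(mm) == 0) next
    # reverse matches become co-linear in subject reverse-complement coords
    s <- if (str == 1L) mm$spos else lenB - mm$spos - L
    runs <- anchor_runs(mm$qpos, s, L)
    ch <- chain_runs(runs, band, max_gap)
    if (nrow(ch) == 0) next
    ch$orientation <- if (str == 1L) "forward" else "reverse"
    if (str == -1L) {
      s1 <- lenB - ch$s_end; s2 <- lenB - ch$s_start
      ch$s_start <- s1; ch$s_end <- s2
    }
    blocks[[length(blocks) + 1]] <- ch
  }
  empty <- tibble::tibble(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          orientation = character(),
                          matched_bases = integer())
  out <- if (length(blocks) == 0) empty else dplyr::bind_rows(blocks)
  out <- out[out$matched_bases >= min_cluster, , drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$matched_bases),
                        .data$q_start)
  out <- out[, c("q_start", "q_end", "s_start", "s_end", "orientation",
                 "matched_bases")]
  structure(out, class = c("alignment_blocks", class(out)),
            query_len = nchar(seqA), subject_len = lenB)
}

# merge same-diagonal anchors into runs; matched bases = union of the
# L-windows along the run (anchors within 2L on the same diagonal merge)
anchor_runs <- function(q, s, L) {
  if (length(q) == 0)
    return(tibble::tibble(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          matched = integer()))
  d <- s - q
  o <- order(d, q)
  q <- q[o]; s <- s[o]; d <- d[o]
  new_run <- c(TRUE, diff(d) != 0 | diff(q) > 2 * L)
  run_id <- cumsum(new_run)
  gap_loss <- ifelse(!new_run & c(0, diff(q)) > L,
                     c(0, diff(q)) - L, 0)
  tibble::tibble(q = q, s = s, id = run_id, loss = gap_loss) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(q_start = min(.data$q), q_end = max(.data$q) + L,
                     s_start = min(.data$s), s_end = max(.data$s) + L,
                     matched = (max(.data$q) + L - min(.data$q)) -
                       sum(.data$loss),
                     .groups = "drop") |>
    dplyr::select(-"id")
}

# greedy chaining of runs sorted by query start
chain_runs <- function(runs, band, max_gap) {
  n <- nrow(runs)
  if (n == 0)
    return(tibble::tibble(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          matched_bases = integer()))
  runs <- dplyr::arrange(runs, .data$q_start, .data$s_start)
  chain_of <- rep(NA_integer_, n)
  # open chains: last run index per chain
  last_q_end <- numeric(0); last_diag <- numeric(0)
  for (i in seq_len(n)) {
    diag_i <- runs$s_start[i] - runs$q_start[i]
    best <- NA_integer_; best_dd <- Inf
    if (length(last_q_end) > 0) {
      gap <- runs$q_start[i] - last_q_end
      dd <- abs(diag_i - last_diag)
      ok <- gap >= -2 * band & gap <= max_gap & dd <= band
      if (any(ok)) {
        cand <- which(ok)
        best <- cand[which.min(dd[cand])]
        best_dd <- dd[best]
      }
    }
    if (is.na(best)) {
      last_q_end <- c(last_q_end, runs$q_end[i])
      last_diag <- c(last_diag, diag_i)
      chain_of[i] <- length(last_q_end)
    } else {
      chain_of[i] <- best
      last_q_end[best] <- max(last_q_end[best], runs$q_end[i])
      last_diag[best] <- diag_i
    }
  }
  runs$chain <- chain_of
  runs |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      q_start = min(.data$q_start), q_end = max(.data$q_end),
      s_start = min(.data$s_start), s_end = max(.data$s_end),
      matched_bases = min(sum(.data$matched),
                          max(.data$q_end) - min(.data$q_start)),
      .groups = "drop") |>
    dplyr::select(-"chain")
}

#' Filter alignment blocks: short fragments and short repeats
#'
#' Applies the two comparison filters in order: (1) blocks spanning fewer
#' than `min_len` bases are removed; (2) among the survivors, blocks
#' spanning fewer than `repeat_max_len` bases whose query interval
#' overlaps a query locus hit by more than `repeat_min_hits` blocks
#' (counting the block itself) are removed as putative short repeats. The
#' span is measured on the query by default. Order of the surviving
#' blocks is preserved, and the filter is idempotent.
#'
#' @param blocks an [anchor_align()] result (or compatible tibble).
#' @param min_len minimum block span in bp (default 500).
#' @param repeat_max_len spans below this are subject to the repeat rule
#'   (default 1250).
#' @param repeat_min_hits repeat rule triggers when more than this many
#'   blocks overlap (default 2, i.e. strictly more than two).
#' @param span_on `"query"` (default) or `"subject"`: which span the
#'   thresholds apply to.
#' @return the filtered block tibble (attributes preserved).
#' @export
filter_blocks <- function(blocks, min_len = 500, repeat_max_len = 1250,
                          repeat_min_hits = 2, span_on = c("query",
                                                           "subject")) {
  span_on <- match.arg(span_on)
  span <- if (span_on == "query") blocks$q_end - blocks$q_start else
    blocks$s_end - blocks$s_start
  keep1 <- span >= min_len
  b <- blocks[keep1, , drop = FALSE]
  span <- span[keep1]
  if (nrow(b) > 0) {
    qr <- IRanges::IRanges(start = b$q_start + 1, end = b$q_end)
    hits <- IRanges::countOverlaps(qr, qr)
    keep2 <- !(span < repeat_max_len & hits > repeat_min_hits)
    b <- b[keep2, , drop = FALSE]
  }
  b
}

#' Group reverse blocks into inversion calls
#'
#' Reverse-orientation blocks whose query intervals lie within
#' `merge_dist` of each other are grouped into a single inversion trace;
#' the call's size is the subject-coordinate span of the merged group.
#' Calls are sorted by query position.
#'
#' @param blocks filtered [anchor_align()] blocks.
#' @param merge_dist maximum query gap between grouped reverse blocks
#'   (default 10 kb).
#' @return tibble of class `inversion_calls`: `q_start`, `q_end`,
#'   `s_start`, `s_end`, `size` (subject span), `support` (number of
#'   reverse blocks).
#' @export
call_inversions <- function(blocks, merge_dist = 10000) {
  rb <- blocks[blocks$orientation == "reverse", , drop = FALSE]
  empty <- tibble::tibble(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          size = integer(), support = integer())
  if (nrow(rb) == 0)
    return(structure(empty, class = c("inversion_calls", class(empty))))
  rb <- dplyr::arrange(rb, .data$q_start)
  grp <- cumsum(c(TRUE, rb$q_start[-1] > cummax(rb$q_end)[-nrow(rb)] +
                    merge_dist))
  out <- rb |>
    dplyr::mutate(grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(q_start = min(.data$q_start),
                     q_end = max(.data$q_end),
                     s_start = min(.data$s_start),
                     s_end = max(.data$s_end),
                     support = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(size = .data$s_end - .data$s_start) |>
    dplyr::arrange(.data$q_start) |>
    dplyr::select("q_start", "q_end", "s_start", "s_end", "size",
                  "support")
  structure(out, class = c("inversion_calls", class(out)))
}

#' Locus annotation for noncoding-span arithmetic
#'
#' @param exons tibble/data.frame with `start`, `end` (0-based half-open),
#'   sorted, non-overlapping: the exons of the focal gene.
#' @param name gene name.
#' @param strand `"+"` (the co-oriented tandem arrangement assumed by the
#'   size arithmetic).
#' @return object of class `locus_annotation`.
#' @export
locus_annotation <- function(exons, name = "focal", strand = "+") {
  exons <- dplyr::arrange(tibble::as_tibble(exons), .data$start)
  stopifnot(nrow(exons) >= 1, all(exons$end > exons$start))
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  structure(list(name = name, strand = strand, exons = exons),
            class = "locus_annotation")
}

#' Upstream-noncoding and first-intron sizes of a locus
#'
#' The upstream intergenic span is the distance from the 3' end of the
#' upstream gene to the 5' start of the focal gene; the first intron is
#' the gap between exon 1 and exon 2. Their sum is the combined "upper
#' noncoding" span of the locus.
#'
#' @param ann a [locus_annotation()] with at least two exons.
#' @param upstream_gene_3prime coordinate of the upstream gene's 3' end
#'   (same 0-based frame as the annotation; may be negative if the focal
#'   gene starts at 0).
#' @return one-row tibble: `upstream_intergenic`, `first_intron`,
#'   `upper_noncoding`.
#' @export
locus_sizes <- function(ann, upstream_gene_3prime) {
  stopifnot(inherits(ann, "locus_annotation"))
  if (nrow(ann$exons) < 2)
    stop("first intron requires at least two exons")
  focal_start <- ann$exons$start[[1]]
  upstream <- focal_start - upstream_gene_3prime
  if (upstream < 0)
    stop("upstream gene overlaps the focal gene: negative intergenic span")
  intron1 <- ann$exons$start[[2]] - ann$exons$end[[1]]
  tibble::tibble(upstream_intergenic = upstream, first_intron = intron1,
                 upper_noncoding = upstream + intron1)
}

#' Export alignment blocks as a dot-plot table
#'
#' Writes block endpoints as TSV (1-based inclusive coordinates, stated in
#' the file header): forward blocks are rising diagonals, reverse blocks
#' falling. The table round-trips losslessly through [read_dotplot()].
#'
#' @param blocks an [anchor_align()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_dotplot <- function(blocks, path) {
  con <- file(path, "w")
  writeLines(c("# dot-plot blocks; coordinates 1-based inclusive",
               "# forward blocks rise, reverse blocks fall",
               paste("q_start", "q_end", "s_start", "s_end", "orientation",
                     "matched_bases", sep = "\t")), con)
  if (nrow(blocks) > 0) {
    df <- data.frame(blocks$q_start + 1, blocks$q_end, blocks$s_start + 1,
                     blocks$s_end, blocks$orientation,
                     blocks$matched_bases)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  close(con)
  invisible(path)
}

#' @rdname export_dotplot
#' @export
read_dotplot <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  out <- tibble::tibble(q_start = df$q_start - 1L, q_end = df$q_end,
                        s_start = df$s_start - 1L, s_end = df$s_end,
                        orientation = df$orientation,
                        matched_bases = df$matched_bases)
  structure(out, class = c("alignment_blocks", class(out)))
}

#' Fraction of a reference covered by alignment blocks
#'
#' Aligns each sequence against the reference and measures the fraction
#' of reference positions covered by the union of block intervals.
#'
#' @param ref reference sequence (character or [hap_seq]).
#' @param seqs character vector of sequences to align.
#' @param ... passed to [anchor_align()].
#' @return covered fraction in `[0, 1]`.
#' @export
aligned_fraction <- function(ref, seqs, ...) {
  if (inherits(ref, "hap_seq")) ref <- ref$seq
  if (is.data.frame(seqs)) seqs <- seqs$seq
  ivs <- list()
  for (s in seqs) {
    b <- anchor_align(ref, s, ...)
    if (nrow(b) > 0)
      ivs[[length(ivs) + 1]] <- IRanges::IRanges(start = b$q_start + 1,
                                                 end = b$q_end)
  }
  if (length(ivs) == 0) return(0)
  merged <- IRanges::reduce(do.call(c, ivs))
  sum(IRanges::width(merged)) / nchar(ref)
}
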