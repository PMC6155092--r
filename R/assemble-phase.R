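#' Map read pairs onto assembly elements
#'
#' Reads are placed by runs of consecutive exact-matching seed k-mers
#' (default length 15) on a consistent diagonal; seeds occurring at more
#' than one location across the element set are ambiguous and never used,
#' so repeated sequence cannot attract reads. A read may touch several
#' elements (it can span the junctions between short unitigs); every touch
#' supported by at least `min_seeds` consecutive seeds is recorded. For
#' link building each read's primary element is the touch with the most
#' seeds (reads with tied primaries are discarded as ambiguous).
#'
#' Mate geometry is normalised to inward-facing ("innie") orientation
#' before link arithmetic, so outward-facing mate-pair libraries are
#' handled identically.
#'
#' @param pairs a `read_pairs` object from [simulate_reads()], or a list
#'   with `read1`, `read2` character vectors and `lib` a [lib_spec].
#' @param elements character vector of element sequences (unitigs or
#'   scaffolds), or a tibble with a `seq` column.
#' @param seed_len seed k-mer length (default 15).
#' @param min_seeds minimum consecutive seed matches per touch (default 3).
#' @return object of class `pair_links`: list with
#'   * `touches`: tibble `pair`, `mate`, `elem`, `strand`, `pos`, `nseeds`
#'     (every touch of every read);
#'   * `links`: tibble `elem_i`, `end_i`, `elem_j`, `end_j`, `count`,
#'     `gap_mean` — mate-based links between the primary elements of the
#'     two mates (`elem_i <= elem_j`; ends are the element ends the
#'     fragment extends from; `gap_mean` the implied gap);
#'   * `lib`: the library spec.
#' @export
map_pairs <- function(pairs, elements, seed_len = 15, min_seeds = 3) {
  if (is.data.frame(elements)) elements <- elements$seq
  stopifnot(is.character(elements))
  lib <- pairs$lib
  rl <- lib$read_len
  t1 <- tibble::as_tibble(cpp_map_touches(unname(pairs$read1), elements,
                                          seed_len, min_seeds))
  t2 <- tibble::as_tibble(cpp_map_touches(unname(pairs$read2), elements,
                                          seed_len, min_seeds))
  t1$mate <- 1L; t2$mate <- 2L
  touches <- dplyr::bind_rows(t1, t2)
  names(touches)[names(touches) == "read"] <- "pair"

  # innie normalisation: flipping both mates of an outie pair gives the
  # same fragment geometry as an innie pair
  if (lib$orientation == "outie") touches$strand <- -touches$strand

  elen <- nchar(elements)

  primary <- if (nrow(touches) == 0) touches else touches |>
    dplyr::group_by(.data$pair, .data$mate) |>
    dplyr::filter(.data$nseeds == max(.data$nseeds)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup()

  p1 <- primary[primary$mate == 1L, ]
  p2 <- primary[primary$mate == 2L, ]
  jj <- dplyr::inner_join(p1, p2, by = "pair", suffix = c("_1", "_2"))
  jj <- jj[jj$elem_1 != jj$elem_2, ]

  links <- tibble::tibble(elem_i = integer(), end_i = character(),
                          elem_j = integer(), end_j = character(),
                          count = integer(), gap_mean = numeric())
  if (nrow(jj) > 0) {
    # end the fragment extends from, and outward distance consumed on each
    # element (innie geometry: a forward mate points right, reverse left)
    end_of <- function(strand) ifelse(strand == 1, "R", "L")
    dist_of <- function(elem, strand, pos)
      ifelse(strand == 1, elen[elem] - pos, pos + rl)
    e1 <- end_of(jj$strand_1); e2 <- end_of(jj$strand_2)
    d1 <- dist_of(jj$elem_1, jj$strand_1, jj$pos_1)
    d2 <- dist_of(jj$elem_2, jj$strand_2, jj$pos_2)
    gap <- lib$insert_mean - d1 - d2
    swap <- jj$elem_1 > jj$elem_2
    li <- tibble::tibble(
      elem_i = ifelse(swap, jj$elem_2, jj$elem_1),
      end_i = ifelse(swap, e2, e1),
      elem_j = ifelse(swap, jj$elem_1, jj$elem_2),
      end_j = ifelse(swap, e1, e2),
      gap = gap)
    links <- li |>
      dplyr::group_by(.data$elem_i, .data$end_i, .data$elem_j,
                      .data$end_j) |>
      dplyr::summarise(count = dplyr::n(), gap_mean = mean(.data$gap),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$elem_i, .data$elem_j)
  }
  structure(list(touches = touches, links = links, lib = lib),
            class = "pair_links")
}

#' @export
print.pair_links <- function(x, ...) {
  cat(sprintf("<pair_links> %d touches, %d link classes\n",
              nrow(x$touches), nrow(x$links)))
  invisible(x)
}

#' Phase bubbles into two haplotype classes
#'
#' Builds a graph whose vertices are bubble arms and whose edge weights are
#' the number of fragments (mate pairs, or single reads spanning two arms)
#' co-touching the two arms. Arm pairs are merged greedily in descending
#' weight order into two haplotype classes per connected component; merges
#' contradicting an existing assignment are skipped. Within a component the
#' labelling is relative (a global 0/1 swap is unidentifiable); the
#' component representative (smallest bubble id) is assigned phase 0.
#'
#' @param bubbles a [detect_bubbles()] result.
#' @param links one `pair_links` object (or a list of them, e.g. one per
#'   library) mapped onto the *unitig* set that the bubbles refer to.
#' @return tibble of class `bubble_phasing`: `bubble`, `component`,
#'   `phase` (0 = arm `a` belongs to haplotype 0 of its component), plus
#'   attribute `n_contradicted`.
#' @export
phase_bubbles <- function(bubbles, links) {
  if (inherits(links, "pair_links")) links <- list(links)
  arm_of <- c(stats::setNames(rep(seq_len(nrow(bubbles)), 2),
                              c(bubbles$arm_a, bubbles$arm_b)))
  is_a <- c(stats::setNames(c(rep(TRUE, nrow(bubbles)),
                              rep(FALSE, nrow(bubbles))),
                            c(bubbles$arm_a, bubbles$arm_b)))
  arm_ids <- c(bubbles$arm_a, bubbles$arm_b)

  # fragment-level co-touches between arm unitigs
  co <- list()
  for (pl in links) {
    tt <- pl$touches[pl$touches$elem %in% arm_ids, c("pair", "elem")]
    tt <- dplyr::distinct(tt)
    if (nrow(tt) == 0) next
    jj <- dplyr::inner_join(tt, tt, by = "pair",
                            relationship = "many-to-many")
    jj <- jj[jj$elem.x < jj$elem.y, ]
    co[[length(co) + 1]] <- jj[, c("elem.x", "elem.y")]
  }
  n_b <- nrow(bubbles)
  phasing_empty <- function() tibble::tibble(
    bubble = bubbles$bubble, component = seq_len(n_b),
    phase = rep(0L, n_b))
  if (length(co) == 0) {
    out <- phasing_empty()
    attr(out, "n_contradicted") <- 0L
    return(structure(out, class = c("bubble_phasing", class(out))))
  }
  co <- dplyr::bind_rows(co)
  names(co) <- c("u1", "u2")
  w <- co |>
    dplyr::count(.data$u1, .data$u2, name = "weight") |>
    dplyr::mutate(b1 = arm_of[as.character(.data$u1)],
                  b2 = arm_of[as.character(.data$u2)],
                  parity = as.integer(is_a[as.character(.data$u1)] !=
                                        is_a[as.character(.data$u2)])) |>
    dplyr::filter(.data$b1 != .data$b2) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$b1, .data$b2,
                   .data$parity)

  # union-find with parity
  parent <- seq_len(n_b)
  par_to_root <- integer(n_b)
  find <- function(b) {
    p <- 0L
    while (parent[b] != b) {
      p <- xor_int(p, par_to_root[b])
      b <- parent[b]
    }
    c(b, p)
  }
  n_contr <- 0L
  if (nrow(w) > 0) for (i in seq_len(nrow(w))) {
    r1 <- find(w$b1[i]); r2 <- find(w$b2[i])
    want <- xor_int(xor_int(r1[2], r2[2]), w$parity[i])
    if (r1[1] == r2[1]) {
      if (want != 0L) n_contr <- n_contr + 1L
      next
    }
    # attach the larger root id under the smaller (deterministic)
    if (r1[1] < r2[1]) {
      parent[r2[1]] <- r1[1]; par_to_root[r2[1]] <- want
    } else {
      parent[r1[1]] <- r2[1]; par_to_root[r1[1]] <- want
    }
  }
  comp <- integer(n_b); phase <- integer(n_b)
  for (b in seq_len(n_b)) {
    f <- find(b); comp[b] <- f[1]; phase[b] <- f[2]
  }
  comp <- match(comp, sort(unique(comp)))
  out <- tibble::tibble(bubble = bubbles$bubble, component = comp,
                        phase = phase)
  attr(out, "n_contradicted") <- n_contr
  structure(out, class = c("bubble_phasing", class(out)))
}

xor_int <- function(a, b) as.integer(xor(a == 1L, b == 1L))
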