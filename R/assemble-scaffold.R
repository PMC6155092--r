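# Haplotype path walking over the unitig graph, mate-pair scaffolding with
# N gaps, consensus construction, and the mate-pair window-link validation.

# out-edges of one unitig end, restricted to an allowed unitig set
out_edges_of <- function(ed, uid, uend, allowed) {
  hit <- ed$u == uid & ed$u_end == uend & ed$v %in% allowed &
    ed$u %in% allowed
  ed[hit, c("v", "v_end")]
}

# maximal simple paths over the allowed unitig subset; returns a list of
# tibbles (id, orient) in left-to-right order
walk_paths <- function(un, ed, allowed) {
  visited <- rep(FALSE, nrow(un))
  paths <- list()
  for (u in sort(allowed)) {
    if (visited[u]) next
    visited[u] <- TRUE
    path <- list(list(id = u, orient = "+"))
    # rightwards
    cur_id <- u; cur_or <- "+"
    repeat {
      rend <- if (cur_or == "+") "R" else "L"
      nx <- out_edges_of(ed, cur_id, rend, allowed)
      if (nrow(nx) != 1) break
      v <- nx$v[1]; ve <- nx$v_end[1]
      if (visited[v]) break
      if (nrow(out_edges_of(ed, v, ve, allowed)) != 1) break
      cur_or <- if (ve == "L") "+" else "-"
      cur_id <- v
      visited[v] <- TRUE
      path[[length(path) + 1]] <- list(id = v, orient = cur_or)
    }
    # leftwards from the start
    cur_id <- u; cur_or <- "+"
    pre <- list()
    repeat {
      lend <- if (cur_or == "+") "L" else "R"
      nx <- out_edges_of(ed, cur_id, lend, allowed)
      if (nrow(nx) != 1) break
      v <- nx$v[1]; ve <- nx$v_end[1]
      if (visited[v]) break
      if (nrow(out_edges_of(ed, v, ve, allowed)) != 1) break
      cur_or <- if (ve == "R") "+" else "-"
      cur_id <- v
      visited[v] <- TRUE
      pre[[length(pre) + 1]] <- list(id = v, orient = cur_or)
    }
    path <- c(rev(pre), path)
    paths[[length(paths) + 1]] <- dplyr::bind_rows(lapply(path, tibble::as_tibble))
  }
  paths
}

path_sequence <- function(un, path, k) {
  segs <- character(nrow(path))
  for (i in seq_len(nrow(path))) {
    s <- un$seq[path$id[i]]
    if (path$orient[i] == "-") s <- revcomp(s)
    segs[i] <- if (i == 1) s else substr(s, k, nchar(s))
  }
  paste(segs, collapse = "")
}

#' Assemble phased scaffolds from a bubble graph
#'
#' Implements the haplotype-extension steps of the bubble-phasing
#' procedure: for each haplotype, the unitig graph restricted to nonbubble
#' unitigs plus that haplotype's phased bubble arms is walked into maximal
#' simple paths (contigs); then, for each library in ascending insert-size
#' order, read pairs are mapped onto the current scaffolds and element
#' ends connected by at least `min_links` concordant links are joined with
#' an N gap of length `max(1, round(insert_mean - flank distances))`.
#' Ends claimed by two partners with similar support (the runner-up
#' carries at least half the best count) are left unjoined and the
#' conflict logged. Finally homologous scaffolds — those carrying arms of
#' the same bubbles — are paired; the longer of a pair is labelled
#' `primary`, the shorter `secondary`, unpaired scaffolds `nonbubble`.
#'
#' @param graph a [build_graph()] result (built from all libraries).
#' @param bubbles a [detect_bubbles()] result.
#' @param phasing a [phase_bubbles()] result.
#' @param libraries list of `read_pairs` objects (any order; sorted by
#'   insert size internally).
#' @param min_links minimum concordant link count to join (default 3).
#' @param seed_len,min_seeds mapping parameters, see [map_pairs()].
#' @return object of class `phased_assembly`: list with `k`, `scaffolds`
#'   (tibble `id`, `seq`, `length`, `role`, `partner`, `hap`,
#'   `bubbles` list-column, `provenance` list-column), `bubbles`,
#'   `phasing`, `join_log`.
#' @export
scaffold_and_iterate <- function(graph, bubbles, phasing, libraries,
                                 min_links = 3, seed_len = 15,
                                 min_seeds = 3) {
  stopifnot(length(libraries) >= 1)
  un <- graph$unitigs; ed <- graph$edges; k <- graph$k
  ins <- vapply(libraries, function(l) l$lib$insert_mean, numeric(1))
  libraries <- libraries[order(ins)]

  arm_ids <- c(bubbles$arm_a, bubbles$arm_b)
  nonbubble_ids <- setdiff(un$id, arm_ids)
  chosen <- function(h) {
    if (nrow(bubbles) == 0) return(integer(0))
    ifelse((phasing$phase + h) %% 2 == 0, bubbles$arm_a, bubbles$arm_b)
  }

  scafs <- list()
  for (h in 0:1) {
    allowed <- sort(c(nonbubble_ids, chosen(h)))
    if (length(allowed) == 0) next
    paths <- walk_paths(un, ed, allowed)
    for (p in paths) {
      bub <- if (nrow(bubbles) == 0) integer(0) else
        bubbles$bubble[bubbles$arm_a %in% p$id | bubbles$arm_b %in% p$id]
      scafs[[length(scafs) + 1]] <- tibble::tibble(
        seq = path_sequence(un, p, k), hap = h,
        bubbles = list(sort(bub)),
        provenance = list(p))
    }
  }
  scaf <- dplyr::bind_rows(scafs)
  # nonbubble contigs are identical in both haplotype walks: keep one copy
  nb <- lengths(scaf$bubbles) == 0
  if (any(nb)) {
    key <- vapply(scaf$seq, function(s) min(s, revcomp(s)), character(1))
    drop <- nb & duplicated(key)
    scaf <- scaf[!drop, ]
    scaf$hap[lengths(scaf$bubbles) == 0] <- NA_integer_
  }
  scaf$id <- seq_len(nrow(scaf))
  scaf$length <- nchar(scaf$seq)

  join_log <- tibble::tibble(stage = character(), elem_i = integer(),
                             elem_j = integer(), reason = character())
  for (lib_pairs in libraries) {
    repeat {
      res <- join_once(scaf, lib_pairs, min_links, seed_len, min_seeds)
      join_log <- dplyr::bind_rows(join_log, res$log)
      if (!res$joined) break
      scaf <- res$scaf
    }
  }

  scaf <- label_roles(scaf)
  structure(list(k = k, scaffolds = scaf, bubbles = bubbles,
                 phasing = phasing, join_log = join_log),
            class = "phased_assembly")
}

# one greedy join pass: map the library, take the best non-conflicted
# candidate, join it; returns the updated scaffold set
join_once <- function(scaf, lib_pairs, min_links, seed_len, min_seeds) {
  log0 <- tibble::tibble(stage = character(), elem_i = integer(),
                         elem_j = integer(), reason = character())
  if (nrow(scaf) < 2) return(list(joined = FALSE, scaf = scaf, log = log0))
  pl <- map_pairs(lib_pairs, scaf$seq, seed_len = seed_len,
                  min_seeds = min_seeds)
  cand <- pl$links[pl$links$count >= min_links & pl$links$gap_mean >
                     -2 * lib_pairs$lib$insert_sd - 100, ]
  if (nrow(cand) == 0) return(list(joined = FALSE, scaf = scaf, log = log0))
  end_key <- function(e, s) paste(e, s)
  ki <- end_key(cand$elem_i, cand$end_i)
  kj <- end_key(cand$elem_j, cand$end_j)
  for (r in seq_len(nrow(cand))) {
    shares <- which(ki %in% c(ki[r], kj[r]) | kj %in% c(ki[r], kj[r]))
    rival_rows <- setdiff(shares, r)
    if (length(rival_rows) > 0 &&
        any(cand$count[rival_rows] >= pmax(min_links, cand$count[r] / 2))) {
      log0 <- dplyr::bind_rows(log0, tibble::tibble(
        stage = "join-conflict", elem_i = cand$elem_i[r],
        elem_j = cand$elem_j[r], reason = "two partners with similar support"))
      next
    }
    i <- cand$elem_i[r]; j <- cand$elem_j[r] # row positions in scaf
    si <- scaf$seq[i]; sj <- scaf$seq[j]
    if (cand$end_i[r] == "L") si <- revcomp(si)
    if (cand$end_j[r] == "R") sj <- revcomp(sj)
    gap <- max(1, round(cand$gap_mean[r]))
    merged <- paste0(si, strrep("N", gap), sj)
    ri <- scaf[i, ]; rj <- scaf[j, ]
    new <- tibble::tibble(
      seq = merged,
      hap = if (identical(ri$hap, rj$hap)) ri$hap else NA_integer_,
      bubbles = list(sort(union(ri$bubbles[[1]], rj$bubbles[[1]]))),
      provenance = list(dplyr::bind_rows(ri$provenance[[1]],
                                         rj$provenance[[1]])),
      id = max(scaf$id) + 1L)
    new$length <- nchar(new$seq)
    scaf <- dplyr::bind_rows(scaf[-c(i, j), ], new)
    return(list(joined = TRUE, scaf = scaf, log = log0))
  }
  list(joined = FALSE, scaf = scaf, log = log0)
}

# primary/secondary/nonbubble labels via shared bubble content
label_roles <- function(scaf) {
  n <- nrow(scaf)
  role <- rep("nonbubble", n)
  partner <- rep(NA_integer_, n)
  has_b <- lengths(scaf$bubbles) > 0
  idx <- which(has_b)
  if (length(idx) >= 2) {
    shared <- function(a, b) length(intersect(scaf$bubbles[[a]],
                                              scaf$bubbles[[b]]))
    for (a in idx) {
      if (!is.na(partner[a])) next
      best <- 0L; bb <- NA_integer_
      for (b in setdiff(idx, a)) {
        if (!is.na(partner[b])) next
        s <- shared(a, b)
        if (s > best) { best <- s; bb <- b }
      }
      if (!is.na(bb) && best > 0) { partner[a] <- bb; partner[bb] <- a }
    }
    for (a in idx) {
      if (is.na(partner[a])) next
      b <- partner[a]
      if (scaf$length[a] > scaf$length[b] ||
          (scaf$length[a] == scaf$length[b] &&
             scaf$seq[a] <= scaf$seq[b])) {
        role[a] <- "primary"; role[b] <- "secondary"
      }
    }
  }
  scaf$role <- role
  scaf$partner <- scaf$id[partner]
  scaf
}

#' @export
print.phased_assembly <- function(x, ...) {
  s <- x$scaffolds
  cat(sprintf(
    "<phased_assembly> k=%d: %d scaffold(s) [%d primary, %d secondary, %d nonbubble], %d bubble(s)\n",
    x$k, nrow(s), sum(s$role == "primary"), sum(s$role == "secondary"),
    sum(s$role == "nonbubble"), nrow(x$bubbles)))
  invisible(x)
}

#' Build consensus scaffolds from a phased assembly
#'
#' Secondary scaffolds are set aside; primary and nonbubble scaffolds are
#' (optionally) joined by remaining mate-pair links exactly as in
#' scaffolding. The result is a mosaic of haplotypes; provenance records
#' which source scaffold (and haplotype) each piece came from and never
#' contains a secondary scaffold.
#'
#' @param assembly a [scaffold_and_iterate()] result.
#' @param libraries optional list of `read_pairs` used to join consensus
#'   pieces (largest insert first is unnecessary; all are used ascending).
#' @param min_links,seed_len,min_seeds as in [scaffold_and_iterate()].
#' @return tibble of class `consensus_set`: `id`, `seq`, `length`,
#'   `sources` (list-column of tibbles `id`, `hap`, `role`).
#' @export
build_consensus <- function(assembly, libraries = NULL, min_links = 3,
                            seed_len = 15, min_seeds = 3) {
  s <- assembly$scaffolds
  keep <- s[s$role %in% c("primary", "nonbubble"),
            c("id", "seq", "length", "hap", "bubbles")]
  # provenance: one record per source phased scaffold, never a secondary
  keep$provenance <- lapply(seq_len(nrow(keep)), function(i)
    tibble::tibble(id = keep$id[i], hap = keep$hap[i],
                   role = s$role[s$id == keep$id[i]]))
  if (!is.null(libraries) && nrow(keep) >= 2) {
    ins <- vapply(libraries, function(l) l$lib$insert_mean, numeric(1))
    for (lp in libraries[order(ins)]) {
      repeat {
        res <- join_once(keep, lp, min_links, seed_len, min_seeds)
        if (!res$joined) break
        keep <- res$scaf
      }
    }
  }
  ord <- order(-keep$length)
  out <- keep[ord, c("id", "seq", "length")]
  out$sources <- keep$provenance[ord]
  out$id <- seq_len(nrow(out))
  structure(out, class = c("consensus_set", class(out)))
}

#' Mate-pair link matrix over fixed windows of a scaffold
#'
#' Segments a scaffold into fixed windows (default 2 kb), maps a mate-pair
#' library onto it, and counts pairs with one mate in window `i` and the
#' other in window `j`. Window pairs supported by fewer than `min_links`
#' mate pairs are reported as zero (dropped from the sparse table). On a
#' correctly assembled scaffold the retained links concentrate on the
#' off-diagonal band `|i - j| ~ insert / window`; a mis-join shows a band
#' interruption with no retained links across the junction.
#'
#' @param scaffold character scalar (or `consensus_set` row / `hap_seq`).
#' @param pairs a `read_pairs` mate-pair library.
#' @param window window size in bp (default 2000).
#' @param min_links minimum mate pairs per retained window pair (default 3).
#' @param seed_len,min_seeds mapping parameters.
#' @return tibble of class `window_links`: `window_i`, `window_j`
#'   (0-based, `window_i <= window_j`), `links`; attributes `window`,
#'   `n_windows`, `min_links`.
#' @export
window_link_matrix <- function(scaffold, pairs, window = 2000,
                               min_links = 3, seed_len = 15,
                               min_seeds = 3) {
  if (inherits(scaffold, "hap_seq")) scaffold <- scaffold$seq
  if (is.data.frame(scaffold)) scaffold <- scaffold$seq[[1]]
  stopifnot(is.character(scaffold), length(scaffold) == 1)
  if (nchar(scaffold) < 2 * window)
    stop("scaffold must be at least two windows long")
  n_win <- ceiling(nchar(scaffold) / window)
  pl <- map_pairs(pairs, scaffold, seed_len = seed_len,
                  min_seeds = min_seeds)
  tt <- pl$touches
  rl <- pairs$lib$read_len
  best <- tt |>
    dplyr::group_by(.data$pair, .data$mate) |>
    dplyr::slice_max(.data$nseeds, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(win = pmin(n_win - 1, pmax(0, floor(
      (.data$pos + rl / 2) / window))))
  w1 <- best[best$mate == 1, c("pair", "win")]
  w2 <- best[best$mate == 2, c("pair", "win")]
  jj <- dplyr::inner_join(w1, w2, by = "pair", suffix = c("_1", "_2"))
  out <- jj |>
    dplyr::mutate(window_i = pmin(.data$win_1, .data$win_2),
                  window_j = pmax(.data$win_1, .data$win_2)) |>
    dplyr::count(.data$window_i, .data$window_j, name = "links") |>
    dplyr::filter(.data$links >= min_links)
  structure(out, class = c("window_links", class(out)), window = window,
            n_windows = n_win, min_links = min_links)
}

#' Dense symmetric matrix form of a window link table
#'
#' @param x a [window_link_matrix()] result.
#' @return an integer matrix, windows by windows.
#' @export
window_link_dense <- function(x) {
  n <- attr(x, "n_windows")
  m <- matrix(0L, n, n)
  if (nrow(x) > 0) {
    m[cbind(x$window_i + 1, x$window_j + 1)] <- x$links
    m[cbind(x$window_j + 1, x$window_i + 1)] <- x$links
  }
  m
}

#' Assembly contiguity statistics
#'
#' @param seqs character vector of scaffold sequences (or a tibble with a
#'   `seq` column).
#' @return one-row tibble: `n`, `total_length`, `n50`, `longest`.
#' @export
assembly_stats <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  len <- sort(nchar(seqs), decreasing = TRUE)
  cum <- cumsum(len)
  n50 <- if (length(len) == 0) NA_integer_ else
    len[which(cum >= cum[length(cum)] / 2)[1]]
  tibble::tibble(n = length(len), total_length = sum(len), n50 = n50,
                 longest = if (length(len) == 0) NA_integer_ else len[1])
}

#' Gapless identity between two sequences
#'
#' Finds the dominant shared-unique-k-mer diagonal between `a` and `b`
#' (both strands) and compares the two sequences base-by-base along it.
#' Intended for SNP-divergent, indel-free comparisons (e.g. a phased
#' scaffold against the haplotype it was simulated from), where a single
#' gapless offset captures the whole alignment.
#'
#' @param a,b character scalars (or [hap_seq]).
#' @param L anchor k-mer length (default 15).
#' @return list: `identity` (matches / aligned columns), `strand` (+1/-1),
#'   `offset` (start of `a` on `b`, 0-based, for the reported strand of
#'   `b`), `aligned` (number of compared columns).
#' @export
seq_identity <- function(a, b, L = 15) {
  if (inherits(a, "hap_seq")) a <- a$seq
  if (inherits(b, "hap_seq")) b <- b$seq
  # N gaps (scaffold joins) break the single-diagonal assumption: score
  # each N-free segment on its own best diagonal and pool the columns
  segs <- strsplit(a, "N+")[[1]]
  segs <- segs[nchar(segs) >= max(2 * L, 50)]
  if (length(segs) == 0) return(list(identity = 0, strand = NA_integer_,
                                     aligned = 0L))
  brc <- revcomp(b)
  seg_score <- function(seg, bb) {
    m <- cpp_unique_matches(seg, bb, L)
    m <- m[m$strand == 1, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    d_tab <- sort(table(m$spos - m$qpos), decreasing = TRUE)
    d <- as.integer(names(d_tab)[1])
    a_from <- max(0, -d); b_from <- max(0, d)
    n_cmp <- min(nchar(seg) - a_from, nchar(bb) - b_from)
    if (n_cmp <= 0) return(NULL)
    va <- utf8ToInt(substr(seg, a_from + 1, a_from + n_cmp))
    vb <- utf8ToInt(substr(bb, b_from + 1, b_from + n_cmp))
    list(matches = sum(va == vb), aligned = n_cmp, support = nrow(m))
  }
  tot <- c(fw = 0, rv = 0)
  per_seg <- lapply(segs, function(seg) {
    fw <- seg_score(seg, b)
    rv <- seg_score(seg, brc)
    use_rv <- is.null(fw) || (!is.null(rv) && rv$support > fw$support)
    sc <- if (use_rv) rv else fw
    if (is.null(sc)) return(NULL)
    sc$strand <- if (use_rv) -1L else 1L
    sc
  })
  per_seg <- per_seg[!vapply(per_seg, is.null, logical(1))]
  if (length(per_seg) == 0) return(list(identity = 0,
                                        strand = NA_integer_,
                                        aligned = 0L))
  matches <- sum(vapply(per_seg, `[[`, numeric(1), "matches"))
  aligned <- sum(vapply(per_seg, `[[`, numeric(1), "aligned"))
  strands <- vapply(per_seg, `[[`, integer(1), "strand")
  list(identity = matches / aligned,
       strand = if (mean(strands == 1) >= 0.5) 1L else -1L,
       aligned = as.integer(aligned))
}
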