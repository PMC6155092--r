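#' Haplotype sequence objects
#'
#' A `hap_seq` is a lightweight container for one haplotype: a DNA sequence
#' plus a feature table (`label`, `start`, `end`; 0-based half-open
#' intervals), standing for a per-allele genomic scaffold around a locus.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param name scaffold name.
#' @param features tibble with columns `label`, `start`, `end` (0-based
#'   half-open, within `[0, nchar(seq))`).
#' @return an object of class `hap_seq`.
#' @export
hap_seq <- function(seq, name = "hap", features = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (is.null(features)) {
    features <- tibble::tibble(label = character(), start = integer(),
                               end = integer())
  }
  features <- tibble::as_tibble(features)
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  n <- nchar(seq)
  if (nrow(features) > 0) {
    stopifnot(all(features$start >= 0), all(features$end <= n),
              all(features$end > features$start))
    # intervals of a single label must not overlap
    by_lab <- split(features, features$label)
    for (f in by_lab) {
      f <- f[order(f$start), ]
      if (nrow(f) > 1 && any(f$start[-1] < f$end[-nrow(f)]))
        stop("overlapping feature intervals for label ", f$label[[1]])
    }
  }
  structure(list(name = name, seq = seq, features = features),
            class = "hap_seq")
}

#' @export
print.hap_seq <- function(x, ...) {
  cat("<hap_seq> ", x$name, ": ", format(nchar(x$seq), big.mark = ","),
      " bp, ", nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

#' @export
length.hap_seq <- function(x) nchar(x$seq)

#' Generate a random genome sequence
#'
#' Bases are drawn independently with the requested GC content; optionally a
#' fraction of the genome is made up of duplicated segments (>= 300 bp each)
#' to exercise repeat-sensitive downstream steps. Deterministic for a fixed
#' seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param repeat_fraction fraction of the genome covered by duplicated
#'   segments (default 0).
#' @param seed integer seed.
#' @param name scaffold name.
#' @return a [hap_seq].
#' @export
generate_genome <- function(length, gc = 0.5, repeat_fraction = 0, seed = 1,
                            name = "genome") {
  if (length < 1000) stop("genome length must be at least 1000 bp")
  stopifnot(gc > 0, gc < 1, repeat_fraction >= 0, repeat_fraction < 0.9)
  with_op_seed(seed, "generate_genome", {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    if (repeat_fraction > 0) {
      target <- round(repeat_fraction * length)
      placed <- 0
      while (placed < target) {
        rl <- min(sample(300:1000, 1), length %/% 4)
        src <- sample.int(length - rl + 1, 1)
        dst <- sample.int(length - rl + 1, 1)
        bases[dst:(dst + rl - 1)] <- bases[src:(src + rl - 1)]
        placed <- placed + rl
      }
    }
    hap_seq(paste(bases, collapse = ""), name = name)
  })
}

#' Variant ledgers
#'
#' A `variant_ledger` records the exact edit from a parent haplotype to a
#' derived allele, in three classes applied in a fixed order by
#' [apply_ledger()]:
#'
#' 1. `inversions` (tibble `start`, `end`): 0-based half-open intervals in
#'    parent coordinates, reverse-complemented in place (length preserving).
#' 2. `snps` (tibble `pos`, `ref`, `alt`): substitutions at 0-based
#'    positions of the post-inversion sequence.
#' 3. `indels` (tibble `pos`, `seq`, `sign`): at 0-based positions of the
#'    post-SNP sequence; `sign = +1` inserts `seq` before `pos`, `sign = -1`
#'    deletes `nchar(seq)` bases starting at `pos` (which must equal `seq`).
#'    Positions refer to the pre-indel sequence; application is in
#'    descending position order so records do not shift each other.
#'
#' @param snps,indels,inversions tibbles as described above.
#' @return an object of class `variant_ledger`.
#' @export
variant_ledger <- function(snps = NULL, indels = NULL, inversions = NULL) {
  empty <- function(...) tibble::tibble(...)
  if (is.null(snps)) snps <- empty(pos = integer(), ref = character(),
                                   alt = character())
  if (is.null(indels)) indels <- empty(pos = integer(), seq = character(),
                                       sign = integer())
  if (is.null(inversions)) inversions <- empty(start = integer(),
                                               end = integer())
  snps <- dplyr::arrange(tibble::as_tibble(snps), .data$pos)
  indels <- dplyr::arrange(tibble::as_tibble(indels), .data$pos)
  inversions <- dplyr::arrange(tibble::as_tibble(inversions), .data$start)
  if (anyDuplicated(snps$pos)) stop("duplicate SNP positions")
  if (anyDuplicated(indels$pos)) stop("duplicate indel positions")
  if (nrow(inversions) > 0) {
    if (any(inversions$end <= inversions$start))
      stop("inversion length must be positive")
    if (nrow(inversions) > 1 &&
        any(inversions$start[-1] < inversions$end[-nrow(inversions)]))
      stop("overlapping inversions are not supported")
  }
  structure(list(snps = snps, indels = indels, inversions = inversions),
            class = "variant_ledger")
}

#' @export
print.variant_ledger <- function(x, ...) {
  cat("<variant_ledger> ", nrow(x$snps), " SNP(s), ", nrow(x$indels),
      " indel(s), ", nrow(x$inversions), " inversion(s)\n", sep = "")
  invisible(x)
}

#' Apply a variant ledger to a parent haplotype
#'
#' Replays the ledger (inversions, then SNPs, then indels; see
#' [variant_ledger()] for the coordinate conventions) and returns the
#' derived sequence. `apply_ledger(parent, ledger)` reproduces the child of
#' [derive_allele()] byte-for-byte.
#'
#' @param parent a [hap_seq] or character scalar.
#' @param ledger a [variant_ledger].
#' @param name name for the returned haplotype.
#' @return a [hap_seq].
#' @export
apply_ledger <- function(parent, ledger, name = "derived") {
  seq <- if (inherits(parent, "hap_seq")) parent$seq else parent
  stopifnot(inherits(ledger, "variant_ledger"))
  n <- nchar(seq)
  inv <- ledger$inversions
  if (nrow(inv) > 0) {
    stopifnot(all(inv$start >= 0), all(inv$end <= n))
    for (i in seq_len(nrow(inv))) {
      s <- inv$start[[i]]; e <- inv$end[[i]]
      seg <- substr(seq, s + 1, e)
      substr(seq, s + 1, e) <- revcomp(seg)
    }
  }
  if (nrow(ledger$snps) > 0) {
    sp <- ledger$snps
    stopifnot(all(sp$pos >= 0), all(sp$pos < n))
    ref <- substring(seq, sp$pos + 1, sp$pos + 1)
    if (!all(ref == sp$ref))
      stop("ledger SNP reference bases do not match the parent sequence")
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    v[sp$pos + 1] <- sp$alt
    seq <- paste(v, collapse = "")
  }
  if (nrow(ledger$indels) > 0) {
    idl <- dplyr::arrange(ledger$indels, dplyr::desc(.data$pos))
    for (i in seq_len(nrow(idl))) {
      p <- idl$pos[[i]]; s <- idl$seq[[i]]; sgn <- idl$sign[[i]]
      if (sgn > 0) {
        seq <- paste0(substr(seq, 1, p), s, substr(seq, p + 1, nchar(seq)))
      } else {
        del <- substr(seq, p + 1, p + nchar(s))
        if (del != s) stop("ledger deletion does not match the sequence")
        seq <- paste0(substr(seq, 1, p), substr(seq, p + nchar(s) + 1,
                                                nchar(seq)))
      }
    }
  }
  hap_seq(seq, name = name)
}

#' Derive a diverged allele from a parent haplotype
#'
#' Samples SNPs and small indels at the requested per-bp rates, applies the
#' requested large inversions (reverse-complemented in place), and returns
#' both the derived haplotype and the exact [variant_ledger()] describing
#' the edit. This emulates allelic divergence at a locus whose alleles
#' differ by large inversions plus background point divergence.
#'
#' SNPs and indels are never placed so close to an inversion boundary that
#' coordinate classes would interact (indels are sampled outside inversion
#' intervals).
#'
#' @param parent a [hap_seq].
#' @param snp_rate per-bp substitution rate.
#' @param indel_rate per-bp indel rate (sizes 1-10 bp, insertions and
#'   deletions equally likely).
#' @param inversions tibble or data.frame with `start`, `end` (0-based
#'   half-open, non-overlapping) or `NULL`.
#' @param insertions optional tibble with `pos`, `len`: explicit large
#'   insertions (e.g. an intron expansion) added to the ledger as indels.
#' @param seed integer seed.
#' @param name name for the derived haplotype.
#' @return list with elements `hap` (a [hap_seq]) and `ledger`
#'   (a [variant_ledger]).
#' @export
derive_allele <- function(parent, snp_rate = 0.005, indel_rate = 0,
                          inversions = NULL, insertions = NULL, seed = 1,
                          name = paste0(parent$name, "_allele")) {
  stopifnot(inherits(parent, "hap_seq"))
  n <- nchar(parent$seq)
  if (!is.null(inversions)) {
    inversions <- tibble::as_tibble(inversions)
    stopifnot(all(inversions$start >= 0), all(inversions$end <= n))
  }
  with_op_seed(seed, "derive_allele", {
    # SNPs: sampled on the parent, positions carried through inversions
    # unchanged (inversions are length preserving), so ledger SNP positions
    # are valid post-inversion coordinates once ref bases are re-read there.
    n_snp <- rbinom(1, n, snp_rate)
    snp_pos <- sort(sample.int(n, n_snp) - 1L)
    n_ind <- rbinom(1, n, indel_rate)
    ind_pos <- sort(sample.int(n, n_ind) - 1L)
    if (!is.null(inversions) && nrow(inversions) > 0 && length(ind_pos) > 0) {
      inside <- rep(FALSE, length(ind_pos))
      for (i in seq_len(nrow(inversions))) {
        inside <- inside | (ind_pos >= inversions$start[[i]] - 10 &
                              ind_pos < inversions$end[[i]] + 10)
      }
      ind_pos <- ind_pos[!inside]
    }
    # keep sampled indels >= 12 bp apart so descending-order application
    # can never touch a later record's bases
    if (length(ind_pos) > 1)
      ind_pos <- ind_pos[c(TRUE, diff(ind_pos) >= 12)]

    inv_tbl <- if (is.null(inversions)) NULL else inversions
    # build the post-inversion sequence to read SNP reference bases
    base_led <- variant_ledger(inversions = inv_tbl)
    post_inv <- apply_ledger(parent, base_led, name = name)$seq

    snp_tbl <- NULL
    if (length(snp_pos) > 0) {
      ref <- substring(post_inv, snp_pos + 1, snp_pos + 1)
      keep <- ref %in% c("A", "C", "G", "T")
      snp_pos <- snp_pos[keep]; ref <- ref[keep]
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1), character(1))
      snp_tbl <- tibble::tibble(pos = snp_pos, ref = ref, alt = unname(alt))
    }

    ind_tbl <- NULL
    if (length(ind_pos) > 0 || !is.null(insertions)) {
      rows <- list()
      post_snp <- apply_ledger(parent,
                               variant_ledger(snps = snp_tbl,
                                              inversions = inv_tbl))$seq
      for (p in ind_pos) {
        sz <- sample(1:10, 1)
        if (runif(1) < 0.5) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            pos = p, seq = paste(sample(c("A", "C", "G", "T"), sz,
                                        replace = TRUE), collapse = ""),
            sign = 1L)
        } else {
          if (p + sz > nchar(post_snp)) next
          rows[[length(rows) + 1]] <- tibble::tibble(
            pos = p, seq = substr(post_snp, p + 1, p + sz), sign = -1L)
        }
      }
      if (!is.null(insertions)) {
        insertions <- tibble::as_tibble(insertions)
        for (i in seq_len(nrow(insertions))) {
          ins <- paste(sample(c("A", "C", "G", "T"), insertions$len[[i]],
                              replace = TRUE), collapse = "")
          rows[[length(rows) + 1]] <- tibble::tibble(
            pos = insertions$pos[[i]], seq = ins, sign = 1L)
        }
      }
      if (length(rows) > 0) ind_tbl <- dplyr::bind_rows(rows)
      if (!is.null(ind_tbl) && anyDuplicated(ind_tbl$pos) > 0)
        ind_tbl <- ind_tbl[!duplicated(ind_tbl$pos), ]
    }

    ledger <- variant_ledger(snps = snp_tbl, indels = ind_tbl,
                             inversions = inv_tbl)
    child <- apply_ledger(parent, ledger, name = name)
    child$features <- parent$features
    list(hap = child, ledger = ledger)
  })
}

#' Write haplotype features as BED
#'
#' BED uses 0-based half-open intervals, matching the internal convention.
#'
#' @param hap a [hap_seq].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hap, path) {
  stopifnot(inherits(hap, "hap_seq"))
  f <- hap$features
  df <- data.frame(chrom = hap$name, start = f$start, end = f$end,
                   name = f$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
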