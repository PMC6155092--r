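#' Count canonical k-mers from reads
#'
#' Every window of `k` consecutive A/C/G/T bases (windows containing any
#' other character are skipped entirely) contributes one count to its
#' canonical form — the lexicographic minimum of the window and its reverse
#' complement — so both strands count as one entity. The result is the
#' occurrence-depth histogram: for each depth, the number of distinct
#' canonical k-mers seen that many times.
#'
#' @param reads character vector of read sequences, FASTQ path(s), a
#'   `read_pairs` object, or a list of any of these.
#' @param k k-mer size, 1-32 (default 32).
#' @return a `kmer_hist`: tibble with columns `depth`, `count` and
#'   attributes `k`, `total_kmers` (sum of depth x count) and
#'   `distinct_kmers`.
#' @export
count_kmers <- function(reads, k = 32) {
  if (inherits(reads, "read_pairs"))
    reads <- c(unname(reads$read1), unname(reads$read2))
  reads <- as_reads(reads)
  res <- cpp_kmer_hist(reads, as.integer(k))
  h <- tibble::tibble(depth = res$depth, count = res$count)
  structure(h, class = c("kmer_hist", class(h)), k = as.integer(k),
            total_kmers = res$total_kmers,
            distinct_kmers = res$distinct_kmers)
}

#' Write / read a k-mer histogram as two-column TSV
#'
#' @param hist a `kmer_hist` (or any tibble with `depth`, `count`).
#' @param path file path.
#' @return `path` invisibly; `read_kmer_hist()` returns a `kmer_hist`.
#' @export
write_kmer_hist <- function(hist, path) {
  write.table(as.data.frame(hist[, c("depth", "count")]), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_kmer_hist
#' @param k k-mer size to record on the restored object.
#' @export
read_kmer_hist <- function(path, k = 32) {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t"))
  structure(df, class = c("kmer_hist", class(df)), k = as.integer(k),
            total_kmers = sum(df$depth * df$count),
            distinct_kmers = sum(df$count))
}

# dense counts over 1..max depth, smoothed by a centered moving average of
# window 3 (counts outside the depth range are zero)
smoothed_counts <- function(hist) {
  d_max <- max(hist$depth)
  dense <- numeric(d_max)
  dense[hist$depth] <- hist$count
  padded <- c(0, dense, 0)
  (padded[1:d_max] + padded[2:(d_max + 1)] + padded[3:(d_max + 2)]) / 3
}

#' Locate the error trough and heterozygous/homozygous peaks
#'
#' Scans the (moving-average smoothed, window 3) histogram upward from
#' depth 1. The error trough is the first local minimum — the bottom
#' between the sequencing-error mass near depth 1 and the genomic peaks.
#' Candidate peaks are local maxima above the trough; if the two largest
#' have a depth ratio in `[1.7, 2.3]` the smaller-depth one is called the
#' heterozygous peak and the larger the homozygous peak; with a single
#' peak, it is homozygous and the heterozygous peak is absent (`NA`).
#' Count ties are broken toward the higher-depth peak as homozygous.
#'
#' @param hist a `kmer_hist`.
#' @param ratio_window acceptable hom/het depth ratio range.
#' @return list of class `kmer_peaks`: `error_trough_depth`,
#'   `het_peak_depth` (`NA` if absent), `hom_peak_depth`.
#' @export
find_peaks <- function(hist, ratio_window = c(1.7, 2.3)) {
  stopifnot(nrow(hist) > 0)
  sm <- smoothed_counts(hist)
  D <- length(sm)
  if (D < 2) stop("histogram too degenerate for peak detection")
  # first local minimum scanning up from depth 1 (depth 1 itself if the
  # histogram rises immediately, i.e. there is no error mass)
  dense <- numeric(D)
  dense[hist$depth] <- hist$count
  trough <- NA_integer_
  if (dense[2] > dense[1]) trough <- 1L else {
    for (d in 2:(D - 1)) {
      if (sm[d] <= sm[d - 1] && sm[d] < sm[d + 1]) { trough <- d; break }
    }
  }
  if (is.na(trough))
    stop("no error trough / genomic peak structure found in histogram")
  # local maxima above the trough
  peaks <- integer(0)
  for (d in (trough + 1):D) {
    lo <- if (d > 1) sm[d - 1] else -Inf
    hi <- if (d < D) sm[d + 1] else -Inf
    if (sm[d] >= lo && sm[d] >= hi && sm[d] > 0 &&
        (sm[d] > lo || sm[d] > hi)) peaks <- c(peaks, d)
  }
  if (length(peaks) == 0)
    stop("no local maximum above the error trough; cannot locate ",
         "homozygous peak")
  het <- NA_integer_
  if (length(peaks) >= 2) {
    ord <- order(sm[peaks], peaks, decreasing = TRUE) # count, then depth
    top2 <- sort(peaks[ord[1:2]])
    ratio <- top2[2] / top2[1]
    if (ratio >= ratio_window[1] && ratio <= ratio_window[2]) {
      het <- top2[1]; hom <- top2[2]
    } else {
      hom <- peaks[ord[1]]
    }
  } else {
    hom <- peaks[[1]]
  }
  structure(list(error_trough_depth = as.integer(trough),
                 het_peak_depth = as.integer(het),
                 hom_peak_depth = as.integer(hom)),
            class = "kmer_peaks")
}

#' @export
print.kmer_peaks <- function(x, ...) {
  cat(sprintf("<kmer_peaks> trough %d, het %s, hom %d\n",
              x$error_trough_depth,
              ifelse(is.na(x$het_peak_depth), "absent",
                     as.character(x$het_peak_depth)),
              x$hom_peak_depth))
  invisible(x)
}

#' Estimate the haploid genome size from a k-mer histogram
#'
#' Total retained k-mer mass (sum of depth x count over depths at or above
#' the error trough — k-mers rarer than the bottom between zero and the
#' heterozygous peak are excluded as sequencing errors) divided by the
#' homozygous peak depth, floored to an integer.
#'
#' @param hist a `kmer_hist`.
#' @param peaks optional precomputed [find_peaks()] result.
#' @return list of class `genome_size_estimate`: `hom_peak_depth`,
#'   `het_peak_depth`, `error_trough_depth`, `retained_kmer_total`,
#'   `haploid_size`.
#' @export
estimate_genome_size <- function(hist, peaks = NULL) {
  if (is.null(peaks)) peaks <- find_peaks(hist)
  keep <- hist$depth >= peaks$error_trough_depth
  retained <- sum(hist$depth[keep] * hist$count[keep])
  structure(list(hom_peak_depth = peaks$hom_peak_depth,
                 het_peak_depth = peaks$het_peak_depth,
                 error_trough_depth = peaks$error_trough_depth,
                 retained_kmer_total = retained,
                 haploid_size = floor(retained / peaks$hom_peak_depth)),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "<genome_size_estimate> haploid %s bp (hom peak %d, trough %d%s)\n",
    format(x$haploid_size, big.mark = ","), x$hom_peak_depth,
    x$error_trough_depth,
    ifelse(is.na(x$het_peak_depth), "",
           sprintf(", het peak %d", x$het_peak_depth))))
  invisible(x)
}

#' Read budget for a target assembly coverage
#'
#' `floor(haploid_size / mean_read_len * target_coverage)`: the number of
#' reads needed so that the assembler sees the optimum coverage depth
#' (default 56-fold) of the estimated haploid genome.
#'
#' @param haploid_size estimated haploid genome size in bp.
#' @param mean_read_len mean read length in bp (> 0).
#' @param target_coverage target fold coverage (default 56).
#' @return integer-valued double (counts can exceed 2^31).
#' @export
compute_maxreads <- function(haploid_size, mean_read_len,
                             target_coverage = 56) {
  stopifnot(haploid_size > 0)
  if (mean_read_len <= 0) stop("mean_read_len must be positive")
  if (target_coverage < 0) stop("target_coverage must be non-negative")
  floor(haploid_size / mean_read_len * target_coverage)
}

#' Fold coverage implied by a sequencing yield
#'
#' @param total_bases total sequenced bases.
#' @param genome_size assumed genome size in bp (> 0).
#' @return fold coverage as a real number.
#' @export
sequence_coverage <- function(total_bases, genome_size) {
  stopifnot(genome_size > 0)
  total_bases / genome_size
}
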