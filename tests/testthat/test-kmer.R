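# a clean synthetic histogram with an error shoulder, a heterozygous peak
# at depth 15 and a homozygous peak at depth 30
synthetic_hist <- function() {
  depth <- 1:38
  count <- c(1e6, 2e5, 4e4, 8e3, 1600, 320, 30, 200, 1000, 5000,
             15000, 30000, 42000, 48000, 50000, 48000, 42000, 30000,
             15000, 5000, 1000, 500, 700, 2000, 10000, 30000, 60000,
             85000, 95000, 100000, 95000, 85000, 60000, 30000, 10000,
             2000, 500, 100)
  h <- tibble::tibble(depth = depth, count = count)
  structure(h, class = c("kmer_hist", class(h)), k = 32L,
            total_kmers = sum(depth * count),
            distinct_kmers = sum(count))
}

test_that("single-read and reverse-complement counting behave canonically", {
  h <- count_kmers("ACGTACGT", k = 8)
  expect_equal(nrow(h), 1)
  expect_equal(h$depth, 1)
  expect_equal(h$count, 1)
  expect_equal(attr(h, "total_kmers"), 1)

  r <- "ACGGTTCAGGTAC"
  h1 <- count_kmers(r, k = 5)
  h2 <- count_kmers(c(r, revcomp(r)), k = 5)
  expect_equal(h2$depth, 2 * h1$depth)
  expect_equal(h2$count, h1$count)
  # full reverse-complement invariance of a read set
  g <- rand_dna(3000, seed = 41)
  reads <- tile_reads(g, 100, step = 13)
  expect_equal(as.data.frame(count_kmers(reads, 21)),
               as.data.frame(count_kmers(revcomp(reads), 21)))
})

test_that("histogram conservation matches a brute-force window enumerator", {
  g <- rand_dna(8000, seed = 42)
  reads <- tile_reads(g, 100, step = 3)
  # sprinkle N to exercise window skipping
  reads[5] <- paste0(substr(reads[5], 1, 40), "N",
                     substr(reads[5], 42, 100))
  for (k in c(7, 16)) {
    h <- count_kmers(reads, k)
    o <- oracle_kmer_hist(reads, k)
    expect_equal(tibble::tibble(depth = h$depth, count = h$count),
                 o, ignore_attr = TRUE)
    expect_equal(attr(h, "total_kmers"), sum(o$depth * o$count))
  }
})

test_that("error-free homozygous coverage peaks at c(L-k+1)/L and has no het peak", {
  g <- generate_genome(20000, seed = 43)
  rp <- simulate_reads(g, g, lib_spec("paired-end", read_len = 100,
                                      insert_mean = 300, coverage = 30),
                       seed = 6)
  h <- count_kmers(rp, k = 32)
  pk <- find_peaks(h)
  expected <- 30 * (100 - 32 + 1) / 100
  expect_lt(abs(pk$hom_peak_depth - expected) / expected, 0.10)
  expect_true(is.na(pk$het_peak_depth))
})

test_that("trough/het/hom detection matches the constructed histogram", {
  pk <- find_peaks(synthetic_hist())
  expect_lte(pk$error_trough_depth, 7)
  expect_equal(pk$het_peak_depth, 15)
  expect_equal(pk$hom_peak_depth, 30)
})

test_that("degenerate histograms signal estimation errors", {
  h1 <- structure(tibble::tibble(depth = 1L, count = 1e6),
                  class = c("kmer_hist", "tbl_df", "tbl", "data.frame"))
  expect_error(find_peaks(h1), "degenerate|trough")
  h2 <- structure(tibble::tibble(depth = 1:6,
                                 count = c(1e6, 1e5, 1e4, 1e3, 100, 10)),
                  class = c("kmer_hist", "tbl_df", "tbl", "data.frame"))
  expect_error(find_peaks(h2), "trough|peak")
})

test_that("genome size is total retained k-mers over the homozygous depth", {
  # ideal histogram: all mass at depth d
  h <- structure(tibble::tibble(depth = c(19L, 20L, 21L),
                                count = c(1000, 50000, 1000)),
                 class = c("kmer_hist", "tbl_df", "tbl", "data.frame"))
  est <- estimate_genome_size(h)
  expect_equal(est$haploid_size,
               floor((19 * 1000 + 20 * 50000 + 21 * 1000) / 20))

  # adding pure depth-1 error mass below the trough leaves it unchanged
  base <- synthetic_hist()
  est1 <- estimate_genome_size(base)
  noisy <- base
  noisy$count[noisy$depth == 1] <- noisy$count[noisy$depth == 1] + 1e7
  attr(noisy, "total_kmers") <- sum(noisy$depth * noisy$count)
  est2 <- estimate_genome_size(noisy)
  expect_gt(est1$error_trough_depth, 1)
  expect_equal(est2$haploid_size, est1$haploid_size)
})

test_that("size estimate is invariant to duplicating the read set", {
  g <- generate_genome(20000, seed = 44)
  rp <- simulate_reads(g, g, lib_spec("paired-end", insert_mean = 300,
                                      coverage = 30), seed = 7)
  reads <- c(unname(rp$read1), unname(rp$read2))
  h1 <- count_kmers(reads, 25)
  h2 <- count_kmers(c(reads, reads), 25)
  expect_equal(attr(h2, "total_kmers"), 2 * attr(h1, "total_kmers"))
  e1 <- estimate_genome_size(h1)
  e2 <- estimate_genome_size(h2)
  # peak depth doubles (up to one smoothing bin)
  expect_lte(abs(e2$hom_peak_depth - 2 * e1$hom_peak_depth), 1)
  expect_lt(abs(e2$haploid_size - e1$haploid_size) / e1$haploid_size,
            0.03)
})

test_that("read-budget and coverage arithmetic reproduce the worked examples", {
  expect_equal(compute_maxreads(423e6, 150, 56), 157920000)
  expect_equal(compute_maxreads(1000, 100, 1), 10)
  expect_equal(compute_maxreads(1000, 100, 0), 0)
  expect_error(compute_maxreads(1000, 0, 56), "read_len")
  expect_equal(round(sequence_coverage(4.31e9, 423e6), 2), 10.19)
  expect_equal(sequence_coverage(423e6, 423e6), 1.0)
  expect_equal(round(sequence_coverage(4.44e9, 423e6), 2), 10.5)
})

test_that("histogram TSV round-trips", {
  h <- synthetic_hist()
  f <- tempfile(fileext = ".tsv")
  write_kmer_hist(h, f)
  h2 <- read_kmer_hist(f, k = 32)
  expect_equal(as.data.frame(h2), as.data.frame(h[, c("depth", "count")]))
  expect_equal(attr(h2, "total_kmers"), attr(h, "total_kmers"))
})
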