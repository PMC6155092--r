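test_that("generated genomes have forced length, no N, and are seed-deterministic", {
  g <- generate_genome(50000, gc = 0.5, repeat_fraction = 0, seed = 1)
  expect_s3_class(g, "hap_seq")
  expect_equal(nchar(g$seq), 50000)
  expect_false(grepl("N", g$seq, fixed = TRUE))
  g2 <- generate_genome(50000, gc = 0.5, repeat_fraction = 0, seed = 1)
  expect_identical(g$seq, g2$seq)
  g3 <- generate_genome(50000, gc = 0.5, repeat_fraction = 0, seed = 2)
  expect_false(identical(g$seq, g3$seq))
  expect_error(generate_genome(500), "at least 1000")
})

test_that("observed GC tracks the requested fraction (binomial bound)", {
  g <- generate_genome(100000, gc = 0.35, seed = 7)
  gc_obs <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.35), 0.02)
})

test_that("repeat_fraction introduces duplicated long segments", {
  g <- generate_genome(20000, gc = 0.5, repeat_fraction = 0.2, seed = 3)
  starts <- seq(1, 20000 - 99)
  wins <- substring(g$seq, starts, starts + 99)
  expect_gt(sum(duplicated(wins)), 0)
  g0 <- generate_genome(20000, gc = 0.5, repeat_fraction = 0, seed = 3)
  wins0 <- substring(g0$seq, starts, starts + 99)
  expect_equal(sum(duplicated(wins0)), 0)
})

test_that("derive_allele with zero rates returns the parent verbatim", {
  g <- generate_genome(5000, seed = 4)
  da <- derive_allele(g, snp_rate = 0, indel_rate = 0, seed = 1)
  expect_identical(da$hap$seq, g$seq)
  expect_equal(nrow(da$ledger$snps), 0)
  expect_equal(nrow(da$ledger$indels), 0)
  expect_equal(nrow(da$ledger$inversions), 0)
})

test_that("an inversion reverse-complements the segment in place", {
  g <- generate_genome(100000, seed = 5)
  da <- derive_allele(g, snp_rate = 0, indel_rate = 0,
                      inversions = data.frame(start = 10000, end = 76000),
                      seed = 1)
  expect_equal(nchar(da$hap$seq), nchar(g$seq))
  expect_identical(substr(da$hap$seq, 10001, 76000),
                   revcomp(substr(g$seq, 10001, 76000)))
  expect_identical(substr(da$hap$seq, 1, 10000), substr(g$seq, 1, 10000))
  expect_error(
    derive_allele(g, inversions = data.frame(start = c(100, 5000),
                                             end = c(6000, 9000))),
    "overlap")
})

test_that("sampled SNP counts follow the binomial oracle", {
  g <- generate_genome(100000, seed = 6)
  da <- derive_allele(g, snp_rate = 0.005, indel_rate = 0, seed = 3)
  n <- nrow(da$ledger$snps)
  expect_lt(abs(n - 500), 3 * sqrt(500 * 0.995))
})

test_that("applying the ledger to the parent reproduces the child byte-for-byte", {
  g <- generate_genome(30000, seed = 8)
  for (s in 1:3) {
    da <- derive_allele(g, snp_rate = 0.004, indel_rate = 5e-4,
                        inversions = data.frame(start = 8000, end = 20000),
                        insertions = data.frame(pos = 25000, len = 500),
                        seed = s)
    expect_identical(apply_ledger(g, da$ledger)$seq, da$hap$seq)
  }
})

test_that("error-free reads are exact substrings and truth tags decode them", {
  g <- generate_genome(50000, seed = 9)
  lib <- lib_spec("paired-end", read_len = 100, insert_mean = 300,
                  error_rate = 0, coverage = 30)
  rp <- simulate_reads(g, g, lib, seed = 2)
  expect_equal(length(rp$read1), ceiling(30 * 50000 / 200))
  tr <- read_truth(names(rp$read1))
  idx <- seq(1, length(rp$read1), length.out = 200)
  for (i in round(idx)) {
    frag <- substr(g$seq, tr$start[i] + 1, tr$start[i] + tr$insert[i])
    expect_identical(rp$read1[[i]], substr(frag, 1, 100))
    expect_identical(rp$read2[[i]],
                     revcomp(substr(frag, tr$insert[i] - 99,
                                    tr$insert[i])))
  }
  expect_error(simulate_reads(g, g, lib_spec(insert_mean = 60000),
                              seed = 1), "insert_mean")
})

test_that("insert sizes and haplotype origin match their sampling models", {
  g <- generate_genome(50000, seed = 10)
  h <- derive_allele(g, snp_rate = 0.002, seed = 2)$hap
  lib <- lib_spec("paired-end", read_len = 100, insert_mean = 400,
                  insert_sd = 40, coverage = 30)
  rp <- simulate_reads(g, h, lib, seed = 3)
  tr <- read_truth(names(rp$read1))
  n <- nrow(tr)
  expect_lt(abs(mean(tr$insert) - 400), 3 * 40 / sqrt(n))
  frac_a <- mean(tr$hap == "A")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / n))
})

test_that("outie mate-pairs point outward from the fragment", {
  g <- generate_genome(20000, seed = 11)
  lib <- lib_spec("mate-pair", read_len = 100, insert_mean = 3000,
                  coverage = 5)
  rp <- simulate_reads(g, g, lib, seed = 4)
  tr <- read_truth(names(rp$read1))
  i <- 5
  frag <- substr(g$seq, tr$start[i] + 1, tr$start[i] + tr$insert[i])
  expect_identical(rp$read1[[i]], revcomp(substr(frag, 1, 100)))
  expect_identical(rp$read2[[i]],
                   substr(frag, tr$insert[i] - 99, tr$insert[i]))
})

test_that("substitution errors hit roughly error_rate of the bases", {
  g <- generate_genome(50000, seed = 12)
  lib <- lib_spec("paired-end", insert_mean = 300, error_rate = 0.01,
                  coverage = 10)
  rp <- simulate_reads(g, g, lib, seed = 5)
  tr <- read_truth(names(rp$read1))
  mism <- vapply(seq_len(200), function(i) {
    truth <- substr(g$seq, tr$start[i] + 1, tr$start[i] + 100)
    sum(utf8ToInt(truth) != utf8ToInt(rp$read1[[i]]))
  }, numeric(1))
  rate <- sum(mism) / (200 * 100)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 20000))
})

test_that("FASTA/FASTQ round-trips preserve sequences and names", {
  g <- generate_genome(2000, seed = 13)
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(chr1 = g$seq), fa)
  expect_identical(unname(read_fasta(fa)["chr1"]), g$seq)
  fq <- tempfile(fileext = ".fq")
  reads <- c(`r1/1` = substr(g$seq, 1, 100), `r2/1` = substr(g$seq, 101, 200))
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(unname(back), unname(reads))
})
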