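test_that("self-comparison yields the full-length forward identity block first", {
  s <- rand_dna(5000, seed = 71)
  b <- anchor_align(s, s)
  expect_gte(nrow(b), 1)
  expect_equal(b$orientation[1], "forward")
  expect_lte(b$q_start[1], 12)
  expect_gte(b$q_end[1], 5000 - 12)
  expect_gte(b$matched_bases[1], 0.99 * 5000)
  expect_equal(b$q_start[1], b$s_start[1])
})

test_that("comparison against the reverse complement yields one reverse block", {
  s <- rand_dna(5000, seed = 72)
  b <- anchor_align(s, revcomp(s))
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "reverse")
  expect_gte(b$matched_bases, 0.99 * 5000)
})

test_that("a constructed 10 kb inversion produces forward-reverse-forward blocks", {
  a <- rand_dna(30000, seed = 73)
  b <- paste0(substr(a, 1, 10000),
              revcomp(substr(a, 10001, 20000)),
              substr(a, 20001, 30000))
  blocks <- anchor_align(a, b)
  expect_equal(nrow(blocks), 3)
  expect_equal(sort(table(blocks$orientation), decreasing = TRUE),
               sort(table(c("forward", "forward", "reverse")),
                    decreasing = TRUE))
  rb <- blocks[blocks$orientation == "reverse", ]
  expect_lt(abs((rb$s_end - rb$s_start) - 10000), 2 * 12)
  inv <- call_inversions(blocks)
  expect_equal(nrow(inv), 1)
  expect_lt(abs(inv$size - 10000), 2 * 12)
  expect_equal(inv$support, 1)
})

test_that("inversion calls are symmetric between the two comparison directions", {
  a <- rand_dna(30000, seed = 74)
  b <- paste0(substr(a, 1, 8000),
              revcomp(substr(a, 8001, 18000)),
              substr(a, 18001, 30000))
  iab <- call_inversions(anchor_align(a, b))
  iba <- call_inversions(anchor_align(b, a))
  expect_equal(nrow(iab), 1)
  expect_equal(nrow(iba), 1)
  expect_equal(iab$size, iba$size)
  expect_equal(iab$q_start, iba$s_start)
  expect_equal(iab$s_start, iba$q_start)
})

test_that("surviving blocks really match at their reported spans", {
  a <- rand_dna(20000, seed = 75)
  da <- derive_allele(hap_seq(a), snp_rate = 0.005, seed = 17)
  blocks <- anchor_align(a, da$hap$seq)
  fb <- filter_blocks(blocks)
  for (r in seq_len(min(nrow(fb), 5))) {
    qa <- substr(a, fb$q_start[r] + 1, fb$q_end[r])
    sb <- substr(da$hap$seq, fb$s_start[r] + 1, fb$s_end[r])
    if (fb$orientation[r] == "reverse") sb <- revcomp(sb)
    n <- min(nchar(qa), nchar(sb))
    id <- mean(utf8ToInt(substr(qa, 1, n)) == utf8ToInt(substr(sb, 1, n)))
    expect_gte(id, fb$matched_bases[r] / (fb$q_end[r] - fb$q_start[r]))
  }
})

test_that("block filtering applies the length rule then the repeat rule", {
  mk <- function(qs, len) tibble::tibble(
    q_start = qs, q_end = qs + len, s_start = qs, s_end = qs + len,
    orientation = "forward", matched_bases = len)
  toy <- dplyr::bind_rows(
    mk(0, 400), mk(1000, 600),
    mk(5000, 1200), mk(5100, 1200), mk(5050, 1200),
    mk(10000, 2000))
  out <- filter_blocks(toy, min_len = 500, repeat_max_len = 1250,
                       repeat_min_hits = 2)
  expect_equal(sort(out$q_end - out$q_start), c(600, 2000))
  # idempotence
  expect_equal(as.data.frame(filter_blocks(out)), as.data.frame(out))
  # blocks at or above repeat_max_len are exempt from the repeat rule
  big <- dplyr::bind_rows(mk(0, 1300), mk(50, 1300), mk(100, 1300))
  expect_equal(nrow(filter_blocks(big)), 3)
  # no reverse blocks -> no inversion calls
  expect_equal(nrow(call_inversions(out)), 0)
})

test_that("locus size arithmetic matches the worked toys", {
  ann <- locus_annotation(data.frame(start = c(0, 1100),
                                     end = c(100, 1200)))
  sz <- locus_sizes(ann, upstream_gene_3prime = -500)
  expect_equal(sz$first_intron, 1000)
  expect_equal(sz$upstream_intergenic, 500)
  expect_equal(sz$upper_noncoding, 1500)
  # inserting 50 kb into the intron raises first_intron by exactly 50 kb
  ann2 <- locus_annotation(data.frame(start = c(0, 51100),
                                      end = c(100, 51200)))
  expect_equal(locus_sizes(ann2, -500)$first_intron, 51000)
  expect_error(locus_sizes(ann, upstream_gene_3prime = 50), "negative")
  expect_error(locus_sizes(locus_annotation(data.frame(start = 0,
                                                       end = 100)), -10),
               "two exons")
})

test_that("dot-plot tables round-trip losslessly", {
  a <- rand_dna(6000, seed = 76)
  b <- paste0(substr(a, 1, 2000), revcomp(substr(a, 2001, 4000)),
              substr(a, 4001, 6000))
  blocks <- anchor_align(a, b)
  f <- tempfile(fileext = ".tsv")
  export_dotplot(blocks, f)
  back <- read_dotplot(f)
  expect_equal(as.data.frame(back), as.data.frame(blocks),
               ignore_attr = TRUE)
  # identity comparison gives a single rising diagonal
  self <- anchor_align(a, a)
  expect_equal(self$orientation[1], "forward")
  # empty block list -> header-only file
  export_dotplot(blocks[0, ], f)
  expect_equal(nrow(read_dotplot(f)), 0)
})

test_that("ledger-sized intron inversions are recovered within 5%", {
  g <- generate_genome(100000, seed = 77)
  da <- derive_allele(g, snp_rate = 0.005,
                      inversions = data.frame(start = 20000, end = 86000),
                      seed = 18)
  fb <- filter_blocks(anchor_align(g, da$hap$seq))
  inv <- call_inversions(fb)
  expect_equal(nrow(inv), 1)
  expect_lt(abs(inv$size - 66000) / 66000, 0.05)
})
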