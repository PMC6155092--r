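canon_seq <- function(x) pmin(x, revcomp(x))

test_that("a nonrepetitive genome assembles into a single unitig equal to itself", {
  g <- rand_dna(20000, seed = 51)
  gr <- build_graph(tile_reads(g, 100, step = 1), k = 31, min_count = 1)
  un <- extract_unitigs(gr)
  expect_equal(nrow(un), 1)
  expect_identical(canon_seq(un$seq), canon_seq(g))
  expect_equal(un$length, un$n_kmers + 31 - 1)
  expect_equal(nrow(detect_bubbles(gr)), 0)
  expect_error(build_graph("ACGT", k = 31), "read length")
})

test_that("graph k-mers and unitig k-mers are the same multiset", {
  g <- rand_dna(9000, seed = 52)
  reads <- tile_reads(g, 100, step = 2)
  gr <- build_graph(reads, k = 21, min_count = 1)
  expect_equal(sum(gr$unitigs$n_kmers), gr$distinct_kmers)
  # each retained k-mer occurs in exactly one unitig
  h <- count_kmers(gr$unitigs$seq, 21)
  expect_equal(h$depth, 1)
  expect_equal(h$count, gr$distinct_kmers)
  # and the unitig k-mer set equals the brute-force read k-mer set
  o <- oracle_kmer_hist(reads, 21)
  expect_equal(gr$distinct_kmers, sum(o$count))
})

test_that("one isolated SNP produces exactly one bubble with k-node arms", {
  k <- 31
  g <- rand_dna(4000, seed = 53)
  g2 <- g
  mid <- substr(g, 2000, 2000)
  substr(g2, 2000, 2000) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  gr <- build_graph(c(tile_reads(g, 100), tile_reads(g2, 100)),
                    k = k, min_count = 1)
  bb <- detect_bubbles(gr)
  expect_equal(nrow(bb), 1)
  expect_gte(nrow(extract_unitigs(gr)), 4)
  expect_equal(nchar(bb$arm_a_seq), 2 * k - 1)
  expect_equal(nchar(bb$arm_b_seq), 2 * k - 1)
  # arms differ at exactly one base
  expect_equal(sum(utf8ToInt(bb$arm_a_seq) != utf8ToInt(bb$arm_b_seq)), 1)
})

test_that("m well-separated SNPs produce m bubbles", {
  g <- rand_dna(6000, seed = 54)
  g2 <- g
  pos <- c(1000, 2500, 4000)
  for (p in pos) {
    b <- substr(g2, p, p)
    substr(g2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  gr <- build_graph(c(tile_reads(g, 100), tile_reads(g2, 100)),
                    k = 31, min_count = 1)
  expect_equal(nrow(detect_bubbles(gr)), 3)
})

test_that("assembly is strand-symmetric", {
  g <- rand_dna(8000, seed = 55)
  g2 <- g
  substr(g2, 4000, 4000) <- if (substr(g, 4000, 4000) == "A") "C" else "A"
  reads <- c(tile_reads(g, 100, 3), tile_reads(g2, 100, 3))
  u1 <- build_graph(reads, 31, 1)$unitigs$seq
  u2 <- build_graph(revcomp(reads), 31, 1)$unitigs$seq
  expect_setequal(canon_seq(u1), canon_seq(u2))
})

test_that("read mapping links same-haplotype arms and never cross-arm at zero error", {
  g <- rand_dna(3000, seed = 56)
  g2 <- g
  for (p in c(1000, 1400)) {
    b <- substr(g2, p, p)
    substr(g2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  gr <- build_graph(c(tile_reads(g, 100), tile_reads(g2, 100)), 31, 1)
  bb <- detect_bubbles(gr)
  expect_equal(nrow(bb), 2)
  hA <- hap_seq(g); hB <- hap_seq(g2)
  rp <- simulate_reads(hA, hB, lib_spec("paired-end", insert_mean = 500,
                                        coverage = 40), seed = 8)
  pl <- map_pairs(rp, gr$unitigs$seq)
  tr <- read_truth(names(rp$read1))
  arm_hap <- function(arm_seq) {
    if (grepl(arm_seq, g, fixed = TRUE) ||
        grepl(revcomp(arm_seq), g, fixed = TRUE)) "A" else "B"
  }
  arm_tbl <- tibble::tibble(
    elem = c(bb$arm_a, bb$arm_b),
    hap = c(vapply(bb$arm_a_seq, arm_hap, character(1)),
            vapply(bb$arm_b_seq, arm_hap, character(1))))
  tt <- dplyr::inner_join(pl$touches, arm_tbl, by = "elem")
  tt$true_hap <- tr$hap[tt$pair]
  # every arm touch comes from a read of that arm's haplotype
  expect_true(all(tt$hap == tt$true_hap))
})

test_that("short reads yield no seed touches", {
  g <- rand_dna(2000, seed = 57)
  rp <- list(read1 = c(x = substr(g, 1, 10)), read2 = c(x = substr(g, 50, 59)),
             lib = lib_spec("paired-end", read_len = 10, insert_mean = 100))
  pl <- map_pairs(rp, g)
  expect_equal(nrow(pl$touches), 0)
  expect_equal(nrow(pl$links), 0)
})

test_that("link tables are symmetric under mate swap", {
  g <- rand_dna(4000, seed = 58)
  a <- substr(g, 1, 1900); b <- substr(g, 2101, 4000)
  rp <- simulate_reads(hap_seq(g), hap_seq(g),
                       lib_spec("paired-end", insert_mean = 500,
                                coverage = 30), seed = 9)
  pl1 <- map_pairs(rp, c(a, b))
  rp2 <- rp
  rp2$read1 <- rp$read2; rp2$read2 <- rp$read1
  pl2 <- map_pairs(rp2, c(a, b))
  expect_equal(as.data.frame(pl1$links[, c("elem_i", "elem_j", "count")]),
               as.data.frame(pl2$links[, c("elem_i", "elem_j", "count")]))
})

test_that("a chain of bubbles phases perfectly from error-free links", {
  g <- rand_dna(3500, seed = 59)
  g2 <- g
  pos <- c(500, 1000, 1500, 2000, 2500)
  for (p in pos) {
    b <- substr(g2, p, p)
    substr(g2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  gr <- build_graph(c(tile_reads(g, 100), tile_reads(g2, 100)), 31, 1)
  bb <- detect_bubbles(gr)
  expect_equal(nrow(bb), 5)
  rp <- simulate_reads(hap_seq(g), hap_seq(g2),
                       lib_spec("paired-end", insert_mean = 550,
                                coverage = 60), seed = 10)
  ph <- phase_bubbles(bb, map_pairs(rp, gr$unitigs$seq))
  expect_equal(length(unique(ph$component)), 1)
  # truth: arm_a of each bubble belongs to a definite haplotype; phases
  # must agree with truth up to one global flip
  truth <- vapply(bb$arm_a_seq, function(s)
    as.integer(!(grepl(s, g, fixed = TRUE) ||
                   grepl(revcomp(s), g, fixed = TRUE))), integer(1))
  agree <- ph$phase == truth
  expect_true(all(agree) || all(!agree))
})

test_that("zero links leave every bubble its own deterministic component", {
  g <- rand_dna(3000, seed = 60)
  g2 <- g
  substr(g2, 1500, 1500) <- if (substr(g, 1500, 1500) == "A") "G" else "A"
  gr <- build_graph(c(tile_reads(g, 100), tile_reads(g2, 100)), 31, 1)
  bb <- detect_bubbles(gr)
  ph1 <- phase_bubbles(bb, list())
  ph2 <- phase_bubbles(bb, list())
  expect_identical(as.data.frame(ph1), as.data.frame(ph2))
  expect_equal(ph1$component, seq_len(nrow(bb)))
  expect_equal(ph1$phase, rep(0L, nrow(bb)))
})

test_that("a contradictory low-weight link is skipped without changing the phasing", {
  bb <- tibble::tibble(
    bubble = 1:2, source = c(1L, 4L), source_end = "R",
    sink = c(4L, 7L), sink_end = "L",
    arm_a = c(2L, 5L), arm_b = c(3L, 6L),
    arm_a_seq = c("AAA", "CCC"), arm_b_seq = c("GGG", "TTT"),
    arm_a_cov = 10, arm_b_cov = 10)
  consistent <- tibble::tibble(
    pair = rep(1:6, each = 2), mate = rep(1:2, 6),
    elem = rep(c(2L, 5L), 6), strand = 1L, pos = 0, nseeds = 5L)
  contradiction <- tibble::tibble(
    pair = 7:8, mate = 1L, elem = c(2L, 6L), strand = 1L, pos = 0,
    nseeds = 5L)
  contradiction$pair <- c(7L, 7L)
  ph <- phase_bubbles(bb, fake_links(rbind(consistent, contradiction)))
  expect_equal(length(unique(ph$component)), 1)
  expect_equal(ph$phase, c(0L, 0L)) # arm 2 with arm 5: same haplotype
  expect_equal(attr(ph, "n_contradicted"), 1L)
})

test_that("mate-pairs join two contigs across a gap with a calibrated N run", {
  a <- rand_dna(5000, seed = 61)
  gap <- rand_dna(500, seed = 62)
  b <- rand_dna(5000, seed = 63)
  genome <- paste0(a, gap, b)
  contig_reads <- c(tile_reads(a, 100), tile_reads(b, 100))
  gr <- build_graph(contig_reads, 31, 1)
  expect_equal(nrow(gr$unitigs), 2)
  bb <- detect_bubbles(gr)
  ph <- phase_bubbles(bb, list())
  mp <- simulate_reads(hap_seq(genome), hap_seq(genome),
                       lib_spec("mate-pair", insert_mean = 3000,
                                insert_sd = 300, coverage = 20), seed = 11)
  asm <- scaffold_and_iterate(gr, bb, ph, list(mp))
  expect_equal(nrow(asm$scaffolds), 1)
  expect_equal(asm$scaffolds$role, "nonbubble")
  n_run <- nchar(gsub("[^N]", "", asm$scaffolds$seq))
  expect_gt(n_run, 0)
  expect_lt(abs(n_run - 500), 2 * 300)
  # with an unreachable link threshold the input elements come back
  asm2 <- scaffold_and_iterate(gr, bb, ph, list(mp), min_links = 1e6)
  expect_equal(nrow(asm2$scaffolds), 2)
  expect_setequal(canon_seq(asm2$scaffolds$seq), canon_seq(c(a, b)))
})

test_that("a fully homozygous assembly passes through consensus unchanged", {
  g <- rand_dna(6000, seed = 64)
  gr <- build_graph(tile_reads(g, 100), 31, 1)
  bb <- detect_bubbles(gr)
  ph <- phase_bubbles(bb, list())
  rp <- simulate_reads(hap_seq(g), hap_seq(g),
                       lib_spec("paired-end", insert_mean = 300,
                                coverage = 20), seed = 12)
  asm <- scaffold_and_iterate(gr, bb, ph, list(rp))
  cons <- build_consensus(asm)
  expect_equal(nrow(cons), sum(asm$scaffolds$role == "nonbubble"))
  expect_setequal(canon_seq(cons$seq),
                  canon_seq(asm$scaffolds$seq[
                    asm$scaffolds$role == "nonbubble"]))
  # provenance never contains a secondary scaffold
  roles <- unlist(lapply(cons$sources, function(s) s$role))
  expect_false(any(roles == "secondary"))
})

test_that("diploid locus assembles into near-perfect opposite haplotypes", {
  g <- generate_genome(40000, seed = 65)
  da <- derive_allele(g, snp_rate = 0.005, seed = 13)
  libs <- diploid_reads(g, da$hap, seed = 100)
  pe <- c(unname(libs[[1]]$read1), unname(libs[[1]]$read2),
          unname(libs[[2]]$read1), unname(libs[[2]]$read2))
  gr <- build_graph(pe, 31, 2)
  bb <- detect_bubbles(gr)
  ph <- phase_bubbles(bb, lapply(libs, function(lp)
    map_pairs(lp, gr$unitigs$seq)))
  asm <- scaffold_and_iterate(gr, bb, ph, libs)
  s <- asm$scaffolds
  prim <- s[s$role == "primary", ]
  prim <- prim[which.max(prim$length), ]
  sec <- s[!is.na(s$partner) & s$id == prim$partner, ]
  expect_equal(nrow(sec), 1)
  expect_gte(prim$length, sec$length)
  idPA <- seq_identity(prim$seq, g$seq)$identity
  idPB <- seq_identity(prim$seq, da$hap$seq)$identity
  idSA <- seq_identity(sec$seq, g$seq)$identity
  idSB <- seq_identity(sec$seq, da$hap$seq)$identity
  expect_gte(max(idPA, idPB), 0.999)
  expect_gte(max(idSA, idSB), 0.999)
  # primary and secondary align to opposite haplotypes
  expect_true((idPA > idPB) != (idSA > idSB))
  cons <- build_consensus(asm, libraries = libs[3])
  expect_gte(aligned_fraction(g, cons$seq), 0.95)
})

test_that("window links sit on the insert band and vanish across a mis-join", {
  g <- rand_dna(50000, seed = 66)
  mp <- simulate_reads(hap_seq(g), hap_seq(g),
                       lib_spec("mate-pair", insert_mean = 15000,
                                insert_sd = 1500, coverage = 40),
                       seed = 14)
  wl <- window_link_matrix(g, mp, window = 2000, min_links = 3)
  expect_gt(nrow(wl), 0)
  off <- wl$window_j - wl$window_i
  band_max <- ceiling((15000 + 4 * 1500) / 2000)
  expect_true(all(off <= band_max))
  expect_gt(max(off), 15000 / 2000 - 3)

  # deliberately mis-joined scaffold: two unrelated loci concatenated
  x <- rand_dna(30000, seed = 67)
  y <- rand_dna(30000, seed = 68)
  rx <- simulate_reads(hap_seq(x), hap_seq(x),
                       lib_spec("mate-pair", insert_mean = 15000,
                                insert_sd = 1500, coverage = 40),
                       seed = 15)
  ry <- simulate_reads(hap_seq(y), hap_seq(y),
                       lib_spec("mate-pair", insert_mean = 15000,
                                insert_sd = 1500, coverage = 40),
                       seed = 16)
  joined <- list(read1 = c(rx$read1, ry$read1),
                 read2 = c(rx$read2, ry$read2), lib = rx$lib)
  wl2 <- window_link_matrix(paste0(x, y), joined, window = 2000,
                            min_links = 3)
  junction <- 30000 / 2000
  crossing <- wl2$window_i < junction & wl2$window_j >= junction
  expect_equal(sum(crossing), 0)
  expect_gt(nrow(wl2), 0)

  # no input pairs -> empty link table
  empty <- list(read1 = character(0), read2 = character(0), lib = rx$lib)
  wl3 <- window_link_matrix(g, empty, window = 2000)
  expect_equal(nrow(wl3), 0)
  expect_error(window_link_matrix(substr(g, 1, 3000), mp, window = 2000),
               "two windows")
})
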