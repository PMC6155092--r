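# Independent oracles used across the suite. These deliberately avoid the
# package's own compiled kernels: brute-force string enumeration only.

# brute-force canonical k-mer histogram by direct window enumeration
oracle_kmer_hist <- function(reads, k) {
  wins <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  canon <- pmin(wins, revcomp(wins))
  depth_per_kmer <- table(canon)
  hist <- table(as.integer(depth_per_kmer))
  tibble::tibble(depth = as.integer(names(hist)),
                 count = as.numeric(hist))
}

# random DNA string
rand_dna <- function(n, seed = 1, gc = 0.5) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# reads tiling a sequence exactly (error-free, forward strand)
tile_reads <- function(seq, read_len = 100, step = 1) {
  n <- nchar(seq)
  starts <- seq(1, n - read_len + 1, by = step)
  substring(seq, starts, starts + read_len - 1)
}

# a sequence guaranteed to contain no EcoRI/HindIII site (AC repeats)
neutral_seq <- function(n) strrep("AC", ceiling(n / 2)) |> substr(1, n)

# synthetic diploid read set: one helper for the assembly tests
diploid_reads <- function(hapA, hapB, inserts = c(300, 500, 3000),
                          kinds = c("paired-end", "paired-end",
                                    "mate-pair"),
                          coverages = c(20, 20, 16), read_len = 100,
                          seed = 1) {
  hA <- if (inherits(hapA, "hap_seq")) hapA else hap_seq(hapA)
  hB <- if (inherits(hapB, "hap_seq")) hapB else hap_seq(hapB)
  lapply(seq_along(inserts), function(i)
    simulate_reads(hA, hB,
                   lib_spec(kinds[i], read_len = read_len,
                            insert_mean = inserts[i],
                            coverage = coverages[i]),
                   seed = seed + i))
}

# fake pair_links carrying hand-written fragment touches (for adversarial
# phasing tables)
fake_links <- function(touch_tbl) {
  structure(list(touches = touch_tbl,
                 links = tibble::tibble(),
                 lib = lib_spec("paired-end")),
            class = "pair_links")
}
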