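#' Sequencing library specifications
#'
#' Describes one simulated library. Defaults mirror a short-insert
#' paired-end library; mate-pair (jumping) libraries default to outward
#' ("outie") mate orientation, paired-end to inward ("innie").
#'
#' @param kind `"paired-end"` or `"mate-pair"`.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size mean and sd in bp.
#' @param orientation `"innie"` or `"outie"`; default depends on `kind`.
#' @param error_rate per-base substitution probability in `[0, 0.1]`.
#' @param coverage fold sequence coverage of the haploid genome contributed
#'   by this library (both haplotypes together).
#' @return an object of class `lib_spec`.
#' @export
lib_spec <- function(kind = c("paired-end", "mate-pair"), read_len = 100,
                     insert_mean = 300, insert_sd = insert_mean * 0.1,
                     orientation = NULL, error_rate = 0, coverage = 30) {
  kind <- match.arg(kind)
  if (is.null(orientation))
    orientation <- if (kind == "mate-pair") "outie" else "innie"
  orientation <- match.arg(orientation, c("innie", "outie"))
  if (read_len > insert_mean) stop("read_len must not exceed insert_mean")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must lie in [0, 0.1]")
  if (coverage <= 0) stop("coverage must be positive")
  structure(list(kind = kind, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 orientation = orientation, error_rate = error_rate,
                 coverage = coverage),
            class = "lib_spec")
}

#' @export
print.lib_spec <- function(x, ...) {
  cat(sprintf("<lib_spec> %s %dbp reads, insert %g +/- %g (%s), err %g, %gx\n",
              x$kind, x$read_len, x$insert_mean, x$insert_sd, x$orientation,
              x$error_rate, x$coverage))
  invisible(x)
}

#' Simulate paired reads from a diploid genome
#'
#' Fragments are drawn uniformly from the two haplotypes in equal expected
#' proportion; the number of pairs is `coverage * haploid_length /
#' (2 * read_len)` (so total sequenced bases equal `coverage *
#' haploid_length`). Mates are inward-facing for "innie" libraries and
#' outward-facing for "outie" (mate-pair) libraries; fragments are taken
#' from the genome forward strand and never wrap around the ends (linear
#' genome). Errors are substitutions only. Read names encode the true
#' haplotype, fragment start (0-based) and fragment length so every read
#' can be traced back to its origin:
#' `p<idx>:<A|B>:<start>:<insert>/<mate>`.
#'
#' @param hapA,hapB [hap_seq] objects (or character scalars): the two
#'   haplotypes. For a homozygous simulation pass the same sequence twice.
#' @param lib a [lib_spec].
#' @param seed integer seed.
#' @return object of class `read_pairs`: list with character vectors
#'   `read1`, `read2` (named with truth tags), the `lib`, and `haploid_len`.
#' @export
simulate_reads <- function(hapA, hapB, lib, seed = 1) {
  sA <- if (inherits(hapA, "hap_seq")) hapA$seq else hapA
  sB <- if (inherits(hapB, "hap_seq")) hapB$seq else hapB
  stopifnot(nchar(sA) > 0, nchar(sB) > 0, inherits(lib, "lib_spec"))
  if (lib$insert_mean > min(nchar(sA), nchar(sB)))
    stop("insert_mean exceeds haplotype length")
  hl <- nchar(sA)
  rl <- lib$read_len
  n <- ceiling(lib$coverage * hl / (2 * rl))
  with_op_seed(seed, paste0("simulate_reads_", lib$kind, lib$insert_mean), {
    hap <- sample(c("A", "B"), n, replace = TRUE)
    len_of <- c(A = nchar(sA), B = nchar(sB))
    hlen <- unname(len_of[hap])
    frag <- pmax(rl, pmin(round(rnorm(n, lib$insert_mean, lib$insert_sd)),
                          hlen))
    start <- floor(runif(n) * (hlen - frag + 1)) # 0-based
    seqs <- ifelse(hap == "A", sA, sB)
    left <- substring(seqs, start + 1, start + rl)
    right <- substring(seqs, start + frag - rl + 1, start + frag)
    if (lib$orientation == "innie") {
      r1 <- left; r2 <- revcomp(right)
    } else {
      r1 <- revcomp(left); r2 <- right
    }
    if (lib$error_rate > 0) {
      r1 <- add_substitutions(r1, lib$error_rate)
      r2 <- add_substitutions(r2, lib$error_rate)
    }
    base <- sprintf("p%d:%s:%d:%d", seq_len(n), hap, start, frag)
    names(r1) <- paste0(base, "/1")
    names(r2) <- paste0(base, "/2")
    structure(list(read1 = r1, read2 = r2, lib = lib, haploid_len = hl),
              class = "read_pairs")
  })
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs of %dbp %s reads (insert %g)\n",
              length(x$read1), x$lib$read_len, x$lib$kind, x$lib$insert_mean))
  invisible(x)
}

# random substitutions at a per-base rate; only reads drawn to carry at
# least one error are touched
add_substitutions <- function(reads, rate) {
  nb <- nchar(reads)
  nerr <- rbinom(length(reads), nb, rate)
  idx <- which(nerr > 0)
  if (length(idx) == 0) return(reads)
  fixed <- vapply(idx, function(i) {
    v <- strsplit(reads[[i]], "", fixed = TRUE)[[1]]
    at <- sample.int(length(v), nerr[[i]])
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }, character(1))
  reads[idx] <- fixed
  reads
}

#' Decode read-name truth tags
#'
#' @param names character vector of read names produced by
#'   [simulate_reads()].
#' @return tibble with columns `pair`, `hap`, `start`, `insert`, `mate`.
#' @export
read_truth <- function(names) {
  m <- stringi::stri_match_first_regex(names,
    "^p(\\d+):([AB]):(\\d+):(\\d+)/([12])$")
  tibble::tibble(pair = as.integer(m[, 2]), hap = m[, 3],
                 start = as.integer(m[, 4]), insert = as.integer(m[, 5]),
                 mate = as.integer(m[, 6]))
}

#' Write a read pair set to two FASTQ files
#'
#' @param pairs a `read_pairs` object.
#' @param prefix path prefix; files `<prefix>_1.fq` / `<prefix>_2.fq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fq"); p2 <- paste0(prefix, "_2.fq")
  write_fastq(pairs$read1, p1)
  write_fastq(pairs$read2, p2)
  invisible(c(p1, p2))
}
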