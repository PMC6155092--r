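#' Reverse complement of character sequences
#'
#' Vectorised over its input; non-ACGT characters are complemented to `N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCATGCA", x))
}

# Derive a reproducible sub-stream seed from (operation name, master seed),
# so that module calls are order-independent for a fixed master seed.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_op_seed <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, op))
  force(code)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file
#'
#' Simulated reads carry a fixed quality character (`{`, Phred+33 score 58),
#' marking them as synthetic.
#'
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  nm <- names(reads)
  if (is.null(nm)) nm <- paste0("read", seq_along(reads))
  qual <- strrep("{", nchar(reads))
  lines <- as.vector(rbind(paste0("@", nm), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

# Internal: accept reads as a character vector or a FASTQ path (or a list of
# either) and return one character vector.
as_reads <- function(reads) {
  if (is.list(reads)) {
    return(unlist(lapply(reads, as_reads), use.names = FALSE))
  }
  stopifnot(is.character(reads))
  if (length(reads) >= 1 && all(file.exists(reads)) &&
      !grepl("^[ACGTNacgtn]+$", reads[[1]])) {
    return(unlist(lapply(reads, function(p) unname(read_fastq(p))),
                  use.names = FALSE))
  }
  reads
}
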