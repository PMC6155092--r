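#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.genome_size_estimate <- function(x, ...) {
  tibble::tibble(haploid_size = x$haploid_size,
                 hom_peak_depth = x$hom_peak_depth,
                 het_peak_depth = x$het_peak_depth,
                 error_trough_depth = x$error_trough_depth,
                 retained_kmer_total = x$retained_kmer_total)
}

#' @export
tidy.kmer_peaks <- function(x, ...) {
  tibble::tibble(feature = c("error_trough", "het_peak", "hom_peak"),
                 depth = c(x$error_trough_depth, x$het_peak_depth,
                           x$hom_peak_depth))
}

#' @export
tidy.variant_ledger <- function(x, ...) {
  dplyr::bind_rows(
    if (nrow(x$snps) > 0)
      tibble::tibble(class = "snp", pos = x$snps$pos,
                     end = x$snps$pos + 1L,
                     detail = paste0(x$snps$ref, ">", x$snps$alt)),
    if (nrow(x$indels) > 0)
      tibble::tibble(class = ifelse(x$indels$sign > 0, "insertion",
                                    "deletion"),
                     pos = x$indels$pos,
                     end = x$indels$pos + nchar(x$indels$seq),
                     detail = x$indels$seq),
    if (nrow(x$inversions) > 0)
      tibble::tibble(class = "inversion", pos = x$inversions$start,
                     end = x$inversions$end,
                     detail = paste0(x$inversions$end -
                                       x$inversions$start, " bp")))
}

#' @export
tidy.phased_assembly <- function(x, ...) {
  s <- x$scaffolds
  tibble::tibble(id = s$id, length = s$length, role = s$role,
                 partner = s$partner, hap = s$hap,
                 n_bubbles = lengths(s$bubbles))
}

#' @export
glance.phased_assembly <- function(x, ...) {
  st <- assembly_stats(x$scaffolds$seq)
  tibble::tibble(n_scaffolds = st$n, total_length = st$total_length,
                 n50 = st$n50, longest = st$longest,
                 n_bubbles = nrow(x$bubbles),
                 n_primary = sum(x$scaffolds$role == "primary"),
                 n_secondary = sum(x$scaffolds$role == "secondary"),
                 n_nonbubble = sum(x$scaffolds$role == "nonbubble"))
}

#' @export
tidy.candidate_interval <- function(x, ...) {
  tibble::tibble(start = x$start, end = x$end,
                 left_flank_marker = x$left_flank_marker,
                 right_flank_marker = x$right_flank_marker,
                 n_complete = x$n_complete,
                 contains = paste(x$contains, collapse = ","))
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    genome_size_rel_error = x$genome_size$rel_error,
    primary_identity = x$assembly$primary_identity,
    secondary_identity = x$assembly$secondary_identity,
    phasing_accuracy = x$assembly$phasing_accuracy,
    consensus_coverage = x$assembly$consensus_coverage,
    inversion_size_rel_error = x$inversion$size_rel_error,
    interval_contains_causal = x$association$contains_causal_gene,
    f2_chisq_p = x$association$f2_chisq_p)
}
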