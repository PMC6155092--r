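#' Pipeline run configuration
#'
#' A flat, validated key-value configuration for an end-to-end run:
#' simulate a diploid locus, sequence it, estimate genome size from
#' k-mers, assemble phased and consensus scaffolds, validate with
#' mate-pair window links, compare the alleles for inversion traces, and
#' map the causal interval in a simulated cross. Unknown keys are
#' rejected (this catches config typos early). The configuration is
#' serialisable and reloadable losslessly via [write_config()] /
#' [read_config()].
#'
#' The default values define the demonstration conditions: a 200 kb
#' locus, a 66 kb inversion inside the focal gene's first intron, 0.5%
#' allelic SNP divergence, 56x of error-free paired-end plus 3 kb
#' mate-pair reads (20 + 20 + 16), a 15 kb mate-pair validation library,
#' and a BC1 panel of 183 progeny with a marker every 5 kb.
#'
#' @param ... key = value overrides of the defaults (see
#'   `supergene:::config_defaults()`).
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- config_defaults()
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  num <- vapply(config_defaults(), is.numeric, logical(1))
  for (k in names(cfg)[num]) cfg[[k]] <- as.numeric(cfg[[k]])
  stopifnot(cfg$inversion_end >= cfg$inversion_start,
            cfg$inversion_end <= cfg$genome_length)
  structure(cfg, class = "run_config")
}

config_defaults <- function() {
  list(
    seed = 1, out_dir = "supergene_run",
    genome_length = 200000, genome_gc = 0.35, genome_repeat_fraction = 0,
    snp_rate = 0.005, indel_rate = 0,
    inversion_start = 60000, inversion_end = 126000,
    intron_expansion = 0,
    read_len = 100, error_rate = 0,
    pe300_coverage = 20, pe500_coverage = 20, mp3k_coverage = 16,
    mp15k_coverage = 30,
    k = 31, count_k = 32, min_count = 2, min_links = 3,
    seed_len = 15, min_seeds = 3,
    min_anchor = 12, min_cluster = 65,
    block_min_len = 500, repeat_max_len = 1250, repeat_min_hits = 2,
    inv_merge_dist = 10000,
    cross_design = "BC1", cross_n = 183, f2_n = 400,
    marker_spacing = 5000, recomb_rate = 1e-5,
    dominance = "A-dominant")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, x[[k]]))
  invisible(x)
}

#' @rdname run_config
#' @param out_dir output directory.
#' @param seed master seed.
#' @export
demo_config <- function(out_dir = "supergene_demo", seed = 1) {
  run_config(out_dir = out_dir, seed = seed)
}

#' Write / read a run configuration
#'
#' Flat `key = value` text format; unknown keys are errors when reading.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `path` invisibly; `read_config()` returns a `run_config`.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], scientific = FALSE)),
    character(1))
  writeLines(c("# pipeline run configuration", lines), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- stringi::stri_match_first_regex(lines, "^\\s*([^=\\s]+)\\s*=\\s*(.*?)\\s*$")
  if (any(is.na(kv[, 1]))) stop("malformed config line(s)")
  vals <- as.list(kv[, 3])
  names(vals) <- kv[, 2]
  do.call(run_config, vals)
}

# locus layout on the simulated genome: an upstream GATA-like neighbour
# gene ending at 0.2 L, the focal gene's exon 1 at 0.25 L and exon 2 at
# 0.65 L, so the first intron hosts the inversion interval
locus_layout <- function(L) {
  list(upstream_gene_end = round(0.20 * L),
       exon1 = c(round(0.25 * L), round(0.25 * L) + 200),
       exon2 = c(round(0.65 * L), round(0.65 * L) + 400))
}

locus_features <- function(L) {
  lay <- locus_layout(L)
  tibble::tibble(
    label = c("upstream_gene", "exon1", "intron1", "exon2", "focal_gene"),
    start = c(lay$upstream_gene_end - 5000, lay$exon1[1], lay$exon1[2],
              lay$exon2[1], lay$exon1[1]),
    end = c(lay$upstream_gene_end, lay$exon1[2], lay$exon2[1],
            lay$exon2[2], lay$exon2[2]))
}

#' Run the full simulation-to-mapping pipeline
#'
#' Executes every stage in order, writes all intermediate artifacts under
#' `cfg$out_dir` (FASTA haplotypes, FASTQ libraries, ledger and panel
#' TSVs, k-mer histogram, scaffold FASTA, block/dot-plot TSVs,
#' association TSV) and returns a run report comparing every stage
#' against the simulation truth: genome-size estimate vs true haploid
#' length, phased-scaffold identity vs the true haplotypes, consensus
#' coverage of the locus, inversion calls vs the variant ledger, and the
#' candidate interval vs the causal interval. The report (minus
#' timings) is a pure function of the configuration.
#'
#' @param cfg a [run_config()].
#' @param write_artifacts if `FALSE`, skip writing files (used by tests).
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(cfg, write_artifacts = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  out <- cfg$out_dir
  art <- character(0)
  keep <- function(path) { art <<- c(art, path); path }
  if (write_artifacts) dir.create(out, recursive = TRUE,
                                  showWarnings = FALSE)
  timing <- list()
  tic <- function() Sys.time()
  toc <- function(t, stage) timing[[stage]] <<- as.numeric(
    difftime(Sys.time(), t, units = "secs"))

  ## stage 1: diploid locus with known truth -----------------------------
  t <- tic()
  L <- cfg$genome_length
  parent <- generate_genome(L, gc = cfg$genome_gc,
                            repeat_fraction = cfg$genome_repeat_fraction,
                            seed = cfg$seed, name = "alleleA")
  parent$features <- locus_features(L)
  has_inv <- cfg$inversion_end > cfg$inversion_start
  inv_iv <- if (has_inv) c(cfg$inversion_start, cfg$inversion_end) else NULL
  ins <- if (cfg$intron_expansion > 0)
    tibble::tibble(pos = round((cfg$inversion_start +
                                  locus_layout(L)$exon1[2]) / 2),
                   len = cfg$intron_expansion) else NULL
  da <- derive_allele(parent, snp_rate = cfg$snp_rate,
                      indel_rate = cfg$indel_rate,
                      inversions = if (has_inv) tibble::tibble(
                        start = cfg$inversion_start,
                        end = cfg$inversion_end) else NULL,
                      insertions = ins, seed = cfg$seed, name = "alleleB")
  alleleA <- parent
  alleleB <- da$hap
  ledger <- da$ledger
  if (write_artifacts) {
    write_fasta(c(alleleA = alleleA$seq, alleleB = alleleB$seq),
                keep(file.path(out, "alleles.fa")))
    write_bed(alleleA, keep(file.path(out, "features.bed")))
    write.table(as.data.frame(ledger$snps),
                keep(file.path(out, "ledger_snps.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(ledger$inversions),
                keep(file.path(out, "ledger_inversions.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  toc(t, "synth")

  ## stage 2: read libraries --------------------------------------------
  t <- tic()
  mk_lib <- function(kind, insert, cov)
    lib_spec(kind, read_len = cfg$read_len, insert_mean = insert,
             error_rate = cfg$error_rate, coverage = cov)
  libs <- list(
    pe300 = simulate_reads(alleleA, alleleB,
                           mk_lib("paired-end", 300, cfg$pe300_coverage),
                           seed = cfg$seed),
    pe500 = simulate_reads(alleleA, alleleB,
                           mk_lib("paired-end", 500, cfg$pe500_coverage),
                           seed = cfg$seed),
    mp3k = simulate_reads(alleleA, alleleB,
                          mk_lib("mate-pair", 3000, cfg$mp3k_coverage),
                          seed = cfg$seed))
  mp15k <- simulate_reads(alleleA, alleleB,
                          mk_lib("mate-pair", 15000, cfg$mp15k_coverage),
                          seed = cfg$seed)
  if (write_artifacts) {
    for (nm in names(libs))
      keep(write_fastq_pair(libs[[nm]], file.path(out, nm)))
    keep(write_fastq_pair(mp15k, file.path(out, "mp15k")))
  }
  toc(t, "reads")

  ## stage 3: k-mer genome-size estimation ------------------------------
  t <- tic()
  pe_reads <- c(unname(libs$pe300$read1), unname(libs$pe300$read2),
                unname(libs$pe500$read1), unname(libs$pe500$read2))
  hist <- count_kmers(pe_reads, k = cfg$count_k)
  gse <- estimate_genome_size(hist)
  if (write_artifacts)
    write_kmer_hist(hist, keep(file.path(out, "kmer_hist.tsv")))
  maxreads <- compute_maxreads(gse$haploid_size, cfg$read_len)
  toc(t, "kmer")

  ## stage 4: bubble-phased assembly ------------------------------------
  t <- tic()
  graph <- build_graph(pe_reads, k = cfg$k, min_count = cfg$min_count)
  bubbles <- detect_bubbles(graph)
  arm_links <- lapply(libs, function(lp)
    map_pairs(lp, graph$unitigs$seq, seed_len = cfg$seed_len,
              min_seeds = cfg$min_seeds))
  phasing <- phase_bubbles(bubbles, arm_links)
  assembly <- scaffold_and_iterate(graph, bubbles, phasing, libs,
                                   min_links = cfg$min_links,
                                   seed_len = cfg$seed_len,
                                   min_seeds = cfg$min_seeds)
  consensus <- build_consensus(assembly, libraries = libs["mp3k"],
                               min_links = cfg$min_links,
                               seed_len = cfg$seed_len,
                               min_seeds = cfg$min_seeds)
  if (write_artifacts) {
    s <- assembly$scaffolds
    write_fasta(setNames(
      s$seq, sprintf("scaffold%d role=%s partner=%s", s$id, s$role,
                     ifelse(is.na(s$partner), "none", s$partner))),
      keep(file.path(out, "phased_scaffolds.fa")))
    write_fasta(setNames(consensus$seq,
                         sprintf("consensus%d role=consensus",
                                 consensus$id)),
                keep(file.path(out, "consensus_scaffolds.fa")))
  }
  # truth comparison: largest primary + its secondary partner vs the two
  # simulated haplotypes
  prim <- assembly$scaffolds[assembly$scaffolds$role == "primary", ]
  hap_ident <- list(primary = NA_real_, secondary = NA_real_,
                    opposite = NA)
  if (nrow(prim) > 0) {
    prim <- prim[which.max(prim$length), ]
    sec <- assembly$scaffolds[
      !is.na(assembly$scaffolds$partner) &
        assembly$scaffolds$id == prim$partner, ]
    idA <- seq_identity(prim$seq, alleleA$seq)$identity
    idB <- seq_identity(prim$seq, alleleB$seq)$identity
    prim_target <- if (idA >= idB) "A" else "B"
    hap_ident$primary <- max(idA, idB)
    if (nrow(sec) == 1) {
      other <- if (prim_target == "A") alleleB$seq else alleleA$seq
      same <- if (prim_target == "A") alleleA$seq else alleleB$seq
      ido <- seq_identity(sec$seq, other)$identity
      ids <- seq_identity(sec$seq, same)$identity
      hap_ident$secondary <- ido
      hap_ident$opposite <- ido >= ids
    }
  }
  cons_cov <- aligned_fraction(alleleA, consensus$seq,
                               min_anchor = cfg$min_anchor)
  phase_acc <- phasing_accuracy(assembly, alleleA$seq, alleleB$seq)
  toc(t, "assemble")

  ## stage 5: mate-pair window-link validation --------------------------
  t <- tic()
  main_cons <- consensus$seq[[1]]
  wl <- window_link_matrix(main_cons, mp15k, window = 2000,
                           min_links = cfg$min_links)
  band <- round(15000 / 2000)
  in_band <- mean(abs(wl$window_j - wl$window_i) <= band + 1)
  toc(t, "validate")

  ## stage 6: allele comparison and inversion calling -------------------
  t <- tic()
  blocks <- anchor_align(alleleA, alleleB, min_anchor = cfg$min_anchor,
                         min_cluster = cfg$min_cluster)
  fb <- filter_blocks(blocks, min_len = cfg$block_min_len,
                      repeat_max_len = cfg$repeat_max_len,
                      repeat_min_hits = cfg$repeat_min_hits)
  inv <- call_inversions(fb, merge_dist = cfg$inv_merge_dist)
  if (write_artifacts)
    export_dotplot(fb, keep(file.path(out, "dotplot_blocks.tsv")))
  true_size <- cfg$inversion_end - cfg$inversion_start
  inv_err <- if (nrow(inv) > 0 && true_size > 0)
    min(abs(inv$size - true_size)) / true_size else NA_real_
  lay <- locus_layout(L)
  sizes <- locus_sizes(
    locus_annotation(tibble::tibble(
      start = c(lay$exon1[1], lay$exon2[1]),
      end = c(lay$exon1[2], lay$exon2[2]))),
    lay$upstream_gene_end)
  toc(t, "synteny")

  ## stage 7: ddRAD digest ----------------------------------------------
  t <- tic()
  rad <- digest_ddrad(alleleA)
  toc(t, "ddrad")

  ## stage 8: cross and candidate-interval delimitation -----------------
  t <- tic()
  markers <- seq(round(cfg$marker_spacing / 2), L - 1,
                 by = cfg$marker_spacing)
  lay2 <- locus_layout(L)
  causal_iv <- if (has_inv) inv_iv else c(lay2$exon1[1], lay2$exon2[2])
  panel <- simulate_cross(cfg$cross_design, alleleA, alleleB,
                          n = cfg$cross_n, marker_positions = markers,
                          recomb_rate = cfg$recomb_rate,
                          suppressed_interval = inv_iv,
                          causal_interval = causal_iv,
                          dominance = cfg$dominance, seed = cfg$seed)
  assoc <- score_association(panel)
  interval <- delimit_region(assoc, scaffold_len = L,
                             features = alleleA$features)
  f2 <- simulate_cross("F2", alleleA, alleleB, n = cfg$f2_n,
                       marker_positions = markers[1],
                       recomb_rate = cfg$recomb_rate,
                       suppressed_interval = inv_iv,
                       causal_interval = causal_iv,
                       dominance = cfg$dominance, seed = cfg$seed)
  f2_tab <- table(factor(f2$causal_genotype, c("AA", "AB", "BB")))
  f2_chisq <- chisq.test(f2_tab, p = c(0.25, 0.5, 0.25))
  if (write_artifacts) {
    write_panel_tsv(panel, keep(file.path(out, "panel.tsv")))
    write.table(as.data.frame(assoc),
                keep(file.path(out, "association.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sup_markers <- if (has_inv)
    assoc[assoc$pos >= cfg$inversion_start &
            assoc$pos < cfg$inversion_end, ] else assoc[0, ]
  toc(t, "coseg")

  report <- structure(list(
    config = unclass(cfg),
    genome_size = list(truth = L, estimate = gse$haploid_size,
                       rel_error = abs(gse$haploid_size - L) / L,
                       hom_peak = gse$hom_peak_depth,
                       het_peak = gse$het_peak_depth,
                       trough = gse$error_trough_depth,
                       maxreads = maxreads),
    assembly = list(
      n_unitigs = nrow(graph$unitigs), n_bubbles = nrow(bubbles),
      n_scaffolds = nrow(assembly$scaffolds),
      stats = as.list(assembly_stats(assembly$scaffolds$seq)),
      primary_identity = hap_ident$primary,
      secondary_identity = hap_ident$secondary,
      haplotypes_opposite = hap_ident$opposite,
      phasing_accuracy = phase_acc,
      consensus_n = nrow(consensus),
      consensus_coverage = cons_cov),
    validation = list(n_link_pairs = nrow(wl),
                      in_band_fraction = in_band),
    inversion = list(truth_size = true_size, n_calls = nrow(inv),
                     called_sizes = inv$size, size_rel_error = inv_err),
    locus_sizes = as.list(sizes),
    ddrad = list(n_retained_fragments = nrow(rad)),
    association = list(
      interval_start = interval$start, interval_end = interval$end,
      contains_causal_gene = "focal_gene" %in% interval$contains,
      contains_suppressed = if (has_inv)
        interval$start <= cfg$inversion_start &
        interval$end >= cfg$inversion_end else NA,
      suppressed_markers_complete = if (has_inv)
        all(sup_markers$status == "complete") else NA,
      n_complete = interval$n_complete,
      f2_chisq_p = unname(f2_chisq$p.value)),
    artifacts = art,
    timing_s = timing,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (write_artifacts) {
    rep_json <- unclass(report)
    rep_json$timing_s <- NULL; rep_json$elapsed_s <- NULL
    jsonlite::write_json(rep_json, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# fraction of bubbles whose arm-to-haplotype assignment agrees with the
# majority orientation of their phasing component (truth from arm
# sequences: each arm occurs verbatim in exactly one haplotype)
phasing_accuracy <- function(assembly, hapA, hapB) {
  b <- assembly$bubbles
  if (nrow(b) == 0) return(NA_real_)
  ph <- assembly$phasing
  in_hap <- function(arm_seq, hap) {
    grepl(arm_seq, hap, fixed = TRUE) ||
      grepl(revcomp(arm_seq), hap, fixed = TRUE)
  }
  truth <- vapply(seq_len(nrow(b)), function(i) {
    a_in_A <- in_hap(b$arm_a_seq[i], hapA)
    b_in_B <- in_hap(b$arm_b_seq[i], hapB)
    a_in_B <- in_hap(b$arm_a_seq[i], hapB)
    b_in_A <- in_hap(b$arm_b_seq[i], hapA)
    if (a_in_A && b_in_B && !(a_in_B && b_in_A)) 0L
    else if (a_in_B && b_in_A && !(a_in_A && b_in_B)) 1L
    else NA_integer_
  }, integer(1))
  ok <- !is.na(truth)
  if (!any(ok)) return(NA_real_)
  d <- tibble::tibble(component = ph$component[ok],
                      agree = as.integer(ph$phase[ok] == truth[ok]))
  per_comp <- d |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(correct = max(sum(.data$agree),
                                   dplyr::n() - sum(.data$agree)),
                     n = dplyr::n(), .groups = "drop")
  sum(per_comp$correct) / sum(per_comp$n)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  genome size: truth %d, estimate %d (rel err %.3f)\n",
              x$genome_size$truth, x$genome_size$estimate,
              x$genome_size$rel_error))
  cat(sprintf("  assembly: %d bubbles, %d scaffolds, primary identity %s\n",
              x$assembly$n_bubbles, x$assembly$n_scaffolds,
              format(x$assembly$primary_identity, digits = 5)))
  cat(sprintf("  consensus coverage %.3f; phasing accuracy %s\n",
              x$assembly$consensus_coverage,
              format(x$assembly$phasing_accuracy, digits = 4)))
  cat(sprintf("  inversion: truth %d, %d call(s), rel size error %s\n",
              x$inversion$truth_size, x$inversion$n_calls,
              format(x$inversion$size_rel_error, digits = 3)))
  cat(sprintf("  candidate interval [%s, %s), contains causal gene: %s\n",
              format(x$association$interval_start, big.mark = ","),
              format(x$association$interval_end, big.mark = ","),
              x$association$contains_causal_gene))
  invisible(x)
}
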