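Package: supergene
Title: Simulation and Localisation of an Inversion Supergene from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully simulated re-implementation of the
    computational chain used to localise a colour-pattern supergene in
    ladybird beetles: diploid genome and read simulation with a variant
    ledger (SNPs, indels, large inversions), canonical k-mer counting and
    haploid genome-size estimation from k-mer histograms, bubble-preserving
    de Bruijn assembly with read-pair bubble phasing into phased and
    consensus scaffolds, mate-pair window-link validation, filtered pairwise
    scaffold comparison with inversion-trace calling and dot-plot export,
    in-silico ddRAD digestion, and marker co-segregation screening on
    simulated backcross and intercross panels with candidate-interval
    delimitation. Every input is generated with known ground truth from a
    single seed, so each stage can be scored against the truth it was
    simulated from.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    tibble,
    dplyr,
    tidyr,
    generics,
    rlang,
    stringi,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
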