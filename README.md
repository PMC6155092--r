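# supergene

Desk-scale simulation and localisation of an inversion supergene from
short-read data, in R.

Ladybird-beetle colour-pattern morphs are controlled by a single Mendelian
locus — a supergene — whose alleles differ by large (tens of kb)
chromosomal inversions in the noncoding region of a developmental gene.
Finding such a locus from sequencing data takes a chain of computational
steps: estimating the genome size from k-mer spectra, assembling a highly
heterozygous diploid genome while *keeping* the haplotype bubbles instead
of popping them, validating scaffolds with mate-pair links, comparing
allelic scaffolds for inversion traces, and delimiting the causal region
by marker co-segregation in crosses. `supergene` re-implements that whole
chain at desk scale, against fully simulated inputs with known ground
truth, so every stage can be scored exactly.

The package is aimed at people studying structural-variant supergenes
(inversion polymorphisms, recombination suppression, co-segregation
mapping) who want a reproducible, testable model of the analysis chain
rather than a production assembler.

## What is implemented

* **Simulation with a variant ledger** (`generate_genome()`,
  `derive_allele()`, `simulate_reads()`, `digest_ddrad()`,
  `simulate_cross()`): a diploid locus with tunable heterozygosity, allele
  pairs differing by a large inversion (and optionally an intron
  expansion), paired-end / mate-pair reads with truth-tagged names,
  in-silico double-digest RAD fragments with size selection, and BC1/F2
  panels with recombination suppressed inside the inversion. The ledger
  round-trips: `apply_ledger(parent, ledger)` equals the child
  byte-for-byte.
* **k-mer genome-size estimation** (`count_kmers()`, `find_peaks()`,
  `estimate_genome_size()`, `compute_maxreads()`): canonical k-mer
  histograms (default k = 32, both strands counted as one), detection of
  the error trough and the heterozygous/homozygous peaks, and the
  estimator

  `haploid size = (total k-mers at depth >= trough) / hom-peak depth`,

  plus the read budget `floor(size / read length x 56)` for a 56x target.
* **Bubble-preserving assembly with haplotype phasing**
  (`build_graph()`, `detect_bubbles()`, `map_pairs()`,
  `phase_bubbles()`, `scaffold_and_iterate()`, `build_consensus()`,
  `window_link_matrix()`): a de Bruijn graph that keeps heterozygosity
  bubbles, greedy link-weighted fusion of bubble arms into two haplotype
  classes, per-haplotype scaffolding with N gaps sized from insert
  lengths, primary/secondary/nonbubble labelling, mosaic consensus
  scaffolds, and 2 kb-window mate-pair validation (links below 3 pairs
  suppressed).
* **Pairwise scaffold comparison** (`anchor_align()`, `filter_blocks()`,
  `call_inversions()`, `locus_sizes()`, `export_dotplot()`): unique-anchor
  (MUM-like) matching chained into oriented blocks; the two comparison
  filters (spans < 500 bp; spans < 1250 bp hit by more than two blocks);
  grouping of reverse blocks into inversion calls; noncoding-span
  arithmetic (upstream intergenic + first intron).
* **Co-segregation mapping** (`score_association()`, `delimit_region()`):
  recombinant counting under the cross design and dominance model, and
  candidate-interval delimitation by "complete association inside,
  incomplete at both ends".
* **End-to-end pipeline** (`run_config()`, `run_pipeline()`,
  `demo_config()`): one seeded configuration drives all stages and emits
  a JSON report comparing every stage against the simulation truth.

Results are tibbles (or small classed objects with `tidy()` / `glance()`
methods), and each result type has an `autoplot()` method.

## Worked example

```r
library(supergene)
cfg <- demo_config(out_dir = "supergene_demo", seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

```
<run_report>
  genome size: truth 200000, estimate 204444 (rel err 0.022)
  assembly: 822 bubbles, 8 scaffolds, primary identity 1
  consensus coverage 1.000; phasing accuracy 1
  inversion: truth 66000, 1 call(s), rel size error 0
  candidate interval [57,500, 132,500), contains causal gene: TRUE
```

Reading the report: the 32-mer estimator recovered the 200 kb haploid
truth within 2.2%; the assembler phased 822 heterozygosity bubbles into
two haplotype scaffolds that are 100% identical to the two simulated
haplotypes (up to which haplotype is called "primary"); the consensus
mosaic covers the whole locus; the allele comparison called exactly one
inversion whose size matches the simulated 66 kb inversion; and the BC1
panel of 183 progeny delimited a candidate interval ([57.5 kb, 132.5 kb))
that contains both the suppressed inversion ([60 kb, 126 kb)) and the
focal gene. All intermediate artifacts (FASTA/FASTQ/TSV/JSON) are written
under `cfg$out_dir`.

Individual stages work standalone, e.g.:

```r
g  <- generate_genome(30000, gc = 0.4, seed = 5)
rp <- simulate_reads(g, g, lib_spec("paired-end", coverage = 20), seed = 2)
estimate_genome_size(count_kmers(rp, k = 21))
#> <genome_size_estimate> haploid 30,000 bp (hom peak 16, trough 1)
```

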