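---
title: "Methods: simulating and localising an inversion supergene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and localising an inversion supergene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices, and limitations. The package simulates a diploid locus carrying
an inversion supergene and re-implements, at desk scale, the analysis
chain used to localise such loci: k-mer genome-size estimation,
bubble-preserving diploid assembly with haplotype phasing, mate-pair
validation, pairwise allele comparison with inversion-trace calling, and
co-segregation mapping in crosses.

## The simulated system

The generator models a single genomic region (default 200 kb) around a
colour-pattern gene. Two alleles of the region are produced from one
ancestral sequence: the derived allele carries background point
divergence (default 0.5% SNPs per bp — a typical allelic divergence for a
diversified supergene haplotype; the strains' true heterozygosity is a
free parameter of the simulation, not an empirical value) and one large
inversion (default 66 kb, the middle of the 56-76 kb range that motivates
the recovery tests) placed inside the focal gene's first intron. The
locus layout puts an upstream neighbour gene's 3' end at 0.20 L and the
focal gene's exons 1 and 2 at 0.25 L and 0.65 L, so the first intron is
large and hosts the inversion, mirroring the architecture in which
inversion traces sit in the upstream half of a first intron.

Every random operation derives its stream from a single master seed by
hashing the operation name, so calling modules in a different order
changes nothing.

The variant ledger is the ground truth: inversions (applied first, in
parent coordinates, length preserving), then SNPs (post-inversion
coordinates), then indels (descending-position application). The
generator builds the child by incremental editing and the independent
`apply_ledger()` replay must reproduce it byte-for-byte — a property the
suite checks with sampled indels and inversions together.

Read simulation covers paired-end (inward mates) and mate-pair (outward
mates) libraries. Defaults for the assembly conditions are PE300 at 20x,
PE500 at 20x and MP3k at 16x — 56x in total, matching the optimum
coverage the genome-size step targets — with 100 bp reads, insert sd at
10% of the mean, and substitution-only errors. Read names encode the true
haplotype and fragment coordinates, which is what makes phasing accuracy
measurable without alignment. Fragments never span the ends (linear
genome), and fragments are taken from the genome forward strand; strand
symmetry of the assembler is tested separately by reverse-complementing
whole read sets.

Features of real data deliberately *not* modelled: indel sequencing
errors, PCR duplicates and coverage bias, linked-read barcodes, long-read
error profiles, genotyping error in crosses, and X-linked segregation.
Passing tests therefore show correctness of the algorithms under clean
conditions, not robustness to every artefact of real libraries — e.g.
the 99.9% phased-scaffold identity targets are achievable only with
error-free reads, which is exactly how they are simulated.

## k-mer genome-size estimation

Canonical 32-mers are counted over every clean window (windows containing
non-ACGT characters are skipped entirely, not masked). The histogram is
smoothed with a centred moving average of window 3 (zeros outside the
depth range) before scanning: the error trough is the first local
minimum walking up from depth 1 (or depth 1 itself when the histogram
rises immediately, on raw counts, so that boundary smoothing cannot
manufacture a false "rise"); candidate peaks are local maxima above the
trough. When the two largest maxima have a depth ratio in [1.7, 2.3] the
smaller is the heterozygous peak and the larger the homozygous peak;
ties in height break toward the higher depth. The haploid size is the
integer floor of (k-mer mass at depths at or above the trough) divided
by the homozygous peak depth. The exclusion of sub-trough mass removes
sequencing-error k-mers; the estimator is self-correcting for error
windows because they shift both the retained mass and the peak depth by
the same factor.

The original study's peak-picking script is not public, so the smoothing
and extremum rules here are this package's own declared stand-in,
validated by construction on synthetic histograms and by parameter
recovery: at 56x, 0.5% read error and 0.5% heterozygosity on a 200 kb
truth, the median relative error over seeds stays within 5% (it is
typically well under 3%).

## Bubble-preserving assembly and phasing

The graph stage keeps every canonical k-mer seen at least twice (dropping
singleton error k-mers) and performs **no** tip or bubble removal.
A single odd k (default 31) is used rather than a multi-k ramp: with
error-free or low-error synthetic reads there is nothing for k-ramping to
rescue, and a single k keeps the unitig arithmetic exact (unitig length
= node count + k - 1, checked against brute-force window enumeration).

Simple bubbles are a source end with exactly two single-unitig arms
reconverging at one sink end. An isolated SNP gives arms of exactly
2k - 1 bases differing at one position; clustered SNPs merge into longer
arms, accepted up to 5k (beyond that the region is left unphased —
a bounded-search choice). Arm "a" is the lexicographically smaller
oriented arm sequence; all tie-breaks in the package (arm naming, join
ordering, union-find attachment) are lexicographic or index-ordered so
output is byte-deterministic.

Read mapping is exact-match seeding only: 15-mer seeds, runs of at least
3 consecutive seeds on one diagonal, and seeds occurring at more than one
location in the element set are discarded outright. This makes repeats
self-masking and is adequate for error rates at or below about 1%; it is
not a general-purpose mapper. Fragments co-touching two bubble arms
(via either mate, or one read spanning both) vote for co-phasing; arms
are fused greedily in descending vote order under a parity-aware
union-find, skipping contradictions. With error-free links,
contradictions only arise from chimeric placements and are essentially
absent; the suite plants an explicit contradiction to check it is
skipped.

Each haplotype's scaffold is the maximal simple path over nonbubble
unitigs plus that haplotype's arms. Remaining breaks (coverage dropouts,
SNP tangles) are closed per library in ascending insert order: element
ends connected by at least 3 concordant links join with an N gap of
`max(1, round(insert - flank distances))` — the 1-N floor keeps every
join visible. An end claimed by two partners whose runner-up support is
at least half the best is left unjoined and logged. Homologous scaffolds
(sharing bubbles) pair as primary (longer) and secondary (shorter);
consensus scaffolds re-join primaries and nonbubbles only, so provenance
can never contain a secondary.

The six-step phasing procedure this follows is published only as a
sketch; the greedy link-count-ordered fusion and the single-k iteration
used here are an interpretation validated against simulation truth, not
against the original assembler's output.

Scaffold-vs-truth identity is computed gaplessly per N-free segment on
each segment's modal unique-k-mer diagonal. This is exact for SNP-only
simulations (the acceptance conditions); with indels it would
underestimate, which is one reason indels are excluded from the
assembler's read paths and kept only in the ledger for the comparison
module.

## Mate-pair window validation

A 15 kb-insert library mapped back to a consensus scaffold, cut into
2 kb windows; window pairs supported by fewer than 3 mate pairs are
zeroed. On a correct scaffold the retained links form a band at
|i - j| around insert/window (the tests allow the band implied by the
insert mean + 4 sd); across a deliberate mis-join the band is empty,
which is the diagnostic signature.

## Pairwise allele comparison

Anchors are exact matches of length 12 (the anchor length used for
intra-species scaffold comparison in the motivating study) that are
unique in both sequences over both strands — a MUM-like criterion that
reproduces the behaviour class of anchor-chaining aligners without
binding to any one tool. Same-diagonal anchors merge into runs; runs
chain greedily with a 100 bp diagonal band and a 5 kb gap ceiling (both
exposed as arguments; the published analyses show only rendered results,
so these are calibration choices). Chains under 65 matched bases are
dropped.

The two block filters are applied in order: spans under 500 bp are
removed; then spans under 1250 bp whose query interval overlaps a locus
hit by more than two blocks (strictly more than two, counting the block
itself) are removed as short repeats. The thresholds are applied to the
query span by default with a switch for the subject span, since the
original description does not say which; the filter is idempotent by
construction. Reverse blocks within 10 kb of each other on the query
merge into one inversion call whose size is the subject span of the
group. Recovery across 56-76 kb inversions on 700 kb alleles with 0.5%
SNP divergence is within 5% (typically within 0.01%).

Locus-size arithmetic: the upstream noncoding span is the distance from
the upstream gene's 3' end to the focal gene's 5' start; the first
intron is exon-2 start minus exon-1 end; their sum is the "upper
noncoding" span used for cross-taxon comparisons.

## Crosses and co-segregation

Gametes from heterozygous parents receive Poisson crossovers (default
1e-5 per bp per meiosis — deliberately hot so that a 200 kb desk-scale
region behaves like a mappable chromosome arm, with about 5% adjacent-
marker recombination at 5 kb spacing) placed uniformly outside the
suppressed interval and never inside it. Phenotypes are fully penetrant:
in F2, the dominant-allele carriers form one class (black dominates); in
BC1 to the recurrent line, the heterozygote is distinguishable from the
recurrent homozygote (mosaic dominance makes the heterozygote's combined
pattern visible), which is what makes the backcross informative.

Association scoring counts genotype-phenotype mismatches under the
design's truth table; in F2 with a dominant phenotype, AA vs AB never
count against each other. "Complete" association means strictly zero
recombinants — real data would need a genotyping-error allowance, which
is intentionally not modelled. Missing genotypes are excluded per
marker; monomorphic markers are excluded as uninformative. The candidate
interval runs from the last incomplete marker left of the longest
complete run to the first incomplete marker on the right, open to the
scaffold end when a side has no incomplete marker; endpoints are marker
positions, not midpoints.

## Problem sizes and defaults

The shipped conditions are: 200 kb demo locus (100 kb for the assembly
recovery runs), GC 0.35, 0.5% SNP divergence, one 66 kb inversion,
56x total coverage split 20/20/16 across PE300/PE500/MP3k, a 30x MP15k
validation library, k = 32 for counting and k = 31 for assembly,
min_count 2, min_links 3, BC1 n = 183 and F2 n = 400 with markers every
5 kb. Inversion recovery uses 700 kb alleles with inversions of 56, 66
and 76 kb. These sizes keep a full run around a minute while leaving
every statistic comfortably estimable; they are stated here as the
package's study conditions and used identically by the test suite and
`scripts/acceptance.R`.

## Known limitations

* Exact-seed mapping and single-k assembly are not robust above ~1%
  read error; error correction is out of scope.
* Repeats are handled only by seed uniqueness (self-masking), not
  resolved; high `repeat_fraction` genomes will fragment.
* The phasing walk emits arbitrary-but-deterministic arm choices for
  unlinked bubble components; on sparse-coverage simulations this bounds
  achievable scaffold identity.
* `seq_identity()` assumes indel-free alignment within N-free segments.
* The cross simulator is allelic (two founder alleles), with no
  genotyping error, missingness model, or sex chromosomes.
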