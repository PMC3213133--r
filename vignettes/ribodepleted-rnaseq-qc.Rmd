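---
title: "Quality control and quantification of ribo-depleted RNA-Seq with ribotag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and quantification of ribo-depleted RNA-Seq with ribotag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotag)
```

## The problem

Most of a cell's RNA is ribosomal. Libraries prepared by rRNA depletion
(RiboMinus, Ribo-Zero and similar chemistries) rather than polyA selection can
capture non-polyadenylated and very long transcripts — including macro ncRNAs
such as *Airn* (118 kb) and *Kcnq1ot1* (83 kb), largely unspliced RNA
polymerase II transcripts that polyA protocols tend to miss — but they come
with their own quality-control questions:

* How much of the library is still ribosomal or mitochondrial, and is that
  fraction stable across replicates, depletion chemistries and sequencing
  sites?
* Are expression estimates saturated at the achieved sequencing depth?
* How evenly do tags cover gene bodies — does the fragmentation step (RNA
  hydrolysis versus cDNA shearing) bias coverage along the transcript, and are
  UTRs under-represented?
* When two datasets made with different template-preparation protocols are
  compared, how much of the apparent differential expression is protocol,
  not biology — and does it concentrate in particular cDNA size classes?

`ribotag` implements this analysis chain for single-end tag libraries
(36 bp and 51 bp designs), together with a synthetic-data generator that
produces genomes, annotations, reads and per-read ground truth, so that every
stage is testable without external downloads.

## Tag classification

Tags are aligned hierarchically, mirroring the sequential alignment such
studies use: first against the rRNA and mitochondrial reference contigs, then
— for the survivors only — against the nuclear genome. Any placement in the
first stage puts the tag in the `rrna_mito` class even if it would also match
the genome; this ordering is what defines the familiar "rRNA+mito" bar in
library-composition plots. Against the genome, a tag matching exactly once is
`unique`, more than once `repeat`, and nowhere `nomatch`. Repeat tags are
excluded from all downstream quantification.

A placement is any offset, on either strand of any contig, with Hamming
distance at most *k* (no indels): *k* = 2 for tags shorter than 44 bp and
3 otherwise, matching the two read-length designs; lengths between the designs
keep the conservative allowance of 2. The matcher (`align_tags()`) is exact:
it partitions each tag into *k* + 1 disjoint seeds — by pigeonhole, at least
one seed of any ≤ *k*-mismatch placement is mismatch-free — finds seed hits
with `Biostrings::matchPDict()`, and verifies candidates at full length. The
test suite holds it to a literal shift-and-accumulate Hamming scan. Placements
on opposite strands at the same offset count separately (this can only matter
for palindromic corner cases). Bases are compared literally, so an `N` matches
only `N`.

Pre-aligned data enters through `ingest_sam()`, which applies the same
hierarchy using the contig classes, preferring the `NH` tag for multiplicity
and falling back to record counting.

Replicate compositions are compared with `compare_tag_fractions()`: a
two-sample pooled-variance t statistic on the class percentages with a
one-tailed p-value (Student's t, *n*~A~ + *n*~B~ − 2 df), oriented towards
mean(A) > mean(B). The closed form is implemented directly because the
degenerate zero-variance, equal-means case must return t = 0, p = 0.5 rather
than fail; `stats::t.test` is the oracle in the tests.

## Expression: RPKM and PPKM over exon models

Gene models are BED12 records; `thickStart`/`thickEnd` split each transcript's
exons into 5'UTR, CDS and 3'UTR compartments (records with
`thickStart == thickEnd` are noncoding and stay undivided). Each RefSeq-style
entry is quantified independently — no isoform collapsing, since nothing in
the method requires it and any merging rule would be arbitrary.

For a sample of *N* uniquely mapped genomic tags:

* **RPKM** = 10^9^ × (tags overlapping the gene's exon union by ≥ 1 bp) /
  (exonic length in bp × *N*). A tag overlapping two genes counts for both;
  strand is ignored (the libraries carry no strand information).
* **PPKM** replaces the tag count with the per-base pileup summed over exonic
  bases. When every counted tag lies fully inside the exon model,
  PPKM = read_length × RPKM exactly; tags straddling exon-model boundaries
  only contribute their exonic bases, pulling the empirical conversion factor
  below the read length (about 30 for 36 bp tags at a realistic ~15%
  straddle rate).

The denominator *N* counts unique genomic tags only: repeat tags are excluded
from all analyses and rRNA/mito tags are removed before genome alignment, so
neither belongs in a "per million mapped" normalisation. A gene is called
expressed above RPKM 3 (PPKM 90 under the factor-30 conversion); both
thresholds are configurable. Cross-sample agreement is summarised by Pearson
correlation of log10(value + 1) (`pearson_log_scatter()`).

## Saturation

`saturation_analysis()` subsamples the unique tags without replacement at a
ladder of depths (10 replicates by default), recomputes RPKM with the
subsample size as denominator, and reports per expression group the percentage
of genes whose subsampled RPKM lies within ±5% of the full-depth value, with
the replicate minimum and maximum as error bars. At full depth the subsample
is the identity, so every group sits at exactly 100%. Groups are ranges of
full-depth RPKM; the defaults (3,10], (10,100], >100 are package defaults,
configurable per analysis. Genes below the
expression threshold are not grouped, and an empty group yields `NaN` with a
warning — small groups legitimately produce large error bars.

## Gene-body coverage profiles

For every expressed protein-coding gene, each region's exonic sequence (5'UTR,
CDS, 3'UTR separately, introns removed, UTR introns included in nothing — only
exonic UTR bases are binned) is laid out 5'→3' in transcript orientation,
cut into 100 equal bins, and the per-base pileup is accumulated per bin and
divided by read length × total tags. "Number of tags per bin normalised for
tag size" is deliberately read as coverage divided by read length — per-base
pileup is robust to bins narrower than a tag, which is common for small genes.
Profiles are summed over the genes of each cDNA size class — small (< 1 kb),
medium (1–8 kb, boundaries inclusive), large (> 8 kb) — UTR bins are averaged
10→1 for display, and each size class is scaled by its highest bin (ties
would all scale to 1 identically).

Two systematic features of short-tag data are worth knowing when reading the
profiles. First, coverage ramps down within one read length of every exon
junction when junction-spanning tags are unmapped; individual genes therefore
show dips that only average out across many genes, which is why profile
figures are only smooth at transcriptome scale. Second, when a 5'UTR is
shorter than the read length, the transcript-start ramp reaches into the CDS
— small genes show end effects that medium genes do not. Homogeneity claims
in this package's checks are therefore made for the medium class, which is
also where the hydrolysis-versus-shearing contrast is sharpest: shearing-like
5'-weighted fragmentation (start density ∝ exp(−b·x/L)) depresses the 3' end
of the body, while hydrolysis-like uniform fragmentation leaves it flat.

## Cross-dataset comparison

Datasets made with different protocols differ by a roughly multiplicative
offset before they differ gene by gene. `estimate_correction_factor()` scans a
log2-spaced factor grid (2^−4^…2^4^, step 2^0.05^), applies each candidate to
dataset B, and counts genes in the concordant fold-difference bins: genes
expressed in both datasets (threshold re-tested after scaling) within the 8×
ratio, plus genes expressed in neither (the "0 bin"). Counting the
concordantly silent genes is essential: over-scaling pushes silent genes into
single-sided expression and is thereby penalised, which makes the objective
peak at the true offset instead of plateauing above it. The objective is a
step function of the factor, so maxima come in plateaus; the estimator returns
the centre of the tied run (choosing the run nearest factor 1 if several tie),
which bounds the recovery error by one grid step on data that is reasonably
dense around the expression threshold — as transcriptome-scale tables are.

`call_differential()` then applies the chosen factor and calls a gene
differential if it is expressed in exactly one dataset, or expressed in both
with a corrected ratio above 8×. Expression status is judged on each dataset's
own uncorrected scale — the factor only makes values comparable — which keeps
the call symmetric under swapping the tables with the inverted factor. For
single-sided genes the ratio is reported against the not-expressed side
floored at the threshold. Genes expressed in neither dataset are excluded.

Differential genes are profiled by cDNA size (`size_distribution()`): 100 bp
bins below 2 kb, 500 bp bins above, everything larger than 11.5 kb in the
last bin, frequencies relative to the set size. Two spectra are compared with
`wilcoxon_size_test()` separately below and above the 2 kb split, on the
relative frequencies. The rank-sum null distribution is enumerated exactly
(mid-ranks for ties) when the two sides together contribute at most 20 bins,
and approximated normally with the standard tie correction (no continuity
correction) otherwise; identical spectra give p = 1, and an all-zero side
returns `NaN` with a warning.

## The synthetic-data generator

`sim_config()` + `simulate_genome_annotation()` + `simulate_reads()` emulate
the statistical structure the analyses above assume:

* one nuclear contig of non-overlapping multi-exon coding genes cycling
  through the three size classes (cDNA ~0.3–0.9, 1.2–6, 9.5–15 kb; 10% 5'UTR,
  25% 3'UTR; exon count growing with length), optionally one long single-exon
  noncoding gene mimicking a macro ncRNA;
* an exactly duplicated 500 bp intergenic segment, so multi-mapping tags
  provably have two genome placements; separate rRNA (4.5 kb) and
  mitochondrial (16 kb) contigs;
* lognormal transcript abundances (meanlog 1, sdlog 1.5); transcripts are
  sampled proportional to abundance × length, since fragmenting full-length
  RNA yields more fragments from longer molecules;
* fragment starts uniform (hydrolysis) or 5'-weighted with density
  ∝ exp(−bias_rate·x/L) (shearing); starts in UTRs accepted with probability
  `utr_weight` (default 0.3 — the magnitude of UTR depletion is a free
  parameter, chosen to give a clearly visible contrast, not a literature
  value); an additional acceptance exp(−decay·x/1000) models length-dependent
  3' tag loss;
* fragments spanning exon junctions are re-drawn, matching the decision not
  to map junction tags (a small minority at realistic exon sizes);
* contamination and noise classes drawn per read: rRNA 50%, mito 5%, repeat
  6%, unmappable random background 12% by default — the composition of a
  RiboMinus hydrolysis lane (46–73% ribosomal/mito, 9–24% unique, 4–9%
  repeat, 9–21% nomatch); Ribo-Zero-like libraries are emulated by lowering
  `rrna_fraction`;
* tags come off either strand with equal probability; FASTQ qualities are
  constant `I` and never used.

Everything is deterministic given `seed`, down to the written FASTA/BED/FASTQ
bytes. The truth table records each read's origin (gene, rRNA, mito, repeat,
background) and genomic position, and `truth_tag_class()` maps origins to
expected alignment classes.

What the generator does **not** emulate — hence what passing tests do not
show about real data: sequencing errors and base qualities, paired ends,
strand-specific protocols, GC and mappability bias, splice-isoform mixtures,
intronic/pre-mRNA signal, and genuine rDNA copies inside the nuclear contig.
The matcher's truth-agreement checks run at zero sequencing error by design.

## Problem sizes and numerical choices

The checks in `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`
run at desk scale, chosen once as part of the study design: tag-classification
fidelity on five 50,000-read samples; matcher-versus-oracle on
kilobase-scale instances; saturation on 200,000 tags over 30 genes; the
coverage-flatness check on 1,200 genes × 4.8 M tags with equal reads per gene
(profile averaging needs transcriptome-scale gene counts, see above), with the
directional shearing and UTR contrasts at 90 genes × 200,000 tags; and
correction-factor recovery on 2,000-gene tables dense around the expression
threshold. Degenerate inputs are contracts, not accidents: empty read sets
give all-zero counts, an empty differential set gives an all-zero spectrum
with a warning, zero-variance scatter axes give `NaN` correlations with a
warning, and `total_tags = 0` is an error.

## Limitations

The matcher is exact but desk-scale: an exhaustive Hamming search is the
point, not a competitor to indexed aligners, and genome-scale data should
arrive as SAM. Quantification is per-transcript with no isoform
deconvolution, no junction-aware counting and no FPKM/TPM. The differential
call is a pure fold-change rule with no dispersion model or multiple-testing
machinery — by design, since its purpose is protocol comparability, not
discovery.
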