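Package: ribotag
Title: Tag Classification, Expression Quantification and Comparability
    Diagnostics for Ribo-Depleted RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and quantification toolkit for ribosomal-RNA
    depleted single-end RNA-Seq libraries. Classifies sequencing tags
    hierarchically into rRNA/mitochondrial, uniquely mapping, repeat and
    unmapped fractions with an exact k-mismatch matcher; quantifies genes by
    RPKM and PPKM over BED12 exon models split into UTR and CDS compartments;
    assesses sequencing-depth saturation by random tag subsampling; profiles
    5' to 3' gene-body coverage bias by region and cDNA size class; and
    compares transcriptomes across datasets via a fold-concordance correction
    factor, fold-change differential calls, cDNA size distributions and
    Wilcoxon rank-sum tests. Includes a synthetic-data generator emulating
    fragmentation bias, UTR under-sampling and ribosomal contamination, with
    per-read ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
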