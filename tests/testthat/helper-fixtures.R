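# Small fixtures built in code.

# a hand-made two-gene annotation on one contig:
#   geneP (+): utr5 [100,160), cds [160,460)+[760,1360), utr3 [1360,1600)
#   geneM (-): mirror orientation, single cds block with utrs
fixture_annotation <- function() {
  tag_annotation(data.frame(
    gene_id = c("geneP", "geneP", "geneP", "geneP",
                "geneM", "geneM", "geneM"),
    contig = "chr1",
    strand = c(rep("+", 4), rep("-", 3)),
    region = c("utr5", "cds", "cds", "utr3",
               "utr3", "cds", "utr5"),
    start = c(100L, 160L, 760L, 1360L,
              2000L, 2100L, 2900L),
    end = c(160L, 460L, 1360L, 1600L,
            2100L, 2900L, 3000L),
    biotype = "coding"))
}

# deterministic small simulated dataset shared across tests
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_genes = 9, n_reads = 4000,
                        include_macro_ncrna = TRUE,
                        macro_ncrna_length = 12000)
      sg <- simulate_genome_annotation(cfg)
      sr <- simulate_reads(cfg, sg)
      cache <<- list(cfg = cfg, genome = sg, reads = sr)
    }
    cache
  }
})

# a single-exon gene plus uniformly tiled reads over its neighbourhood,
# producing boundary-straddling tags at a controlled rate
fixture_straddle <- function(gene_len = 1500L, n_exons = 4L, read_len = 36L,
                             intron = 300L) {
  exon_w <- gene_len %/% n_exons
  widths <- c(rep(exon_w, n_exons - 1L), gene_len - exon_w * (n_exons - 1L))
  starts <- 500L + cumsum(c(0L, head(widths, -1L) + intron))
  ann <- tag_annotation(data.frame(
    gene_id = "gene1", contig = "chrT", strand = "+", region = "cds",
    start = starts, end = starts + widths, biotype = "noncoding"))
  contig_len <- max(starts + widths) + 1000L
  # every start position whose read overlaps the exon union by >= 1 bp
  cand <- unlist(lapply(seq_len(n_exons), function(j) {
    (starts[j] - read_len + 1L):(starts[j] + widths[j] - 1L)
  }))
  cand <- sort(unique(cand))
  list(ann = ann, contig_len = c(chrT = contig_len), starts = cand,
       read_len = read_len)
}

# placements of gene-derived tags straight from the generator's ground truth
# (bypasses the matcher where alignment is not the property under test)
truth_placements <- function(sr, cfg) {
  tr <- sr$truth[sr$truth$origin_class == "gene", ]
  data.frame(read_id = tr$read_id, contig = tr$contig, start = tr$start,
             strand = "+", mismatches = 0L, width = cfg$read_length)
}
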