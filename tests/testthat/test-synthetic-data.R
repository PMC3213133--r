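test_that("simulation is deterministic given the seed, down to the written bytes", {
  cfg <- sim_config(seed = 7, n_genes = 4, n_reads = 500,
                    include_macro_ncrna = TRUE, macro_ncrna_length = 20000)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- simulate_genome_annotation(cfg)
  r1 <- simulate_reads(cfg, g1)
  g2 <- simulate_genome_annotation(cfg)
  r2 <- simulate_reads(cfg, g2)
  write_sim(g1, r1, d1)
  write_sim(g2, r2, d2)
  for (f in c("genome.fa", "annotation.bed", "reads.fa", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # macro ncRNA mimic present as a single-exon noncoding gene of the set length
  ann <- g1$annotation
  mac <- ann[ann$gene_id == "macro_ncrna", ]
  expect_equal(nrow(mac), 1L)
  expect_equal(mac$biotype, "noncoding")
  expect_equal(unname(cdna_length(ann)["macro_ncrna"]), 20000L)
})

test_that("degenerate configurations still emit contigs and honour capacity", {
  cfg <- sim_config(seed = 3, n_genes = 0, n_reads = 100)
  g <- simulate_genome_annotation(cfg)
  expect_equal(nrow(g$annotation), 0L)
  expect_setequal(unname(ref_class(g$contigs)), c("nuclear", "rrna", "mito"))
  expect_error(
    simulate_genome_annotation(
      sim_config(seed = 3, n_genes = 10, contig_length = 5000)),
    "capacity")
})

test_that("truth classes partition the reads and match the configured mix", {
  sim <- fixture_sim()
  tr <- sim$reads$truth
  expect_equal(nrow(tr), sim$cfg$n_reads)
  expect_equal(anyDuplicated(tr$read_id), 0L)
  expect_true(all(tr$origin_class %in%
                    c("gene", "rrna", "mito", "repeat", "background")))
  frac <- table(tr$origin_class) / nrow(tr)
  expect_equal(unname(frac[["rrna"]]), sim$cfg$rrna_fraction, tolerance = 0.1)
  expect_equal(unname(frac[["background"]]), sim$cfg$background_fraction,
               tolerance = 0.25)
  # no contamination classes when their fractions are zero
  cfg0 <- sim_config(seed = 5, n_genes = 3, n_reads = 300,
                     rrna_fraction = 0, mito_fraction = 0)
  r0 <- simulate_reads(cfg0, simulate_genome_annotation(cfg0))
  expect_false(any(r0$truth$origin_class %in% c("rrna", "mito")))
})

test_that("hydrolysis coverage is uniform over a single-exon transcript interior", {
  cfg <- sim_config(seed = 11, n_genes = 0, n_reads = 50000,
                    rrna_fraction = 0, mito_fraction = 0,
                    repeat_fraction = 0, background_fraction = 0,
                    include_macro_ncrna = TRUE, macro_ncrna_length = 3000,
                    utr_weight = 1, three_prime_decay = 0)
  g <- simulate_genome_annotation(cfg)
  r <- simulate_reads(cfg, g)
  tr <- r$truth
  mac <- g$annotation[g$annotation$gene_id == "macro_ncrna", ]
  rel <- tr$start - mac$start  # genomic == transcript coords, single exon, '+'
  expect_true(all(rel >= 0 & rel <= 3000 - 36))
  # interior per-position start counts are multinomial-uniform
  counts <- tabulate(rel + 1L, nbins = 3000L - 35L)
  binned <- colSums(matrix(counts[1:2900], nrow = 58))
  p <- suppressWarnings(stats::chisq.test(binned)$p.value)
  expect_gt(p, 0.01)
})

test_that("read counts scale with planted transcript abundance", {
  # two identical-length single-exon genes, abundances 1:9
  ann <- tag_annotation(data.frame(
    gene_id = c("g1", "g2"), contig = "chrS", strand = "+", region = "cds",
    start = c(4000L, 6500L), end = c(6000L, 8500L), biotype = "noncoding"))
  cfg <- sim_config(seed = 13, n_genes = 0, n_reads = 20000,
                    contig_length = 10000,
                    rrna_fraction = 0, mito_fraction = 0,
                    repeat_fraction = 0, background_fraction = 0)
  g <- simulate_genome_annotation(cfg)
  g$annotation <- ann
  r <- simulate_reads(cfg, g, abundance = c(g1 = 1, g2 = 9))
  n1 <- sum(r$truth$origin == "g1")
  n2 <- sum(r$truth$origin == "g2")
  expect_equal(n1 + n2, 20000L)
  sd3 <- 3 * sqrt(20000 * 0.1 * 0.9)
  expect_lt(abs(n1 - 2000), sd3)
})

test_that("stronger shearing bias shifts fragment starts towards the 5' end", {
  mean_pos <- vapply(c(0.5, 2, 5), function(b) {
    cfg <- sim_config(seed = 17, n_genes = 0, n_reads = 5000,
                      rrna_fraction = 0, mito_fraction = 0,
                      repeat_fraction = 0, background_fraction = 0,
                      include_macro_ncrna = TRUE, macro_ncrna_length = 4000,
                      fragmentation = "shearing", bias_rate = b)
    g <- simulate_genome_annotation(cfg)
    r <- simulate_reads(cfg, g)
    mac <- g$annotation[g$annotation$gene_id == "macro_ncrna", ]
    mean((r$truth$start - mac$start) / 4000)
  }, 0)
  expect_true(all(diff(mean_pos) < 0))
})

test_that("junction-spanning fragments are re-drawn, not emitted", {
  sim <- fixture_sim()
  tr <- sim$reads$truth
  ann <- sim$genome$annotation
  rl <- sim$cfg$read_length
  gene_reads <- tr[tr$origin_class == "gene", ]
  exons <- IRanges::IRanges(ann$start + 1L, ann$end)
  by_gene <- split(exons, ann$gene_id)
  for (g in unique(gene_reads$origin)) {
    er <- IRanges::reduce(by_gene[[g]])
    reads <- IRanges::IRanges(gene_reads$start[gene_reads$origin == g] + 1L,
                              width = rl)
    within <- IRanges::countOverlaps(reads, er, type = "within")
    expect_true(all(within == 1L), label = g)
  }
})
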