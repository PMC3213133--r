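mutate_read <- function(s, n_mut) {
  if (n_mut == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

test_that("align_tags reproduces the naive Hamming-scan oracle exactly", {
  set.seed(101)
  for (case in 1:4) {
    w <- sample(c(36L, 51L), 1L)
    k <- if (w == 36L) 2L else 3L
    refs <- c(cA = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""),
              cB = paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                         collapse = ""))
    # planted reads at known offsets with 0..k+1 mutations, both strands,
    # plus fully random reads
    reads <- character(0)
    for (i in 1:15) {
      cn <- sample(names(refs), 1L)
      o <- sample.int(nchar(refs[[cn]]) - w + 1L, 1L)
      s <- mutate_read(substr(refs[[cn]], o, o + w - 1L),
                       sample(0:(k + 1L), 1L))
      if (stats::runif(1) < 0.5) s <- revcomp(s)
      reads <- c(reads, s)
    }
    for (i in 1:5) {
      reads <- c(reads, paste(sample(c("A", "C", "G", "T"), w, TRUE),
                              collapse = ""))
    }
    names(reads) <- sprintf("r%02d", seq_along(reads))
    res <- align_tags(reads, refs, max_mismatches = k)
    oracle <- naive_align(reads, refs, k)
    for (id in names(reads)) {
      got <- res$placements[res$placements$read_id == id,
                            c("contig", "start", "strand", "mismatches")]
      exp <- oracle[[id]]
      got <- got[order(got$contig, got$start, got$strand), ]
      exp <- exp[order(exp$contig, exp$start, exp$strand), ]
      rownames(got) <- rownames(exp) <- NULL
      expect_equal(got, exp, label = paste("case", case, id))
    }
    expect_equal(res$n_matches,
                 vapply(oracle, nrow, 0L)[names(reads)],
                 ignore_attr = TRUE)
  }
})

test_that("duplicated segments yield exactly two placements, unique k-mers one", {
  set.seed(7)
  core <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  seg <- substr(core, 501, 600)
  genome <- c(chr = paste0(core, seg))  # segment now present twice
  unique_read <- substr(core, 101, 136)
  dup_read <- substr(seg, 11, 46)
  res <- align_tags(c(u = unique_read, d = dup_read), genome,
                    max_mismatches = 0)
  expect_equal(unname(res$n_matches["u"]), 1L)
  expect_equal(res$placements$mismatches[res$placements$read_id == "u"], 0L)
  expect_equal(unname(res$n_matches["d"]), 2L)
})

test_that("tags longer than a contig are simply unplaced there", {
  res <- align_tags(c(r = strrep("A", 50)), c(tiny = "ACGTACGT"),
                    max_mismatches = 2)
  expect_equal(unname(res$n_matches["r"]), 0L)
})

test_that("hierarchical classification assigns constructed reads to all four classes", {
  sim <- fixture_sim()
  g <- sim$genome
  seqs <- as.character(g$contigs)
  rr <- g$repeat_regions
  reads <- c(
    # 4 rRNA tags
    vapply(c(1, 101, 201, 301), function(o) substr(seqs[["rRNA"]], o, o + 35), ""),
    # 3 unique genome tags from gene bodies (away from the repeat)
    vapply(c(1000, 5000, 9000), function(o) substr(seqs[["chrS"]], o, o + 35), ""),
    # 2 repeat tags
    vapply(rr$start[1] + c(10, 60), function(o)
      substr(seqs[["chrS"]], o + 1, o + 36), ""),
    # 1 unmappable scrambled tag
    strrep("ACGT", 9))
  names(reads) <- sprintf("t%02d", 1:10)
  cl <- classify_tags(reads, g$contigs, max_mismatches = 0)
  expect_equal(unname(cl$counts$counts),
               c(4L, 3L, 2L, 1L))
  expect_equal(cl$counts$total, 10L)
  # class partition invariant
  expect_equal(sum(cl$counts$counts), length(reads))
  # read order invariance
  perm <- sample(length(reads))
  cl2 <- classify_tags(reads[perm], g$contigs, max_mismatches = 0)
  m <- match(cl$tags$read_id, cl2$tags$read_id)
  expect_equal(cl$tags$tag_class, cl2$tags$tag_class[m])
})

test_that("contamination wins over the genome in the alignment hierarchy", {
  # a read present in both the rRNA contig and the genome
  shared <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
  refs <- contig_set(
    c(chr = paste0(strrep("A", 50), shared, strrep("C", 50)),
      rrna = paste0(strrep("G", 20), shared, strrep("T", 20))),
    c(chr = "nuclear", rrna = "rrna"))
  cl <- classify_tags(c(x = shared), refs, max_mismatches = 0)
  expect_equal(cl$tags$tag_class, "rrna_mito")
  expect_equal(cl$tags$n_genome_matches, 0L)
  expect_equal(nrow(cl$unique_placements), 0L)
})

test_that("SAM ingestion classifies by flag, NH multiplicity and contig class", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:rDNA\tLN:5000",
    "u1\t0\tchr1\t101\t255\t4M\t*\t0\t0\tACGT\t*\tNH:i:1",
    "n1\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
    "m1\t0\tchr1\t201\t255\t4M\t*\t0\t0\tACGT\t*\tNH:i:2",
    "m1\t256\tchr1\t501\t255\t4M\t*\t0\t0\tACGT\t*\tNH:i:2",
    "r1\t0\trDNA\t301\t255\t4M\t*\t0\t0\tACGT\t*\tNH:i:1")
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  cmap <- c(chr1 = "nuclear", rDNA = "rrna")
  cl <- ingest_sam(f, cmap)
  cls <- stats::setNames(cl$tags$tag_class, cl$tags$read_id)
  expect_equal(cls[["u1"]], "unique")
  expect_equal(cls[["n1"]], "nomatch")
  expect_equal(cls[["m1"]], "repeat")
  expect_equal(cls[["r1"]], "rrna_mito")
  # 1-based SAM pos converted to 0-based starts
  expect_equal(cl$unique_placements$start[cl$unique_placements$read_id == "u1"],
               100L)
  # unknown contig is an error
  expect_error(ingest_sam(f, c(chr1 = "nuclear")), "class_map")
  # missing header synthesised with a warning
  f2 <- tempfile(fileext = ".sam")
  writeLines(sam[-(1:3)], f2)
  expect_warning(cl2 <- ingest_sam(f2, cmap), "header")
  expect_equal(sort(cl2$tags$read_id), sort(cl$tags$read_id))
})

test_that("classification matches simulation ground truth", {
  sim <- fixture_sim()
  cl <- classify_tags(sim$reads$reads, sim$genome$contigs)
  expected <- truth_tag_class(sim$reads$truth)
  agreement <- mean(cl$tags$tag_class == expected[cl$tags$read_id])
  expect_gte(agreement, 0.99)
  expect_equal(sum(cl$counts$counts), sim$cfg$n_reads)
})

test_that("pooled one-tailed t-test matches stats::t.test and is antisymmetric", {
  a <- c(60, 62, 64)
  b <- c(50, 51, 52)
  res <- compare_tag_fractions(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(unname(res$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  swapped <- compare_tag_fractions(b, a)
  expect_equal(swapped$p.value, 1 - res$p.value, tolerance = 1e-12)
  # identical zero-variance groups: uninformative, t = 0, p = 0.5
  same <- compare_tag_fractions(c(10, 10), c(10, 10))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 0.5)
  expect_error(compare_tag_fractions(c(1), c(2, 3)), "two replicates")
  # counts-object interface
  mk <- function(id, v) tag_class_counts(id, c(rrna_mito = v, unique = 100 - v,
                                               "repeat" = 0, nomatch = 0))
  res2 <- compare_tag_fractions(list(mk("a1", 60), mk("a2", 62), mk("a3", 64)),
                                list(mk("b1", 50), mk("b2", 51), mk("b3", 52)),
                                "rrna_mito")
  expect_equal(res2$p.value, res$p.value)
})
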