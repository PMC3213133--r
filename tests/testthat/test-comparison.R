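mk_table <- function(v, value = "rpkm") {
  df <- data.frame(gene_id = sprintf("g%04d", seq_along(v)))
  df[[value]] <- v
  structure(df, value = value, expressed_threshold = if (value == "rpkm") 3 else 90,
            class = c("expression_table", "data.frame"))
}

# lognormal expression spanning the expressed threshold, as cross-dataset
# comparisons see in practice
random_expression <- function(n = 2000, seed = 1) {
  set.seed(seed)
  stats::rlnorm(n, log(4), 1.2)
}

test_that("identical datasets need no correction and show no differential genes", {
  v <- random_expression(2000, 2)
  a <- mk_table(v)
  res <- estimate_correction_factor(a, mk_table(v))
  expect_equal(res$factor, 1)
  expect_gte(res$n_within_after, res$n_within_before)
  d <- call_differential(a, mk_table(v), factor = res$factor)
  expect_equal(sum(d$differential), 0L)
})

test_that("planted scale differences are recovered within one grid step", {
  v <- random_expression(2000, 3)
  a <- mk_table(v)
  step <- 2^0.05
  for (f in c(0.25, 0.5, 2, 3.5)) {
    b <- mk_table(v / f)  # dataset B reports 1/f of A's level
    res <- estimate_correction_factor(a, b)
    expect_lt(abs(log2(res$factor) - log2(f)), log2(step) + 1e-9,
              label = paste("factor", f))
  }
})

test_that("a differential minority does not drag the correction factor", {
  v <- random_expression(2000, 4)
  w <- v
  idx <- seq_len(200)
  w[idx] <- w[idx] * 20  # 10% of genes truly 20x up in B
  res <- estimate_correction_factor(mk_table(v), mk_table(w))
  expect_lt(abs(log2(res$factor)), 0.05 + 1e-9)
})

test_that("differential calls follow the >8x rule with threshold flooring", {
  a <- mk_table(c(32, 20, 100, 1, 40))
  b <- mk_table(c(3.5, 5, 0, 2, 4.9))
  d <- call_differential(a, b)
  rows <- stats::setNames(seq_len(nrow(d)), d$gene_id)
  # 32 vs 3.5 -> ratio > 8, differential
  expect_true(d$differential[rows[["g0001"]]])
  expect_equal(d$ratio[rows[["g0001"]]], 32 / 3.5, tolerance = 1e-12)
  # 20 vs 5 -> ratio 4, concordant
  expect_false(d$differential[rows[["g0002"]]])
  # 100 vs 0: expressed on one side only, always differential,
  # ratio against the floored threshold
  expect_true(d$differential[rows[["g0003"]]])
  expect_equal(d$status[rows[["g0003"]]], "a_only")
  expect_equal(d$ratio[rows[["g0003"]]], 100 / 3)
  # 1 vs 2: expressed in neither, excluded entirely
  expect_false("g0004" %in% d$gene_id)
  # 40 vs 4.9: ratio just above 8
  expect_true(d$differential[rows[["g0005"]]])
})

test_that("differential calls are symmetric under swapping with inverted factor", {
  v <- random_expression(300, 5)
  set.seed(6)
  w <- v * stats::rlnorm(300, 0, 1)
  a <- mk_table(v); b <- mk_table(w)
  d1 <- call_differential(a, b, factor = 2)
  d2 <- call_differential(b, a, factor = 1 / 2)
  expect_equal(sort(d1$gene_id[d1$differential]),
               sort(d2$gene_id[d2$differential]))
})

test_that("size distributions bin lengths on the comparison scheme and sum to 1", {
  ann <- tag_annotation(data.frame(
    gene_id = c("a", "b", "c"), contig = "c", strand = "+", region = "cds",
    start = c(0L, 1000L, 5000L), end = c(150L, 2950L, 17000L),
    biotype = "noncoding"))
  sd1 <- size_distribution(c("a", "b", "c"), ann)
  expect_equal(sum(sd1$freq), 1, tolerance = 1e-9)
  expect_equal(sd1$freq[sd1$bin == 1L], 1 / 3)   # 150 bp
  expect_equal(sd1$freq[sd1$bin == 19L], 1 / 3)  # 1950 bp
  expect_equal(sd1$freq[sd1$bin == 39L], 1 / 3)  # 12000 bp, last bin
  sd2 <- size_distribution(c("a", "a", "a"), ann)
  expect_equal(max(sd2$freq), 1)
  expect_warning(sd0 <- size_distribution(character(), ann), "empty")
  expect_equal(sum(sd0$count), 0L)
})

test_that("rank-sum test: exact enumeration matches oracles; identical spectra give p = 1", {
  freq_df <- function(f) {
    bins <- seq_along(f) - 1L
    structure(data.frame(bin = bins, min_bp = comparison_bin_lower(bins),
                         count = NA_integer_, freq = f),
              class = c("size_distribution", "data.frame"))
  }
  a <- freq_df(c(0.1, 0.2, 0.3))
  b <- freq_df(c(0.4, 0.5, 0.6))
  res <- suppressWarnings(wilcoxon_size_test(a, b, split = 300))
  oracle <- ranksum_enumerate(a$freq, b$freq)
  expect_equal(unname(res$below$statistic), oracle$W)
  expect_equal(res$below$p.value, oracle$p, tolerance = 1e-10)
  ref <- stats::wilcox.test(a$freq, b$freq, exact = TRUE)
  expect_equal(res$below$p.value, ref$p.value, tolerance = 1e-10)
  # symmetry
  swap <- suppressWarnings(wilcoxon_size_test(b, a, split = 300))
  expect_equal(swap$below$p.value, res$below$p.value, tolerance = 1e-12)
  # identical spectra: all mid-ranks tie, p = 1
  same <- suppressWarnings(wilcoxon_size_test(a, a, split = 300))
  expect_equal(same$below$p.value, 1)
  # a larger tie-free case against wilcox.test exact
  set.seed(8)
  x <- freq_df(stats::runif(9)); y <- freq_df(stats::runif(9))
  r2 <- suppressWarnings(wilcoxon_size_test(x, y, split = 1000))
  ref2 <- stats::wilcox.test(x$freq, y$freq, exact = TRUE)
  expect_equal(r2$below$p.value, ref2$p.value, tolerance = 1e-10)
})

test_that("the approximate branch engages above 20 bins with tie correction", {
  set.seed(9)
  f1 <- stats::runif(40); f1 <- f1 / sum(f1)
  f2 <- stats::runif(40); f2 <- f2 / sum(f2)
  bins <- 0:39
  d1 <- structure(data.frame(bin = bins, min_bp = comparison_bin_lower(bins),
                             count = NA_integer_, freq = f1),
                  class = c("size_distribution", "data.frame"))
  d2 <- structure(data.frame(bin = bins, min_bp = comparison_bin_lower(bins),
                             count = NA_integer_, freq = f2),
                  class = c("size_distribution", "data.frame"))
  res <- wilcoxon_size_test(d1, d2)
  expect_match(res$below$method, "normal approximation")
  ref <- stats::wilcox.test(f1[bins < 20], f2[bins < 20],
                            exact = FALSE, correct = FALSE)
  expect_equal(res$below$p.value, ref$p.value, tolerance = 1e-10)
  # all-zero side degenerates with a warning
  dz <- d1; dz$freq[] <- 0
  w <- testthat::capture_warnings(rz <- wilcoxon_size_test(dz, dz))
  expect_match(w, "all-zero", all = TRUE)
  expect_true(is.nan(rz$below$p.value))
})

test_that("under-detection of small genes surfaces in the differential size spectra", {
  # dataset B systematically misses small genes (< 2 kb): the B-deficient
  # (higher in A) differential set should be enriched for small cDNAs
  set.seed(10)
  n <- 200
  lens <- as.integer(round(stats::rlnorm(n, log(1500), 0.8)))
  lens <- pmin(pmax(lens, 200L), 15000L)
  starts <- cumsum(c(0L, head(lens, -1L) + 100L))
  ann <- tag_annotation(data.frame(
    gene_id = sprintf("g%04d", 1:n), contig = "c", strand = "+",
    region = "cds", start = starts, end = starts + lens,
    biotype = "noncoding"))
  v <- stats::rlnorm(n, log(30), 1)
  w <- v
  small <- lens < 2000L
  drop <- small & stats::runif(n) < 0.4
  w[drop] <- 0.1  # silenced in B
  d <- call_differential(mk_table(v), mk_table(w))
  sd_a <- size_distribution(d, ann, higher_in = "A")
  small_share <- sum(sd_a$freq[sd_a$min_bp < 2000])
  all_dist <- size_distribution(sprintf("g%04d", 1:n), ann)
  expect_gt(small_share, sum(all_dist$freq[all_dist$min_bp < 2000]))
  wt <- wilcoxon_size_test(sd_a, all_dist)
  expect_true(is.finite(wt$below$p.value))
})
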