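merged_values <- function(tableA, tableB, value = NULL) {
  va <- expr_values(tableA, value)
  vb <- expr_values(tableB, value)
  shared <- intersect(names(va), names(vb))
  if (!length(shared)) stop("tables share no genes")
  list(gene_id = shared, a = unname(va[shared]), b = unname(vb[shared]))
}

default_threshold <- function(table, value = NULL) {
  v <- value %||% attr(table, "value") %||% "rpkm"
  thr <- attr(table, "expressed_threshold")
  if (!is.null(thr)) return(thr)
  if (v == "ppkm") 90 else 3
}

# fold-difference histogram: the "0" bin holds genes expressed in neither
# dataset; both-expressed genes fall into log2 ratio bins; genes expressed on
# one side only go to the top ("single-sided") bin
fold_histogram <- function(a, b, thr) {
  breaks <- c(1, 2, 4, 8, 16, 32, 64, 128, Inf)
  labs <- c(paste0("(", breaks[-length(breaks)][-8], ",",
                   breaks[-1][-8], "]"), ">128")
  ea <- a > thr; eb <- b > thr
  counts <- stats::setNames(integer(length(labs) + 2L),
                            c("0", labs, "single-sided"))
  counts[["0"]] <- sum(!ea & !eb)
  counts[["single-sided"]] <- sum(xor(ea, eb))
  both <- ea & eb
  if (any(both)) {
    r <- pmax(a[both], b[both]) / pmin(a[both], b[both])
    idx <- pmin(findInterval(r, breaks, left.open = TRUE), length(labs))
    # ratio exactly 1 falls in the first ratio bin
    idx[r <= 1] <- 1L
    tb <- table(idx)
    counts[labs[as.integer(names(tb))]] <-
      counts[labs[as.integer(names(tb))]] + as.integer(tb)
  }
  counts
}

#' Estimate a cross-dataset correction factor
#'
#' Scales dataset B's expression values by each candidate factor in turn and
#' counts the genes that are expressed in both datasets (re-testing the
#' expressed threshold after scaling) with a fold difference below
#' `ratio_threshold`. The factor maximising this concordant count is returned;
#' ties are broken towards the factor nearest 1. The objective is a step
#' function of the factor, so a log2-spaced grid search is exact up to the
#' grid resolution.
#'
#' @param tableA,tableB `expression_table` objects on a shared gene universe
#'   (same annotation).
#' @param factor_grid Candidate multipliers for B (must contain 1).
#' @param ratio_threshold Fold difference above which genes count as
#'   differential (default 8).
#' @param expressed_threshold Expression cutoff; defaults to the tables' own
#'   (RPKM 3 / PPKM 90).
#' @param value Which column to use (`"rpkm"`/`"ppkm"`).
#' @return A `correction_result` list: `factor`, `n_within_before`,
#'   `n_within_after`, `histogram` (fold-difference bins before/after, the
#'   `0` bin holding genes expressed in neither dataset), and `grid` (the
#'   objective over the whole grid).
#' @export
estimate_correction_factor <- function(tableA, tableB,
                                       factor_grid = 2^seq(-4, 4, by = 0.05),
                                       ratio_threshold = 8,
                                       expressed_threshold = NULL,
                                       value = NULL) {
  stopifnot(ratio_threshold > 1)
  if (!any(abs(log2(factor_grid)) < 1e-9)) {
    stop("factor_grid must contain 1.0")
  }
  m <- merged_values(tableA, tableB, value)
  thr <- expressed_threshold %||% default_threshold(tableA, value)
  # objective: genes in the fold-difference bins below ratio_threshold.
  # The "0" bin (expressed in neither dataset) is one of those bins, so
  # concordantly silent genes count too; genes that scaling pushes into
  # single-sided expression drop out, which is what penalises over- and
  # under-correction.
  n_within <- vapply(factor_grid, function(f) {
    b2 <- f * m$b
    ea <- m$a > thr; eb <- b2 > thr
    both <- ea & eb
    sum(both & pmax(m$a, b2) / pmin(m$a, b2) < ratio_threshold) +
      sum(!ea & !eb)
  }, 0L)
  if (all(vapply(factor_grid, function(f) {
    sum(m$a > thr & f * m$b > thr)
  }, 0L) == 0L)) {
    stop("no gene is expressed in both datasets at any candidate factor")
  }
  # the objective is a step function, so maxima come in plateaus; take the
  # centre of the tied run (the run nearest 1 when several runs tie), which
  # bounds the recovery error by one grid step
  best <- which(n_within == max(n_within))
  runs <- split(best, cumsum(c(1L, diff(best) != 1L)))
  centres <- vapply(runs, function(r) r[ceiling(length(r) / 2)], 0L)
  best <- centres[which.min(abs(log2(factor_grid[centres])))]
  f <- factor_grid[best]
  at1 <- which.min(abs(log2(factor_grid)))
  hist_before <- fold_histogram(m$a, m$b, thr)
  hist_after <- fold_histogram(m$a, f * m$b, thr)
  structure(list(
    factor = f,
    n_within_before = n_within[at1],
    n_within_after = n_within[best],
    histogram = data.frame(bin = names(hist_before),
                           before = as.integer(hist_before),
                           after = as.integer(hist_after),
                           row.names = NULL),
    grid = data.frame(factor = factor_grid, n_within = n_within),
    ratio_threshold = ratio_threshold,
    expressed_threshold = thr), class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("Correction factor (applied to dataset B): ",
      format(x$factor, digits = 4), "\n",
      "genes within ", x$ratio_threshold, "x: ", x$n_within_before,
      " before, ", x$n_within_after, " after\n", sep = "")
  invisible(x)
}

#' Call differentially detected genes between two datasets
#'
#' After applying the correction factor to dataset B, genes expressed in at
#' least one dataset are tested: for genes expressed in both, the ratio is
#' max/min of the two values; a gene expressed in exactly one dataset is
#' differential outright (its ratio is reported against the not-expressed
#' side floored at the expressed threshold). Genes expressed in neither
#' dataset are excluded.
#'
#' @param tableA,tableB `expression_table` objects on a shared gene universe.
#' @param factor Correction multiplier for B (from
#'   [estimate_correction_factor()]; default 1).
#' @param ratio_threshold Differential cutoff (default 8, i.e. > 8-fold).
#' @param expressed_threshold Expression cutoff; defaults to the tables' own.
#' @param value Which column to use.
#' @return A `differential_set` data frame: `gene_id`, `value_a`, `value_b`
#'   (corrected), `status` (`both`/`a_only`/`b_only`), `ratio`,
#'   `differential`, `higher_in` (`A`/`B`).
#' @export
call_differential <- function(tableA, tableB, factor = 1,
                              ratio_threshold = 8,
                              expressed_threshold = NULL, value = NULL) {
  m <- merged_values(tableA, tableB, value)
  thr <- expressed_threshold %||% default_threshold(tableA, value)
  b2 <- factor * m$b
  # expression status is judged on each dataset's own, uncorrected scale;
  # the correction factor only makes the two scales comparable for the ratio.
  # This keeps the call symmetric under swapping tables with 1/factor.
  ea <- m$a > thr; eb <- m$b > thr
  keep <- ea | eb
  a <- m$a[keep]; b <- b2[keep]
  ea <- ea[keep]; eb <- eb[keep]
  status <- ifelse(ea & eb, "both", ifelse(ea, "a_only", "b_only"))
  # only the not-expressed side is floored at the threshold for the ratio
  af <- ifelse(ea, a, pmax(a, thr))
  bf <- ifelse(eb, b, pmax(b, thr))
  ratio <- pmax(af, bf) / pmin(af, bf)
  differential <- (status == "both" & ratio > ratio_threshold) |
    status != "both"
  higher_in <- ifelse(af >= bf, "A", "B")
  structure(data.frame(gene_id = m$gene_id[keep], value_a = a, value_b = b,
                       status = status, ratio = ratio,
                       differential = differential, higher_in = higher_in,
                       row.names = NULL),
            factor = factor, ratio_threshold = ratio_threshold,
            expressed_threshold = thr,
            class = c("differential_set", "data.frame"))
}

#' cDNA size distribution of a gene set
#'
#' Bins gene cDNA lengths (RefSeq-style exonic length including UTRs) into
#' 100 bp bins below 2 kb and 500 bp bins above, with all cDNAs larger than
#' 11.5 kb grouped into the last bin, and reports the count in each bin
#' relative to the total number of genes in the set.
#'
#' @param gene_ids Character vector of genes (e.g. the differential genes
#'   higher in one dataset), or a `differential_set` from which the
#'   differential genes are taken.
#' @param ann A [tag_annotation()] providing the cDNA lengths.
#' @param higher_in When `gene_ids` is a `differential_set`, restrict to
#'   genes higher in `"A"` or `"B"` (default: all differential genes).
#' @return A `size_distribution` data frame over all bins: `bin`, `min_bp`,
#'   `count`, `freq` (relative frequencies summing to 1). An empty gene set
#'   yields zero counts with a warning.
#' @export
size_distribution <- function(gene_ids, ann, higher_in = NULL) {
  if (inherits(gene_ids, "differential_set")) {
    d <- gene_ids[gene_ids$differential, ]
    if (!is.null(higher_in)) d <- d[d$higher_in == higher_in, ]
    gene_ids <- d$gene_id
  }
  bins <- 0:comparison_last_bin()
  counts <- stats::setNames(integer(length(bins)), bins)
  if (!length(gene_ids)) {
    warning("empty gene set; size distribution is all zero")
  } else {
    lens <- cdna_length(ann, include_utrs = TRUE)
    missing <- setdiff(gene_ids, names(lens))
    if (length(missing)) stop("genes absent from annotation: ",
                              paste(missing, collapse = ", "))
    b <- size_class(lens[gene_ids], "comparison")
    tb <- table(b)
    counts[names(tb)] <- as.integer(tb)
  }
  n <- sum(counts)
  structure(data.frame(bin = bins, min_bp = comparison_bin_lower(bins),
                       count = as.integer(counts),
                       freq = if (n > 0) counts / n else counts * 0,
                       row.names = NULL),
            n_genes = n, class = c("size_distribution", "data.frame"))
}

# Wilcoxon rank-sum with mid-ranks: exact by enumeration when the combined
# sample size is small, tie-corrected normal approximation otherwise.
rank_sum_test <- function(x, y, exact_limit = 20L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (all(c(x, y) == 0)) {
    warning("all-zero frequencies on one side of the split")
    return(list(statistic = NaN, p.value = NaN, method = "degenerate"))
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    null_w <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p <- 2 * min(mean(null_w <= W + eps), mean(null_w >= W - eps))
    return(list(statistic = c(W = W), p.value = min(1, p),
                method = "exact enumeration"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = c(W = W), p.value = 1,
                method = "normal approximation (all ties)"))
  }
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = c(W = W), p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation with tie correction")
}

#' Wilcoxon rank-sum comparison of two cDNA size spectra
#'
#' Compares the relative bin frequencies of two size distributions separately
#' below and above a split point (default 2 kb), testing whether one dataset's
#' differential genes are enriched for small (or large) cDNAs. The null
#' distribution is enumerated exactly when the combined number of bins is at
#' most 20; otherwise a normal approximation with mid-rank tie correction is
#' used. Two-sided p-values; identical spectra give p = 1.
#'
#' @param distA,distB `size_distribution` objects on the same binning scheme.
#' @param split Split point in bp (default 2000).
#' @return A `size_test` list with `below` and `above` components, each
#'   carrying `statistic` (rank sum of `distA`'s bins), `p.value` and
#'   `method`.
#' @export
wilcoxon_size_test <- function(distA, distB, split = 2000) {
  stopifnot(inherits(distA, "size_distribution"),
            inherits(distB, "size_distribution"))
  if (nrow(distA) != nrow(distB) || any(distA$bin != distB$bin)) {
    stop("distributions must share the binning scheme")
  }
  below <- distA$min_bp < split
  res <- list(
    below = rank_sum_test(distA$freq[below], distB$freq[below]),
    above = rank_sum_test(distA$freq[!below], distB$freq[!below]))
  structure(c(res, list(split = split)), class = "size_test")
}

#' @export
print.size_test <- function(x, ...) {
  cat("Wilcoxon rank-sum on relative size-bin frequencies (split ",
      x$split, " bp)\n", sep = "")
  for (side in c("below", "above")) {
    cat(sprintf("  %-5s split: W = %s, p = %s  [%s]\n", side,
                format(x[[side]]$statistic), format(x[[side]]$p.value,
                                                    digits = 4),
                x[[side]]$method))
  }
  invisible(x)
}
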