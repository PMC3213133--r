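# Independent reference implementations used as oracles. These deliberately
# take the most literal route (exhaustive scans, full enumeration, closed
# forms) and stay independent of the package's optimised code paths.

# Literal Hamming scan: for every contig, every offset, both strands, count
# mismatches position by position and report placements with <= k.
naive_align_one <- function(read, refs, k) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read)))
  out <- list()
  for (cn in names(refs)) {
    s <- strsplit(refs[[cn]], "", fixed = TRUE)[[1L]]
    L <- length(s)
    for (orient in c("+", "-")) {
      p <- strsplit(if (orient == "+") read else rc, "", fixed = TRUE)[[1L]]
      w <- length(p)
      if (L < w) next
      mism <- integer(L - w + 1L)
      for (j in seq_len(w)) {
        mism <- mism + (s[j:(L - w + j)] != p[j])
      }
      hit <- which(mism <= k)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          contig = cn, start = hit - 1L, strand = orient,
          mismatches = mism[hit])
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(),
               strand = character(), mismatches = integer())
}

naive_align <- function(reads, refs, k) {
  refs_chr <- stats::setNames(as.character(refs), names(refs))
  res <- lapply(as.character(reads), naive_align_one, refs = refs_chr, k = k)
  names(res) <- names(reads)
  res
}

# Closed-form Pearson correlation from raw sums
pearson_closed_form <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Exact rank-sum null distribution by bitmask enumeration (independent of the
# package's combn-based path)
ranksum_enumerate <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  null_w <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) == n1) null_w <- c(null_w, sum(r[bits == 1L]))
  }
  eps <- 1e-9
  p <- 2 * min(mean(null_w <= W + eps), mean(null_w >= W - eps))
  list(W = W, p = min(1, p))
}

# random placement table for pileup/expression tests
random_placements <- function(n, contig, contig_len, width = 36L) {
  data.frame(read_id = sprintf("r%05d", seq_len(n)),
             contig = contig,
             start = sample.int(contig_len - width + 1L, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             mismatches = 0L, width = width)
}
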