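#' Sequencing-depth saturation analysis
#'
#' At each requested depth, random tag subsets are drawn without replacement
#' and RPKM recomputed with the subsample size as denominator. A gene's RPKM
#' has saturated at that depth when it lies within `tolerance` (default 5%)
#' of its full-depth RPKM. The percentage of saturated genes is reported per
#' expression group (groups defined by ranges of full-depth RPKM), with the
#' minimum and maximum over replicates as error bars. A curve reaching its
#' plateau before the final tag count indicates the group was sequenced
#' exhaustively.
#'
#' @param placements Placement data frame of unique tags.
#' @param ann A [tag_annotation()] (optionally restricted to the gene set of
#'   interest, e.g. coding or noncoding genes).
#' @param depths Integer vector of subsample sizes; defaults to ten evenly
#'   spaced depths up to the full tag count.
#' @param groups Named list of `c(lower, upper)` full-depth RPKM ranges
#'   (lower exclusive, upper inclusive). The defaults (3,10], (10,100] and
#'   >100 are package defaults, configurable.
#' @param n_replicates Random subsets per depth (default 10).
#' @param tolerance Relative tolerance for "saturated" (default 0.05).
#' @param seed Seed for the subsampling; the analysis is deterministic
#'   given it.
#' @return A `saturation_curve` data frame: `depth`, `group`, `n_genes`,
#'   `mean`, `min`, `max` (percent saturated). Empty groups yield `NaN` with
#'   a warning (small gene numbers also produce large error bars).
#' @export
saturation_analysis <- function(placements, ann, depths = NULL,
                                groups = list("(3,10]" = c(3, 10),
                                              "(10,100]" = c(10, 100),
                                              ">100" = c(100, Inf)),
                                n_replicates = 10L, tolerance = 0.05,
                                seed = 1L) {
  n <- nrow(placements)
  if (n < 1L) stop("no placements")
  if (is.null(depths)) depths <- unique(pmax(1L, round(n * seq(0.1, 1, 0.1))))
  if (any(depths < 1L | depths > n)) stop("depths must lie in [1, total tags]")
  final <- compute_rpkm(placements, ann, total_tags = n)
  grl <- exon_ranges(ann)
  reads <- placements_granges(placements)
  ov <- GenomicRanges::findOverlaps(grl, reads, ignore.strand = TRUE)
  hit_by_gene <- split(S4Vectors::subjectHits(ov),
                       factor(S4Vectors::queryHits(ov),
                              levels = seq_along(grl)))
  len <- as.numeric(final$exon_length)
  rpkm_final <- final$rpkm
  member <- lapply(groups, function(g) {
    which(rpkm_final > g[1L] & rpkm_final <= g[2L])
  })
  empty <- vapply(member, length, 0L) == 0L
  if (any(empty)) {
    warning("group(s) with zero genes: ",
            paste(names(groups)[empty], collapse = ", "))
  }
  set.seed(seed)
  rows <- list()
  inc <- logical(n)
  for (d in depths) {
    pct <- matrix(NA_real_, n_replicates, length(groups))
    for (r in seq_len(n_replicates)) {
      inc[] <- FALSE
      inc[sample.int(n, d)] <- TRUE
      counts <- vapply(hit_by_gene, function(ix) sum(inc[ix]), 0)
      rpkm_sub <- 1e9 * counts / (len * d)
      within <- abs(rpkm_sub - rpkm_final) <= tolerance * rpkm_final
      for (gi in seq_along(groups)) {
        if (!empty[gi]) pct[r, gi] <- 100 * mean(within[member[[gi]]])
      }
    }
    for (gi in seq_along(groups)) {
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, group = names(groups)[gi],
        n_genes = length(member[[gi]]),
        mean = mean(pct[, gi]), min = suppressWarnings(min(pct[, gi])),
        max = suppressWarnings(max(pct[, gi])))
    }
  }
  out <- do.call(rbind, rows)
  out$min[is.na(out$mean)] <- NaN
  out$max[is.na(out$mean)] <- NaN
  out$mean[is.na(out$mean)] <- NaN
  structure(out, n_replicates = n_replicates, tolerance = tolerance,
            total_tags = n, class = c("saturation_curve", "data.frame"))
}

#' @export
plot.saturation_curve <- function(x, ...) {
  grp <- unique(x$group)
  cols <- seq_along(grp)
  graphics::plot(range(x$depth), c(0, 100), type = "n",
                 xlab = "tags sampled", ylab = "% genes within tolerance", ...)
  for (i in seq_along(grp)) {
    xi <- x[x$group == grp[i], ]
    graphics::lines(xi$depth, xi$mean, col = cols[i], type = "b", pch = 20)
    graphics::arrows(xi$depth, xi$min, xi$depth, xi$max, angle = 90,
                     code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("bottomright", legend = grp, col = cols, lty = 1)
  invisible(x)
}

#' Gene-body coverage profiles by region and size class
#'
#' For every expressed protein-coding gene, the exonic sequence of each region
#' (5'UTR, CDS, 3'UTR) is laid out in 5' to 3' transcript orientation
#' (strand-aware), divided into 100 equal bins, and the per-base pileup is
#' accumulated per bin and normalised for the tag size and the total number of
#' tags. Profiles are summed over the genes of each cDNA size class (small
#' < 1 kb, medium 1-8 kb, large > 8 kb), UTR bins are averaged 10-to-1 into 10
#' display bins, and each size class is plotted relative to its highest bin
#' (global maximum over UTR5 + CDS + UTR3 of the class equals 1).
#'
#' @param placements Placement data frame of unique tags.
#' @param ann A [tag_annotation()].
#' @param expressed Character vector of gene ids to profile (typically
#'   coding genes with RPKM > 3, from [compute_rpkm()]).
#' @param contig_lengths Named contig lengths or a [contig_set()].
#' @param total_tags Total uniquely mapped tags (defaults to
#'   `nrow(placements)`).
#' @param n_bins Body bins per region before UTR averaging (default 100).
#' @param utr_display_bins Display bins for UTRs (default 10).
#' @return A `coverage_profiles` data frame: `size_class`, `region`, `bin`,
#'   `value`, plus `n_genes` per class as an attribute. Genes lacking a UTR
#'   are excluded from that region's profile; size classes without expressed
#'   genes produce a warning and no rows.
#' @export
coverage_profile <- function(placements, ann, expressed, contig_lengths,
                             total_tags = nrow(placements), n_bins = 100L,
                             utr_display_bins = 10L) {
  pileup <- compute_pileup(placements, contig_lengths)
  read_length <- if (nrow(placements)) round(mean(placements$width)) else 1
  ids <- intersect(unique(ann$gene_id), expressed)
  lens <- cdna_length(ann, include_utrs = TRUE)
  cls <- size_class(lens[ids], "coverage")
  regions <- c("utr5", "cds", "utr3")
  rows <- list()
  n_genes <- stats::setNames(integer(3), levels(cls))
  for (sc in levels(cls)) {
    gset <- ids[cls == sc]
    n_genes[sc] <- length(gset)
    if (!length(gset)) {
      warning("no expressed genes in size class '", sc, "'")
      next
    }
    acc <- list(utr5 = numeric(n_bins), cds = numeric(n_bins),
                utr3 = numeric(n_bins))
    for (g in gset) {
      e <- ann[ann$gene_id == g, ]
      strand <- e$strand[1L]
      cn <- e$contig[1L]
      for (rg in regions) {
        er <- e[e$region == rg, , drop = FALSE]
        if (!nrow(er)) next
        er <- er[order(er$start), , drop = FALSE]
        v <- as.numeric(pileup[[cn]][IRanges::IRanges(er$start + 1L, er$end)])
        if (strand == "-") v <- rev(v)
        L <- length(v)
        # bin b covers positions ceil((b-1)L/100)+1 .. ceil(bL/100)
        cs <- cumsum(v)
        idx <- ceiling(seq_len(n_bins) * L / n_bins)
        acc[[rg]] <- acc[[rg]] + diff(c(0, cs[idx]))
      }
    }
    norm <- read_length * total_tags
    for (rg in regions) acc[[rg]] <- acc[[rg]] / norm
    for (rg in c("utr5", "utr3")) {
      m <- matrix(acc[[rg]], nrow = n_bins %/% utr_display_bins)
      acc[[rg]] <- colMeans(m)
    }
    peak <- max(unlist(acc))
    if (peak == 0) peak <- 1
    for (rg in regions) {
      rows[[length(rows) + 1L]] <- data.frame(
        size_class = sc, region = rg, bin = seq_along(acc[[rg]]),
        value = acc[[rg]] / peak)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size_class = character(), region = character(),
               bin = integer(), value = numeric())
  structure(out, n_genes = n_genes, read_length = read_length,
            total_tags = total_tags,
            class = c("coverage_profiles", "data.frame"))
}

#' @export
plot.coverage_profiles <- function(x, size_class = NULL, ...) {
  scs <- unique(x$size_class)
  if (!is.null(size_class)) scs <- intersect(scs, size_class)
  op <- graphics::par(mfrow = c(length(scs), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (sc in scs) {
    xi <- x[x$size_class == sc, ]
    u5 <- xi$value[xi$region == "utr5"]
    cds <- xi$value[xi$region == "cds"]
    u3 <- xi$value[xi$region == "utr3"]
    vals <- c(u5, cds, u3)
    graphics::plot(seq_along(vals), vals, type = "l", ylim = c(0, 1),
                   xlab = "", ylab = "relative coverage", main = sc, ...)
    graphics::abline(v = c(length(u5), length(u5) + length(cds)) + 0.5,
                     lty = 3)
  }
  invisible(x)
}
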