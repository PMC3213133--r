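placements_granges <- function(placements) {
  GenomicRanges::GRanges(placements$contig,
                         IRanges::IRanges(placements$start + 1L,
                                          width = placements$width))
}

#' Per-base pileup of uniquely mapping tags
#'
#' The pileup is the number of tags covering each base of each contig. Only
#' unique-class tags should contribute; repeat tags are excluded from all
#' quantification.
#'
#' @param placements Placement data frame of unique tags (`contig`, 0-based
#'   `start`, `width`), e.g. `classify_tags(...)$unique_placements`.
#' @param contig_lengths Named integer vector of contig lengths, or a
#'   [contig_set()] from which lengths are taken.
#' @return An [IRanges::RleList], one run-length encoded coverage vector per
#'   contig. Total mass equals the summed tag widths.
#' @export
compute_pileup <- function(placements, contig_lengths) {
  if (!is.numeric(contig_lengths)) {
    contig_lengths <- stats::setNames(S4Vectors::width(contig_lengths),
                                      names(contig_lengths))
  }
  if (nrow(placements)) {
    if (any(!placements$contig %in% names(contig_lengths))) {
      stop("placements on unknown contig")
    }
    if (any(placements$start < 0L) ||
        any(placements$start + placements$width >
            contig_lengths[placements$contig])) {
      stop("tag placement exceeds contig bounds")
    }
  }
  out <- lapply(names(contig_lengths), function(cn) {
    p <- placements[placements$contig == cn, , drop = FALSE]
    IRanges::coverage(IRanges::IRanges(p$start + 1L, width = p$width),
                      width = contig_lengths[[cn]])
  })
  methods::as(stats::setNames(out, names(contig_lengths)), "SimpleRleList")
}

#' RPKM over exon models
#'
#' A tag counts for a gene when it overlaps the gene's exon union (UTRs plus
#' CDS) by at least one base; a tag overlapping two genes counts for both.
#' RPKM = 1e9 * exon_read_count / (exonic length in bp * total_tags), with
#' `total_tags` the number of uniquely mapped genomic tags in the sample.
#' Strand is ignored (single-end libraries without strand information).
#'
#' @param placements Placement data frame of unique tags.
#' @param ann A [tag_annotation()].
#' @param total_tags Denominator: uniquely mapped tags in the sample; must be
#'   positive. Defaults to `nrow(placements)`.
#' @param expressed_threshold A gene is called expressed when its RPKM exceeds
#'   this (default 3).
#' @return An `expression_table` data frame: `gene_id`, `exon_length`,
#'   `exon_read_count`, `rpkm`, `expressed`.
#' @export
compute_rpkm <- function(placements, ann, total_tags = nrow(placements),
                         expressed_threshold = 3) {
  if (total_tags <= 0) stop("total_tags must be positive")
  len <- cdna_length(ann, include_utrs = TRUE)
  if (any(len == 0L)) stop("zero-length exon model")
  grl <- exon_ranges(ann)
  counts <- if (nrow(placements)) {
    GenomicRanges::countOverlaps(grl, placements_granges(placements),
                                 ignore.strand = TRUE)
  } else stats::setNames(integer(length(grl)), names(grl))
  len <- len[names(grl)]
  rpkm <- 1e9 * as.numeric(counts) / (as.numeric(len) * total_tags)
  structure(data.frame(gene_id = names(grl),
                       exon_length = as.integer(len),
                       exon_read_count = as.integer(counts),
                       rpkm = rpkm,
                       expressed = rpkm > expressed_threshold,
                       row.names = NULL),
            total_tags = total_tags, value = "rpkm",
            expressed_threshold = expressed_threshold,
            class = c("expression_table", "data.frame"))
}

#' PPKM over exon models
#'
#' As RPKM, but instead of counting tags, the per-base pileup is summed over
#' the exonic bases of the gene:
#' PPKM = 1e9 * pileup_sum / (exonic length * total_tags). When every counted
#' tag lies fully inside the exon model, PPKM equals read_length * RPKM; tags
#' partially overlapping the exon boundaries lower the ratio (empirically a
#' factor near 30 for 36 bp tags on real exon models).
#'
#' @param pileup An [compute_pileup()] result.
#' @param ann A [tag_annotation()].
#' @param total_tags Denominator as in [compute_rpkm()].
#' @param expressed_threshold Expression call threshold on PPKM (default 90,
#'   the PPKM equivalent of RPKM 3 under the factor-30 conversion).
#' @return An `expression_table` data frame: `gene_id`, `exon_length`,
#'   `pileup_sum`, `ppkm`, `expressed`.
#' @export
compute_ppkm <- function(pileup, ann, total_tags, expressed_threshold = 90) {
  if (total_tags <= 0) stop("total_tags must be positive")
  len <- cdna_length(ann, include_utrs = TRUE)
  if (any(len == 0L)) stop("zero-length exon model")
  ids <- unique(ann$gene_id)
  psum <- numeric(length(ids))
  for (i in seq_along(ids)) {
    e <- ann[ann$gene_id == ids[i], ]
    cn <- e$contig[1L]
    if (!cn %in% names(pileup)) stop("contig ", cn, " missing from pileup")
    v <- IRanges::Views(pileup[[cn]], IRanges::IRanges(e$start + 1L, e$end))
    psum[i] <- sum(as.numeric(sum(v)))
  }
  len <- len[ids]
  ppkm <- 1e9 * psum / (as.numeric(len) * total_tags)
  structure(data.frame(gene_id = ids, exon_length = as.integer(len),
                       pileup_sum = psum, ppkm = ppkm,
                       expressed = ppkm > expressed_threshold,
                       row.names = NULL),
            total_tags = total_tags, value = "ppkm",
            expressed_threshold = expressed_threshold,
            class = c("expression_table", "data.frame"))
}

#' @export
print.expression_table <- function(x, n = 10L, ...) {
  cat("Expression table (", attr(x, "value"), ", ", nrow(x), " genes, ",
      attr(x, "total_tags"), " total tags, expressed > ",
      attr(x, "expressed_threshold"), ")\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more genes\n", sep = "")
  invisible(x)
}

expr_values <- function(table, value = NULL) {
  value <- value %||% attr(table, "value") %||% "rpkm"
  if (!value %in% names(table)) stop("table carries no '", value, "' column")
  stats::setNames(table[[value]], table$gene_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-sample scatter on log-transformed expression values
#'
#' Values are adjusted by +1 and log10-transformed before computing Pearson's
#' correlation over the shared gene universe (a perfect correlation is R = 1).
#'
#' @param tableA,tableB `expression_table` objects sharing a gene universe.
#' @param value Which column to correlate (`"rpkm"` or `"ppkm"`); defaults to
#'   the tables' own value type.
#' @return A `log_scatter` list: `r` (Pearson correlation; `NaN` with a
#'   warning when one side has zero variance) and `data` (per-gene transformed
#'   pairs).
#' @export
pearson_log_scatter <- function(tableA, tableB, value = NULL) {
  va <- expr_values(tableA, value)
  vb <- expr_values(tableB, value)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 2L) stop("need at least two shared genes")
  x <- log10(va[shared] + 1)
  y <- log10(vb[shared] + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance on one axis; correlation undefined")
    r <- NaN
  } else {
    r <- stats::cor(x, y)
  }
  structure(list(r = r,
                 data = data.frame(gene_id = shared, x = unname(x),
                                   y = unname(y))),
            class = "log_scatter")
}

#' @export
print.log_scatter <- function(x, ...) {
  cat("log10(value + 1) scatter over ", nrow(x$data), " genes; Pearson R = ",
      format(x$r, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.log_scatter <- function(x, ...) {
  graphics::plot(x$data$x, x$data$y,
                 xlab = "log10(value + 1), sample A",
                 ylab = "log10(value + 1), sample B",
                 main = sprintf("R = %.3f", x$r), pch = 20, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write a pileup track as bedGraph
#'
#' @param pileup An [compute_pileup()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(pileup, path) {
  gr <- methods::as(pileup, "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  gr <- gr[S4Vectors::mcols(gr)$score > 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write an expression table as TSV
#' @param table An `expression_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
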