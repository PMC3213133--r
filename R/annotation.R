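#' Transcript annotation tables
#'
#' The annotation container is a data frame with one row per exon interval and
#' columns `gene_id`, `contig`, `strand` (`+`/`-`), `region` (`utr5`, `cds`,
#' `utr3`), `start`, `end` (0-based, half-open genomic coordinates) and
#' `biotype` (`coding`/`noncoding`). Coding transcripts carry their coding
#' exons under `cds` and untranslated exon pieces under `utr5`/`utr3`;
#' noncoding transcripts carry all exons under `cds` with no UTR rows.
#' Each `gene_id` is one transcript; alternative isoforms are distinct ids.
#'
#' @param exons Data frame as described above.
#' @param provenance Free-text origin note, kept as an attribute.
#' @return A validated `tag_annotation` data frame.
#' @export
tag_annotation <- function(exons, provenance = "") {
  req <- c("gene_id", "contig", "strand", "region", "start", "end", "biotype")
  if (!all(req %in% names(exons))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  }
  exons <- as.data.frame(exons)[req]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(!exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(!exons$region %in% c("utr5", "cds", "utr3"))) {
    stop("region must be utr5, cds or utr3")
  }
  if (any(!exons$biotype %in% c("coding", "noncoding"))) {
    stop("biotype must be coding or noncoding")
  }
  if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
    stop("exon intervals must satisfy 0 <= start < end")
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    if (length(unique(e$contig)) != 1L || length(unique(e$strand)) != 1L ||
        length(unique(e$biotype)) != 1L) {
      stop("gene ", g, ": contig, strand and biotype must be constant")
    }
    if (anyDuplicated(e[c("region", "start")])) stop("gene ", g, ": duplicated exons")
    for (r in unique(e$region)) {
      er <- e[e$region == r, ]
      if (nrow(er) > 1L && any(er$start[-1L] < er$end[-nrow(er)])) {
        stop("gene ", g, ": overlapping ", r, " exons")
      }
    }
    has_cds <- any(e$region == "cds")
    if (e$biotype[1L] == "coding" && !has_cds) stop("gene ", g, ": coding without cds")
    if (e$biotype[1L] == "noncoding" && any(e$region != "cds")) {
      stop("gene ", g, ": noncoding genes must carry all exons as cds")
    }
  }
  structure(exons, provenance = provenance,
            class = c("tag_annotation", "data.frame"))
}

#' Summarise an annotation at the gene level
#'
#' @param ann A `tag_annotation`.
#' @return Data frame with one row per transcript: `gene_id`, `contig`,
#'   `strand`, `biotype`, `cdna_length` (all exonic bases incl. UTRs).
#' @export
gene_table <- function(ann) {
  len <- cdna_length(ann, include_utrs = TRUE)
  first <- ann[!duplicated(ann$gene_id), c("gene_id", "contig", "strand", "biotype")]
  first <- first[match(names(len), first$gene_id), ]
  rownames(first) <- NULL
  first$cdna_length <- unname(len)
  first
}

bed12_prescan <- function(lines) {
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      stop("BED12 parse error at line ", i, ": expected 12 fields, found ",
           length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(2, 3, 7, 8, 10)]))
    if (anyNA(num)) stop("BED12 parse error at line ", i, ": non-numeric coordinate")
    chromStart <- num[1]; chromEnd <- num[2]
    thickStart <- num[3]; thickEnd <- num[4]; blockCount <- num[5]
    if (thickStart > thickEnd) {
      stop("BED12 parse error at line ", i, ": thickStart > thickEnd")
    }
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1L]]))
    starts <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1L]]))
    if (anyNA(sizes) || anyNA(starts) ||
        length(sizes) != blockCount || length(starts) != blockCount) {
      stop("BED12 parse error at line ", i, ": malformed block lists")
    }
    if (any(chromStart + starts + sizes > chromEnd) || any(starts < 0)) {
      stop("BED12 validation error at line ", i,
           ": blocks outside chromStart/chromEnd")
    }
  }
  invisible(TRUE)
}

#' Read transcript models from a BED12 file
#'
#' Blocks give the exon structure; `thickStart`/`thickEnd` delimit the coding
#' sequence. Exonic bases left of `thickStart` become 5'UTR on the `+` strand
#' (3'UTR on `-`), bases right of `thickEnd` symmetrically. Records with
#' `thickStart == thickEnd` are noncoding and keep all exons undivided.
#'
#' @param path BED12 file path.
#' @param cds_from_thick If `FALSE`, skip the UTR/CDS split: every record
#'   keeps its full exon structure undivided, with biotype derived from the
#'   record name via the `NR_` prefix rule (see [classify_refseq_biotype()]).
#' @return A [tag_annotation()] data frame.
#' @export
read_annotation <- function(path, cds_from_thick = TRUE) {
  bed12_prescan(readLines(path))
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) stop("BED12 records must be named")
  if (anyDuplicated(nm)) stop("duplicate gene_id in BED12: one transcript per name")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    g <- gr[i]
    blocks <- S4Vectors::mcols(g)$blocks[[1L]]
    # genomic 0-based half-open exon intervals
    ex_start <- GenomicRanges::start(g) - 1L + BiocGenerics::start(blocks) - 1L
    ex_end <- ex_start + BiocGenerics::width(blocks)
    strand <- as.character(GenomicRanges::strand(g))
    if (!strand %in% c("+", "-")) {
      stop("gene ", nm[i], ": BED12 strand must be '+' or '-'")
    }
    thick <- S4Vectors::mcols(g)$thick
    t_start <- BiocGenerics::start(thick) - 1L
    t_end <- t_start + BiocGenerics::width(thick)
    if (!cds_from_thick || t_start == t_end) {
      biotype <- if (cds_from_thick) "noncoding" else {
        unname(classify_refseq_biotype(nm[i], warn = FALSE))
      }
      out[[i]] <- data.frame(
        gene_id = nm[i],
        contig = as.character(GenomicRanges::seqnames(g)),
        strand = strand, region = "cds",
        start = ex_start, end = ex_end, biotype = biotype)
      next
    }
    pieces <- list()
    for (j in seq_along(ex_start)) {
      s <- ex_start[j]; e <- ex_end[j]
      left <- c(s, min(e, max(s, t_start)))
      mid <- c(max(s, t_start), min(e, t_end))
      right <- c(max(s, min(e, t_end)), e)
      for (seg in list(c(left, 1L), c(mid, 2L), c(right, 3L))) {
        if (seg[2L] > seg[1L]) {
          pieces[[length(pieces) + 1L]] <- seg
        }
      }
    }
    pm <- do.call(rbind, pieces)
    lab <- if (strand == "+") c("utr5", "cds", "utr3") else c("utr3", "cds", "utr5")
    out[[i]] <- data.frame(
      gene_id = nm[i],
      contig = as.character(GenomicRanges::seqnames(g)),
      strand = strand, region = lab[pm[, 3L]],
      start = pm[, 1L], end = pm[, 2L], biotype = "coding")
  }
  tag_annotation(do.call(rbind, out), provenance = path)
}

#' Write an annotation back to BED12
#'
#' Adjacent UTR/CDS pieces are merged back into single blocks, so a file read
#' with [read_annotation()] is reproduced coordinate-exactly.
#'
#' @param ann A `tag_annotation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  ids <- unique(ann$gene_id)
  grs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- ann[ann$gene_id == ids[i], ]
    blocks <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    chrom_start1 <- min(BiocGenerics::start(blocks))
    cds <- e[e$region == "cds", ]
    if (e$biotype[1L] == "noncoding") {
      thick <- IRanges::IRanges(chrom_start1, width = 0L)
    } else {
      thick <- IRanges::IRanges(min(cds$start) + 1L, max(cds$end))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = e$contig[1L],
      ranges = IRanges::IRanges(chrom_start1, max(BiocGenerics::end(blocks))),
      strand = e$strand[1L])
    S4Vectors::mcols(gr)$name <- ids[i]
    S4Vectors::mcols(gr)$score <- 0
    S4Vectors::mcols(gr)$itemRgb <- NA_character_
    S4Vectors::mcols(gr)$thick <- thick
    S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(
      IRanges::shift(blocks, 1L - chrom_start1))
    grs[[i]] <- gr
  }
  rtracklayer::export(do.call(c, grs), path, format = "bed")
  invisible(path)
}

#' Partition RefSeq-style identifiers into coding and noncoding
#'
#' An identifier is noncoding if it starts with `NR_` or is listed in
#' `ncrna_list`; everything else is coding. Identifiers with an unrecognised
#' prefix default to coding with a warning.
#'
#' @param ids Character vector of RefSeq-style accessions.
#' @param ncrna_list Character vector of accessions known to be noncoding.
#' @param warn Warn on unrecognised prefixes.
#' @return Named character vector, values `"coding"` or `"noncoding"`.
#' @examples
#' classify_refseq_biotype(c("NM_000001", "NR_027784"))
#' @export
classify_refseq_biotype <- function(ids, ncrna_list = character(), warn = TRUE) {
  noncoding <- startsWith(ids, "NR_") | ids %in% ncrna_list
  known <- startsWith(ids, "NM_") | startsWith(ids, "NR_") |
    startsWith(ids, "XM_") | startsWith(ids, "XR_") | ids %in% ncrna_list
  if (warn && any(!known)) {
    warning("unrecognised prefix for ", sum(!known),
            " identifier(s); defaulting to coding")
  }
  stats::setNames(ifelse(noncoding, "noncoding", "coding"), ids)
}

#' cDNA length of each transcript
#'
#' @param ann A `tag_annotation`.
#' @param include_utrs Sum over UTR and CDS exons (`TRUE`) or CDS exons only.
#' @return Named integer vector of exonic lengths in bp.
#' @export
cdna_length <- function(ann, include_utrs = TRUE) {
  keep <- if (include_utrs) rep(TRUE, nrow(ann)) else ann$region == "cds"
  w <- (ann$end - ann$start)[keep]
  out <- tapply(w, ann$gene_id[keep], sum)
  # preserve genes whose kept set is empty (cannot happen: cds always present)
  stats::setNames(as.integer(out), names(out))
}

#' Assign a cDNA length to a size class or histogram bin
#'
#' Two schemes are provided. `coverage` yields the three gene-body coverage
#' groups: `small` (< 1 kb), `medium` (1-8 kb inclusive) and `large` (> 8 kb).
#' `comparison` yields the size-distribution histogram bin index: 100 bp bins
#' below 2 kb (bin `floor(length/100)`), 500 bp bins above
#' (`20 + floor((length - 2000)/500)`), with every cDNA larger than 11.5 kb
#' grouped into the last bin (index 39).
#'
#' @param length_bp Positive integer vector of cDNA lengths.
#' @param scheme `"coverage"` or `"comparison"`.
#' @return Factor of class labels (`coverage`) or integer bin indices
#'   (`comparison`).
#' @examples
#' size_class(c(500, 1000, 8000, 8001), "coverage")
#' size_class(c(1950, 2000, 11499, 12000), "comparison")
#' @export
size_class <- function(length_bp, scheme = c("coverage", "comparison")) {
  scheme <- match.arg(scheme)
  if (any(length_bp <= 0)) stop("lengths must be positive")
  if (scheme == "coverage") {
    cls <- ifelse(length_bp < 1000, "small",
                  ifelse(length_bp <= 8000, "medium", "large"))
    return(factor(cls, levels = c("small", "medium", "large")))
  }
  bin <- ifelse(length_bp < 2000, length_bp %/% 100,
                20L + (length_bp - 2000) %/% 500)
  as.integer(pmin(bin, comparison_last_bin()))
}

# last comparison bin: the 500 bp bin containing 11.5 kb; larger cDNAs collapse here
comparison_last_bin <- function() 20L + (11500L - 2000L) %/% 500L

#' Lower bp bound of each comparison-scheme size bin
#' @param bins Integer bin indices from [size_class()] comparison scheme.
#' @return Integer vector of bin lower bounds in bp.
#' @export
comparison_bin_lower <- function(bins) {
  ifelse(bins < 20L, bins * 100L, 2000L + (bins - 20L) * 500L)
}

#' Exon ranges of an annotation as a GRangesList
#'
#' @param ann A `tag_annotation`.
#' @param region Optional subset of regions (`utr5`, `cds`, `utr3`).
#' @return A [GenomicRanges::GRangesList], one element per transcript, ranges
#'   1-based as usual for GRanges.
#' @export
exon_ranges <- function(ann, region = NULL) {
  e <- if (is.null(region)) ann else ann[ann$region %in% region, ]
  gr <- GenomicRanges::GRanges(e$contig,
                               IRanges::IRanges(e$start + 1L, e$end),
                               strand = e$strand)
  S4Vectors::split(gr, factor(e$gene_id, levels = unique(ann$gene_id)))
}
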