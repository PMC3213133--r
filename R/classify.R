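#' Tag class counts for one sample
#'
#' @param sample_id Sample label.
#' @param counts Named integer vector with entries `rrna_mito`, `unique`,
#'   `repeat`, `nomatch`.
#' @return A `tag_class_counts` object.
#' @export
tag_class_counts <- function(sample_id, counts) {
  cls <- c("rrna_mito", "unique", "repeat", "nomatch")
  if (!all(cls %in% names(counts))) {
    stop("counts must be named rrna_mito, unique, repeat, nomatch")
  }
  counts <- as.integer(counts[cls])
  names(counts) <- cls
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(sample_id = sample_id, counts = counts,
                 total = sum(counts)), class = "tag_class_counts")
}

#' @export
print.tag_class_counts <- function(x, ...) {
  cat("Tag classes for sample '", x$sample_id, "' (", x$total, " tags)\n",
      sep = "")
  pct <- if (x$total > 0) 100 * x$counts / x$total else rep(0, 4)
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-10s %9d  (%5.1f%%)\n", names(x$counts)[i], x$counts[i],
                pct[i]))
  }
  invisible(x)
}

#' Percentages of the four tag classes
#' @param x A `tag_class_counts`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
tag_class_percent <- function(x) {
  stopifnot(inherits(x, "tag_class_counts"), x$total > 0)
  100 * x$counts / x$total
}

#' Hierarchically classify tags into rRNA/mito, unique, repeat and nomatch
#'
#' Mirrors the sequential alignment of a ribo-depletion QC pipeline: tags are
#' first matched against the rRNA and mitochondrial references; any tag with a
#' placement there is classed `rrna_mito` and removed before genome alignment,
#' even if it would also match the genome. Remaining tags are matched against
#' the nuclear contigs: exactly one placement is `unique`, more than one
#' `repeat`, none `nomatch`. Repeat tags are excluded from all downstream
#' quantification.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector of tags.
#' @param refs A [contig_set()] containing both contamination (`rrna`, `mito`)
#'   and `nuclear` contigs.
#' @param max_mismatches Passed to [align_tags()]; `NULL` for the
#'   length-dependent default.
#' @param sample_id Label stored in the returned counts.
#' @return A `tag_classification` list: `tags` (data frame `read_id`,
#'   `tag_class`, `n_genome_matches`, `length`), `unique_placements`
#'   (placements of unique-class tags, for pileups and counting) and `counts`
#'   (a [tag_class_counts()]).
#' @export
classify_tags <- function(reads, refs, max_mismatches = NULL,
                          sample_id = "sample") {
  reads <- as_read_set(reads)
  rc <- ref_class(refs)
  contam <- refs[rc %in% c("rrna", "mito")]
  nuclear <- refs[rc == "nuclear"]
  if (length(nuclear) == 0L) stop("no nuclear contigs in refs")
  n <- length(reads)
  tag_class <- rep("nomatch", n)
  n_genome <- integer(n)
  if (length(contam) && n) {
    st1 <- align_tags(reads, contam, max_mismatches)
    is_cont <- st1$n_matches[names(reads)] > 0L
  } else {
    is_cont <- rep(FALSE, n)
  }
  tag_class[is_cont] <- "rrna_mito"
  rest <- reads[!is_cont]
  placements <- NULL
  if (length(rest)) {
    st2 <- align_tags(rest, nuclear, max_mismatches)
    nm <- st2$n_matches[names(rest)]
    cls <- ifelse(nm == 1L, "unique", ifelse(nm > 1L, "repeat", "nomatch"))
    tag_class[!is_cont] <- cls
    n_genome[!is_cont] <- nm
    uids <- names(rest)[nm == 1L]
    placements <- st2$placements[st2$placements$read_id %in% uids, ,
                                 drop = FALSE]
    rownames(placements) <- NULL
  } else {
    placements <- data.frame(read_id = character(), contig = character(),
                             start = integer(), strand = character(),
                             mismatches = integer(), width = integer())
  }
  counts <- tag_class_counts(sample_id, c(
    rrna_mito = sum(tag_class == "rrna_mito"),
    unique = sum(tag_class == "unique"),
    "repeat" = sum(tag_class == "repeat"),
    nomatch = sum(tag_class == "nomatch")))
  structure(list(
    tags = data.frame(read_id = names(reads), tag_class = tag_class,
                      n_genome_matches = n_genome,
                      length = S4Vectors::width(reads)),
    unique_placements = placements,
    counts = counts), class = "tag_classification")
}

#' @export
print.tag_classification <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Ingest an external SAM alignment
#'
#' Groups records by read, converts coordinates to 0-based, and classifies
#' each read with the same hierarchy as [classify_tags()]: any placement on an
#' `rrna`/`mito` contig wins, then genome multiplicity (the `NH` tag when
#' present, otherwise the number of mapped records) decides
#' `unique`/`repeat`, and the unmapped flag gives `nomatch`. A SAM file
#' without a header gets a minimal one synthesised from `class_map` (with a
#' warning); records on contigs absent from `class_map` are an error.
#'
#' @param path SAM file path.
#' @param class_map Named character vector mapping contig name to
#'   `nuclear`/`rrna`/`mito`.
#' @param sample_id Label for the counts.
#' @return A `tag_classification` (see [classify_tags()]).
#' @export
ingest_sam <- function(path, class_map, sample_id = "sample") {
  lines <- readLines(path)
  if (!any(startsWith(lines, "@SQ"))) {
    warning("SAM file has no @SQ header; synthesising one from class_map")
    body <- lines[!startsWith(lines, "@")]
    f <- strsplit(body, "\t", fixed = TRUE)
    rn <- vapply(f, `[`, "", 3L)
    pos <- suppressWarnings(as.integer(vapply(f, `[`, "", 4L)))
    sq <- vapply(names(class_map), function(cn) {
      here <- rn == cn & !is.na(pos)
      len <- if (any(here)) max(pos[here]) + 1000L else 1000L
      sprintf("@SQ\tSN:%s\tLN:%d", cn, len)
    }, "")
    lines <- c("@HD\tVN:1.6\tSO:unsorted", sq, body)
    path <- tempfile(fileext = ".sam")
    writeLines(lines, path)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth"),
    tag = "NH")
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  qn <- b$qname
  mapped <- !bitwAnd(b$flag, 4L)
  rn <- as.character(b$rname)
  if (any(mapped & !(rn %in% names(class_map)))) {
    stop("SAM records on contig(s) absent from class_map: ",
         paste(unique(rn[mapped & !(rn %in% names(class_map))]), collapse = ", "))
  }
  ids <- unique(qn)
  tag_class <- character(length(ids))
  n_genome <- integer(length(ids))
  lens <- integer(length(ids))
  place <- list()
  idx_by_read <- split(seq_along(qn), factor(qn, levels = ids))
  nh <- b$tag$NH
  for (i in seq_along(ids)) {
    ix <- idx_by_read[[i]]
    lens[i] <- max(b$qwidth[ix], 0L, na.rm = TRUE)
    mix <- ix[mapped[ix]]
    if (!length(mix)) {
      tag_class[i] <- "nomatch"
      next
    }
    cls <- class_map[rn[mix]]
    if (any(cls %in% c("rrna", "mito"))) {
      tag_class[i] <- "rrna_mito"
      next
    }
    mult <- if (!is.null(nh) && !is.na(nh[mix[1L]])) nh[mix[1L]] else length(mix)
    n_genome[i] <- mult
    tag_class[i] <- if (mult == 1L) "unique" else "repeat"
    if (mult == 1L) {
      place[[length(place) + 1L]] <- data.frame(
        read_id = ids[i], contig = rn[mix[1L]],
        start = b$pos[mix[1L]] - 1L,
        strand = as.character(b$strand[mix[1L]]),
        mismatches = NA_integer_, width = b$qwidth[mix[1L]])
    }
  }
  placements <- if (length(place)) do.call(rbind, place) else
    data.frame(read_id = character(), contig = character(), start = integer(),
               strand = character(), mismatches = integer(), width = integer())
  counts <- tag_class_counts(sample_id, c(
    rrna_mito = sum(tag_class == "rrna_mito"),
    unique = sum(tag_class == "unique"),
    "repeat" = sum(tag_class == "repeat"),
    nomatch = sum(tag_class == "nomatch")))
  structure(list(
    tags = data.frame(read_id = ids, tag_class = tag_class,
                      n_genome_matches = n_genome, length = lens),
    unique_placements = placements, counts = counts),
    class = "tag_classification")
}

#' One-tailed pooled-variance t-test on tag-class percentages
#'
#' Compares the percentage of one tag class between two groups of replicate
#' samples with a two-sample equal-variance t statistic and a one-tailed
#' p-value oriented towards `mean(A) > mean(B)` (Student's t with
#' `nA + nB - 2` degrees of freedom). With zero pooled variance and equal
#' means the test is uninformative and p = 0.5 is returned.
#'
#' @param groupA,groupB Lists of [tag_class_counts()] objects (at least two
#'   replicates each), or numeric vectors of percentages.
#' @param tag_class Which class to compare (ignored when percentages are
#'   passed directly).
#' @return An object of class `htest`.
#' @export
compare_tag_fractions <- function(groupA, groupB, tag_class = "rrna_mito") {
  pct <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(s) tag_class_percent(s)[[tag_class]], 0)
  }
  a <- pct(groupA); b <- pct(groupB)
  if (length(a) < 2L || length(b) < 2L) {
    stop("at least two replicates per group are required")
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  dm <- mean(a) - mean(b)
  if (se == 0) {
    tstat <- if (dm == 0) 0 else sign(dm) * Inf
  } else {
    tstat <- dm / se
  }
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  structure(list(
    statistic = c(t = tstat), parameter = c(df = df), p.value = p,
    estimate = c(`mean of A` = mean(a), `mean of B` = mean(b)),
    alternative = "one-tailed: mean(A) greater than mean(B)",
    method = "Two-sample pooled-variance t-test on tag-class percentages",
    data.name = paste0(tag_class, " percentages")), class = "htest")
}
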