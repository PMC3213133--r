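#' Reference contigs with alignment classes
#'
#' A contig set bundles reference sequences (nuclear genome contigs, rRNA
#' repeat units, the mitochondrial chromosome) with the class each contig
#' plays during hierarchical tag alignment: tags are matched against `rrna`
#' and `mito` contigs first and only the remainder against `nuclear` contigs.
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector of
#'   uppercase nucleotide sequences (A, C, G, T, N only).
#' @param ref_class Character vector of classes, one per contig, each one of
#'   `"nuclear"`, `"rrna"` or `"mito"`. Either named by contig or given in the
#'   same order as `seqs`.
#' @return A `DNAStringSet` whose `mcols()` carry a `ref_class` column.
#' @examples
#' cs <- contig_set(c(chr1 = "ACGTACGT", rDNA = "GGGGCCCC"),
#'                  c(chr1 = "nuclear", rDNA = "rrna"))
#' ref_class(cs)
#' @export
contig_set <- function(seqs, ref_class) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (!methods::is(seqs, "DNAStringSet")) {
    stop("'seqs' must be a DNAStringSet or character vector")
  }
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("contig names must be present and unique")
  }
  af <- Biostrings::alphabetFrequency(seqs)
  ok <- rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE]) == S4Vectors::width(seqs)
  if (!all(ok)) {
    stop("contig(s) ", paste(nm[!ok], collapse = ", "),
         " contain letters other than A,C,G,T,N")
  }
  if (!is.null(names(ref_class))) {
    if (!all(nm %in% names(ref_class))) stop("ref_class missing for some contigs")
    ref_class <- ref_class[nm]
  }
  if (length(ref_class) != length(seqs)) {
    stop("ref_class must have one entry per contig")
  }
  ref_class <- as.character(ref_class)
  bad <- setdiff(unique(ref_class), c("nuclear", "rrna", "mito"))
  if (length(bad)) stop("unknown ref_class: ", paste(bad, collapse = ", "))
  S4Vectors::mcols(seqs)$ref_class <- ref_class
  seqs
}

#' @rdname contig_set
#' @param x A contig set created by [contig_set()] or [read_genome()].
#' @export
ref_class <- function(x) {
  rc <- S4Vectors::mcols(x)$ref_class
  if (is.null(rc)) stop("'x' carries no ref_class metadata; see contig_set()")
  stats::setNames(as.character(rc), names(x))
}

#' Read reference contigs from FASTA with a class sidecar
#'
#' @param fasta Path to a FASTA file of reference sequences.
#' @param class_file Optional path to a two-column tab-separated table
#'   (contig name, ref class) assigning each contig to `nuclear`, `rrna` or
#'   `mito`. Alternatively pass the assignment directly via `ref_class`.
#' @param ref_class Named character vector used when `class_file` is `NULL`;
#'   contigs absent from it default to `"nuclear"`.
#' @return A contig set (see [contig_set()]).
#' @export
read_genome <- function(fasta, class_file = NULL, ref_class = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(class_file)) {
    tab <- utils::read.table(class_file, sep = "\t", header = FALSE,
                             col.names = c("contig", "class"),
                             stringsAsFactors = FALSE)
    ref_class <- stats::setNames(tab$class, tab$contig)
  }
  rc <- stats::setNames(rep("nuclear", length(seqs)), names(seqs))
  if (!is.null(ref_class)) {
    known <- intersect(names(ref_class), names(seqs))
    rc[known] <- ref_class[known]
  }
  contig_set(seqs, rc)
}

#' Write a contig set to FASTA (and optionally its class sidecar)
#'
#' @param contigs A contig set.
#' @param fasta Output FASTA path.
#' @param class_file Optional path for the two-column ref-class table.
#' @return Invisibly, `fasta`.
#' @export
write_genome <- function(contigs, fasta, class_file = NULL) {
  Biostrings::writeXStringSet(contigs, fasta)
  if (!is.null(class_file)) {
    utils::write.table(data.frame(names(contigs), ref_class(contigs)),
                       class_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta)
}
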