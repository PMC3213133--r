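#' Default mismatch allowance for a tag length
#'
#' 2 mismatches for tags shorter than 44 bp (the 36 bp design), 3 for longer
#' tags (the 51 bp design). Lengths between the two designs keep the
#' conservative allowance of 2.
#'
#' @param length_bp Integer vector of tag lengths.
#' @return Integer vector of mismatch allowances.
#' @export
default_max_mismatches <- function(length_bp) {
  ifelse(length_bp < 44L, 2L, 3L)
}

as_read_set <- function(reads) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (!methods::is(reads, "DNAStringSet")) {
    stop("'reads' must be a DNAStringSet or character vector")
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  }
  if (anyDuplicated(names(reads))) stop("read ids must be unique")
  reads
}

# disjoint seed partition of a read of width w into k+1 segments; any
# placement with <= k mismatches leaves at least one segment mismatch-free
seed_partition <- function(w, k) {
  nseg <- k + 1L
  base <- w %/% nseg
  rem <- w - base * nseg
  widths <- rep(base, nseg) + as.integer(seq_len(nseg) <= rem)
  data.frame(offset = cumsum(c(0L, widths[-nseg])), width = widths)
}

# candidate verification: Hamming distance between equal-width window and read
hamming_keep <- function(windows, reads_chr, k) {
  wm <- t(vapply(strsplit(windows, "", fixed = TRUE), identity,
                 character(nchar(windows[1L]))))
  rm_ <- t(vapply(strsplit(reads_chr, "", fixed = TRUE), identity,
                  character(nchar(reads_chr[1L]))))
  rowSums(wm != rm_)
}

#' Exhaustively place tags on reference contigs allowing mismatches
#'
#' Reports every offset, on either strand of every contig, where a tag matches
#' with at most `max_mismatches` Hamming mismatches (no indels). The search is
#' exact: a pigeonhole seed partition (`k + 1` disjoint segments, one of which
#' must match exactly) generates candidates via [Biostrings::matchPDict()],
#' which are then verified at full length. Reads longer than a contig simply
#' yield no placement there.
#'
#' @param reads Named [Biostrings::DNAStringSet] (or character vector) of tags.
#' @param refs A [contig_set()], `DNAStringSet`, or named character vector of
#'   reference contigs.
#' @param max_mismatches Single allowance applied to all reads, or `NULL` for
#'   the length-dependent default ([default_max_mismatches()]).
#' @return A `tag_alignments` list: `placements` (data frame `read_id`,
#'   `contig`, `start` 0-based, `strand`, `mismatches`, `width`) and
#'   `n_matches` (named integer, total placements per read, zero included).
#' @export
align_tags <- function(reads, refs, max_mismatches = NULL) {
  reads <- as_read_set(reads)
  if (is.character(refs)) refs <- Biostrings::DNAStringSet(refs)
  if (length(refs) == 0L) stop("reference set must be non-empty")
  if (is.null(names(refs))) stop("reference contigs must be named")
  widths <- S4Vectors::width(reads)
  k_read <- if (is.null(max_mismatches)) default_max_mismatches(widths) else
    rep(as.integer(max_mismatches), length(reads))
  ref_chr <- stats::setNames(as.character(refs), names(refs))
  ref_dna <- lapply(ref_chr, Biostrings::DNAString)

  all_place <- list()
  for (grp in split(seq_along(reads), paste(widths, k_read))) {
    w <- widths[grp[1L]]
    k <- k_read[grp[1L]]
    fwd <- as.character(reads[grp])
    rev <- as.character(Biostrings::reverseComplement(reads[grp]))
    sp <- seed_partition(w, k)
    # seed table: read index (into grp), strand, offset in oriented read
    seeds <- character(0); seed_read <- integer(0)
    seed_off <- integer(0); seed_strand <- character(0)
    for (j in seq_len(nrow(sp))) {
      o <- sp$offset[j]; sw <- sp$width[j]
      seeds <- c(seeds, substring(fwd, o + 1L, o + sw),
                 substring(rev, o + 1L, o + sw))
      seed_read <- c(seed_read, seq_along(grp), seq_along(grp))
      seed_off <- c(seed_off, rep(o, 2L * length(grp)))
      seed_strand <- c(seed_strand, rep(c("+", "-"), each = length(grp)))
    }
    for (sw in unique(nchar(seeds))) {
      sel <- which(nchar(seeds) == sw)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(seeds[sel])))
      for (cn in names(ref_chr)) {
        clen <- nchar(ref_chr[[cn]])
        if (clen < w) next
        mi <- Biostrings::matchPDict(pd, ref_dna[[cn]])
        hits <- Biostrings::startIndex(mi)
        nh <- lengths(hits)
        if (!sum(nh)) next
        pat <- rep.int(sel, nh)
        # candidate read start (1-based) on the contig
        cand <- data.frame(
          ri = seed_read[pat],
          strand = seed_strand[pat],
          start1 = unlist(hits, use.names = FALSE) - seed_off[pat])
        cand <- cand[cand$start1 >= 1L & cand$start1 + w - 1L <= clen, ]
        if (!nrow(cand)) next
        key <- (cand$ri * 2 + (cand$strand == "-")) * (clen + 1) + cand$start1
        cand <- cand[!duplicated(key), , drop = FALSE]
        windows <- substring(ref_chr[[cn]], cand$start1, cand$start1 + w - 1L)
        oriented <- ifelse(cand$strand == "+", fwd[cand$ri], rev[cand$ri])
        mism <- hamming_keep(windows, oriented, k)
        ok <- mism <= k
        if (!any(ok)) next
        all_place[[length(all_place) + 1L]] <- data.frame(
          read_id = names(reads)[grp[cand$ri[ok]]],
          contig = cn,
          start = cand$start1[ok] - 1L,
          strand = cand$strand[ok],
          mismatches = mism[ok],
          width = w)
      }
    }
  }
  placements <- if (length(all_place)) do.call(rbind, all_place) else
    data.frame(read_id = character(), contig = character(), start = integer(),
               strand = character(), mismatches = integer(), width = integer())
  # a placement can surface through seeds of different widths: keep one copy
  placements <- placements[!duplicated(placements[c("read_id", "contig",
                                                    "start", "strand")]), ,
                           drop = FALSE]
  placements <- placements[order(match(placements$read_id, names(reads)),
                                 placements$contig, placements$start,
                                 placements$strand), , drop = FALSE]
  rownames(placements) <- NULL
  n_matches <- stats::setNames(integer(length(reads)), names(reads))
  if (nrow(placements)) {
    tab <- table(placements$read_id)
    n_matches[names(tab)] <- as.integer(tab)
  }
  structure(list(placements = placements, n_matches = n_matches,
                 max_mismatches = stats::setNames(k_read, names(reads))),
            class = "tag_alignments")
}
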