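#' Configuration for the synthetic ribo-depleted RNA-Seq generator
#'
#' The generator emulates the statistical structure a ribo-depleted single-end
#' library shows: lognormally distributed transcript abundances, fragment
#' sampling that is uniform along the transcript (RNA hydrolysis) or 5'-biased
#' (cDNA shearing), reduced sampling of UTR bases, a length-dependent loss of
#' tags towards the 3' end, rRNA and mitochondrial contamination, multi-mapping
#' tags from an exactly duplicated genomic segment, and an unmappable
#' background fraction.
#'
#' @param seed Integer seed; every simulated object is deterministic given it.
#' @param n_genes Number of nuclear multi-exon coding genes (cycled over the
#'   three coverage size classes small/medium/large).
#' @param contig_length Optional nuclear contig length in bp; computed from
#'   the gene layout when `NULL`. Too small a value is a capacity error.
#' @param utr5_frac,utr3_frac Fraction of each coding cDNA assigned to the
#'   5' and 3' UTR.
#' @param expression_meanlog,expression_sdlog Lognormal abundance parameters.
#' @param n_reads Total tags to emit.
#' @param read_length Tag length in bp (the study designs are 36 and 51).
#' @param rrna_fraction,mito_fraction Expected contamination proportions.
#' @param repeat_fraction Expected proportion of tags from the duplicated
#'   segment (each such tag matches the genome exactly twice).
#' @param background_fraction Expected proportion of random unmappable tags.
#' @param fragmentation `"hydrolysis"` (uniform fragment starts) or
#'   `"shearing"` (start density proportional to `exp(-bias_rate * x/L)`).
#' @param bias_rate Dimensionless 5' bias decay for shearing; 0 for hydrolysis.
#' @param utr_weight Acceptance probability for fragments starting in a UTR,
#'   in (0, 1].
#' @param three_prime_decay Per-kb acceptance loss `exp(-decay * x/1000)`
#'   applied along every transcript, reproducing length-dependent 3' tag loss.
#' @param include_macro_ncrna Add one long single-exon noncoding gene
#'   (macro ncRNA mimic, cf. Airn/Kcnq1ot1).
#' @param macro_ncrna_length Its length in bp.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 30,
                       contig_length = NULL,
                       utr5_frac = 0.10,
                       utr3_frac = 0.25,
                       expression_meanlog = 1,
                       expression_sdlog = 1.5,
                       n_reads = 50000,
                       read_length = 36,
                       rrna_fraction = 0.50,
                       mito_fraction = 0.05,
                       repeat_fraction = 0.06,
                       background_fraction = 0.12,
                       fragmentation = c("hydrolysis", "shearing"),
                       bias_rate = NULL,
                       utr_weight = 0.3,
                       three_prime_decay = 0,
                       include_macro_ncrna = FALSE,
                       macro_ncrna_length = 20000) {
  fragmentation <- match.arg(fragmentation)
  if (is.null(bias_rate)) bias_rate <- if (fragmentation == "shearing") 2 else 0
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_genes >= 0, n_reads >= 0, read_length >= 12,
            utr5_frac >= 0, utr3_frac >= 0, utr5_frac + utr3_frac < 1,
            bias_rate >= 0, three_prime_decay >= 0,
            utr_weight > 0, utr_weight <= 1)
  fr <- c(rrna_fraction, mito_fraction, repeat_fraction, background_fraction)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0,1]")
  if (rrna_fraction + mito_fraction + repeat_fraction > 1) {
    stop("rrna_fraction + mito_fraction + repeat_fraction must be <= 1")
  }
  if (sum(fr) > 1) stop("contamination + background fractions exceed 1")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              contig_length = contig_length,
              utr5_frac = utr5_frac, utr3_frac = utr3_frac,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              rrna_fraction = rrna_fraction, mito_fraction = mito_fraction,
              repeat_fraction = repeat_fraction,
              background_fraction = background_fraction,
              fragmentation = fragmentation, bias_rate = bias_rate,
              utr_weight = utr_weight, three_prime_decay = three_prime_decay,
              include_macro_ncrna = isTRUE(include_macro_ncrna),
              macro_ncrna_length = as.integer(macro_ncrna_length))
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# split total into n parts, each >= minw
random_composition <- function(total, n, minw) {
  if (n == 1L) return(total)
  if (total < n * minw) stop("cannot split ", total, " into ", n, " exons")
  extra <- total - n * minw
  cuts <- sort(sample.int(extra + n - 1L, n - 1L))
  w <- diff(c(0L, cuts, extra + n)) - 1L + minw
  stopifnot(sum(w) == total, all(w >= minw))
  w
}

# map a transcript-coordinate interval [a,b) through one gene's exon layout
# exons: data.frame(t0, width, gstart, gend) in transcript order; strand
map_transcript_interval <- function(a, b, exons, strand) {
  res <- list()
  for (j in seq_len(nrow(exons))) {
    t0 <- exons$t0[j]; w <- exons$width[j]
    lo <- max(a, t0); hi <- min(b, t0 + w)
    if (hi <= lo) next
    if (strand == "+") {
      gs <- exons$gstart[j] + (lo - t0); ge <- exons$gstart[j] + (hi - t0)
    } else {
      gs <- exons$gend[j] - (hi - t0); ge <- exons$gend[j] - (lo - t0)
    }
    res[[length(res) + 1L]] <- c(gs, ge)
  }
  do.call(rbind, res)
}

#' Simulate a toy genome and transcript annotation
#'
#' Emits one nuclear contig carrying non-overlapping multi-exon coding genes
#' spanning the three coverage size classes, optionally one long single-exon
#' noncoding gene, plus an exactly duplicated 500 bp segment (multi-mapping
#' source), one rRNA contig and one mitochondrial contig. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_genome` list: `contigs` (a [contig_set()]), `annotation`
#'   (a [tag_annotation()]), `repeat_regions` (the two copies of the
#'   duplicated segment) and `config`.
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rl <- cfg$read_length
  n <- cfg$n_genes
  cls <- rep(c("small", "medium", "large"), length.out = max(n, 0L))
  cdna <- integer(n)
  for (i in seq_len(n)) {
    cdna[i] <- switch(cls[i],
                      small = sample(300:900, 1L),
                      medium = sample(1200:6000, 1L),
                      large = sample(9500:15000, 1L))
  }
  exon_rows <- list()
  cursor <- 0L
  min_exon <- max(60L, rl + 4L)
  for (i in seq_len(n)) {
    gid <- sprintf("gene_%03d", i)
    u5 <- max(min(as.integer(round(cfg$utr5_frac * cdna[i])), cdna[i] - 2L), 1L)
    u3 <- max(min(as.integer(round(cfg$utr3_frac * cdna[i])), cdna[i] - u5 - 1L), 1L)
    cds <- cdna[i] - u5 - u3
    n_ex <- max(2L, min(12L, cdna[i] %/% 800L + 2L))
    n_ex <- min(n_ex, cdna[i] %/% min_exon)
    n_ex <- max(n_ex, 2L)
    widths <- random_composition(cdna[i], n_ex, min_exon)
    introns <- sample(200:1500, n_ex - 1L, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    gap <- sample(500:2000, 1L)
    g0 <- cursor + gap
    gstarts <- g0 + cumsum(c(0L, widths[-n_ex] + introns))
    gends <- gstarts + widths
    cursor <- gends[n_ex]
    # transcript order: '+' keeps genomic order, '-' reverses it
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ex <- data.frame(t0 = cumsum(c(0L, widths[ord][-n_ex])),
                     width = widths[ord],
                     gstart = gstarts[ord], gend = gends[ord])
    segs <- rbind(
      cbind(map_transcript_interval(0L, u5, ex, strand), 1L),
      cbind(map_transcript_interval(u5, u5 + cds, ex, strand), 2L),
      cbind(map_transcript_interval(u5 + cds, cdna[i], ex, strand), 3L))
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = gid, contig = "chrS", strand = strand,
      region = c("utr5", "cds", "utr3")[segs[, 3L]],
      start = segs[, 1L], end = segs[, 2L], biotype = "coding")
  }
  if (cfg$include_macro_ncrna) {
    gap <- sample(500:2000, 1L)
    g0 <- cursor + gap
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = "macro_ncrna", contig = "chrS", strand = "+", region = "cds",
      start = g0, end = g0 + cfg$macro_ncrna_length, biotype = "noncoding")
    cursor <- g0 + cfg$macro_ncrna_length
  }
  # duplicated segment: two identical 500 bp copies in intergenic space
  seg_len <- max(500L, 2L * rl)
  rep1 <- cursor + 1000L
  rep2 <- rep1 + seg_len + 1000L
  cursor <- rep2 + seg_len
  needed <- cursor + 500L
  contig_length <- cfg$contig_length
  if (is.null(contig_length)) {
    contig_length <- needed
  } else if (contig_length < needed) {
    stop("capacity error: contig_length ", contig_length,
         " too small for layout (needs ", needed, " bp)")
  }
  chr <- random_dna(contig_length)
  seg <- random_dna(seg_len)
  substr(chr, rep1 + 1L, rep1 + seg_len) <- seg
  substr(chr, rep2 + 1L, rep2 + seg_len) <- seg
  contigs <- contig_set(
    c(chrS = chr, rRNA = random_dna(4500L), chrM = random_dna(16000L)),
    c(chrS = "nuclear", rRNA = "rrna", chrM = "mito"))
  ann_df <- if (length(exon_rows)) do.call(rbind, exon_rows) else
    data.frame(gene_id = character(), contig = character(),
               strand = character(), region = character(),
               start = integer(), end = integer(), biotype = character())
  structure(list(
    contigs = contigs,
    annotation = tag_annotation(ann_df, provenance = "ribotag simulation"),
    repeat_regions = data.frame(contig = "chrS",
                                start = c(rep1, rep2),
                                end = c(rep1, rep2) + seg_len),
    config = cfg), class = "sim_genome")
}

# per-gene exon layout in transcript order, plus region piece offsets
transcript_layout <- function(ann, gid) {
  e <- ann[ann$gene_id == gid, ]
  strand <- e$strand[1L]
  # exon = maximal run of genomically adjacent pieces (UTR/CDS splits rejoin)
  er <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
  gstart <- BiocGenerics::start(er) - 1L
  gend <- BiocGenerics::end(er)
  ord <- if (strand == "+") order(gstart) else order(-gstart)
  gstart <- gstart[ord]; gend <- gend[ord]
  w <- gend - gstart
  ex <- data.frame(t0 = cumsum(c(0L, w[-length(w)])), width = w,
                   gstart = gstart, gend = gend)
  # region pieces in transcript coordinates
  pord <- if (strand == "+") order(e$start) else order(-e$start)
  pw <- (e$end - e$start)[pord]
  pieces <- data.frame(t0 = cumsum(c(0L, pw[-length(pw)])), width = pw,
                       region = e$region[pord])
  list(strand = strand, contig = e$contig[1L], exons = ex, pieces = pieces,
       length = sum(w))
}

draw_fragment_starts <- function(m, max_start, cfg, L) {
  if (cfg$fragmentation == "hydrolysis" || cfg$bias_rate == 0) {
    return(sample.int(max_start + 1L, m, replace = TRUE) - 1L)
  }
  b <- cfg$bias_rate
  mc <- max_start + 1
  u <- stats::runif(m)
  x <- -(L / b) * log(1 - u * (1 - exp(-b * mc / L)))
  pmin(as.integer(floor(x)), max_start)
}

#' Simulate single-end tags with per-read ground truth
#'
#' Read origins are drawn from the contamination, repeat, background and
#' transcript classes; transcripts are picked with probability proportional to
#' abundance times length (fragmentation of full-length RNA yields more
#' fragments from longer molecules). Within a transcript the fragment start is
#' uniform (hydrolysis) or 5'-weighted (shearing); starts falling in UTRs are
#' accepted with probability `utr_weight`, and all starts with probability
#' `exp(-three_prime_decay * x/1000)`. Fragments spanning exon junctions are
#' re-drawn (junction tags are not mapped downstream). Tags are emitted from
#' either strand with equal probability.
#'
#' @param cfg A [sim_config()] (the same one used for the genome).
#' @param sim A `sim_genome` from [simulate_genome_annotation()].
#' @param abundance Optional named vector of true relative abundances (one per
#'   transcript) overriding the lognormal draw, for controlled experiments.
#' @return A `sim_reads` list: `reads` (named [Biostrings::DNAStringSet]),
#'   `truth` (data frame `read_id`, `origin` - a gene_id or one of
#'   `rrna`/`mito`/`repeat`/`background` -, `origin_class`, `contig`, `start`),
#'   `abundance` (true relative transcript abundances) and `config`.
#' @export
simulate_reads <- function(cfg, sim, abundance = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "sim_genome"))
  set.seed((cfg$seed %% 1000000L) * 2011L + 7L)
  rl <- cfg$read_length
  n <- cfg$n_reads
  ann <- sim$annotation
  ids <- unique(ann$gene_id)
  seqs <- stats::setNames(as.character(sim$contigs), names(sim$contigs))

  abund <- if (!is.null(abundance)) {
    if (!all(ids %in% names(abundance))) {
      stop("abundance must name every transcript")
    }
    abundance[ids]
  } else if (length(ids)) {
    stats::setNames(stats::rlnorm(length(ids), cfg$expression_meanlog,
                                  cfg$expression_sdlog), ids)
  } else stats::setNames(numeric(0), character(0))

  p_gene <- 1 - cfg$rrna_fraction - cfg$mito_fraction -
    cfg$repeat_fraction - cfg$background_fraction
  probs <- c(rrna = cfg$rrna_fraction, mito = cfg$mito_fraction,
             rep = cfg$repeat_fraction, bg = cfg$background_fraction,
             gene = p_gene)
  if (length(ids) == 0L) {
    probs["gene"] <- 0
    if (sum(probs) == 0) stop("configuration error: no read source has weight")
    probs <- probs / sum(probs)
  }
  cat_draw <- sample(names(probs), n, replace = TRUE, prob = probs)

  read_seq <- character(n)
  truth_origin <- character(n)
  truth_contig <- rep(NA_character_, n)
  truth_start <- rep(NA_integer_, n)

  take_window <- function(contig, starts) {
    substring(seqs[[contig]], starts + 1L, starts + rl)
  }
  for (cont in c("rrna", "mito")) {
    idx <- which(cat_draw == cont)
    if (!length(idx)) next
    cname <- if (cont == "rrna") "rRNA" else "chrM"
    st <- sample.int(nchar(seqs[[cname]]) - rl + 1L, length(idx),
                     replace = TRUE) - 1L
    read_seq[idx] <- take_window(cname, st)
    truth_origin[idx] <- cont
    truth_contig[idx] <- cname
    truth_start[idx] <- st
  }
  idx <- which(cat_draw == "rep")
  if (length(idx)) {
    copy <- sample.int(2L, length(idx), replace = TRUE)
    rr <- sim$repeat_regions
    off <- sample.int(rr$end[1L] - rr$start[1L] - rl + 1L, length(idx),
                      replace = TRUE) - 1L
    st <- rr$start[copy] + off
    read_seq[idx] <- take_window("chrS", st)
    truth_origin[idx] <- "repeat"
    truth_contig[idx] <- "chrS"
    truth_start[idx] <- st
  }
  idx <- which(cat_draw == "bg")
  if (length(idx)) {
    blob <- random_dna(length(idx) * rl)
    read_seq[idx] <- substring(blob, (seq_along(idx) - 1L) * rl + 1L,
                               seq_along(idx) * rl)
    truth_origin[idx] <- "background"
  }
  gidx <- which(cat_draw == "gene")
  if (length(gidx)) {
    lens <- cdna_length(ann, include_utrs = TRUE)[ids]
    short <- lens < rl
    if (any(short)) stop("configuration error: transcript(s) shorter than read_length")
    tw <- abund * lens
    tid <- sample(ids, length(gidx), replace = TRUE, prob = tw)
    for (g in unique(tid)) {
      ridx <- gidx[tid == g]
      lay <- transcript_layout(ann, g)
      L <- lay$length
      max_start <- L - rl
      piece_bounds <- c(lay$pieces$t0, L)
      piece_is_utr <- lay$pieces$region %in% c("utr5", "utr3")
      exon_bounds <- c(lay$exons$t0, L)
      need <- length(ridx)
      acc <- integer(0)
      stale <- 0L
      while (length(acc) < need) {
        m <- max(2L * (need - length(acc)), 32L)
        x <- draw_fragment_starts(m, max_start, cfg, L)
        p <- exp(-cfg$three_prime_decay * x / 1000)
        pc <- findInterval(x, piece_bounds, rightmost.closed = FALSE)
        p <- p * ifelse(piece_is_utr[pc], cfg$utr_weight, 1)
        keep <- stats::runif(m) < p
        # junction fragments are re-drawn: start and last base in same exon
        e1 <- findInterval(x, exon_bounds)
        e2 <- findInterval(x + rl - 1L, exon_bounds)
        keep <- keep & (e1 == e2)
        if (!any(keep)) {
          stale <- stale + 1L
          if (stale > 200L) {
            stop("configuration error: acceptance probability is zero for ", g)
          }
          next
        }
        stale <- 0L
        acc <- c(acc, x[keep])
      }
      acc <- acc[seq_len(need)]
      ei <- findInterval(acc, exon_bounds)
      t0 <- lay$exons$t0[ei]
      gstart <- if (lay$strand == "+") {
        lay$exons$gstart[ei] + (acc - t0)
      } else {
        lay$exons$gend[ei] - (acc - t0) - rl
      }
      read_seq[ridx] <- take_window(lay$contig, gstart)
      truth_origin[ridx] <- g
      truth_contig[ridx] <- lay$contig
      truth_start[ridx] <- gstart
    }
  }
  # the library has no strand information: flip half the tags
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    read_seq[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(read_seq[flip])))
  }
  read_id <- sprintf("read_%06d", seq_len(n))
  reads <- Biostrings::DNAStringSet(read_seq)
  names(reads) <- read_id
  truth <- data.frame(
    read_id = read_id,
    origin = truth_origin,
    origin_class = ifelse(truth_origin %in% c("rrna", "mito", "repeat",
                                              "background"),
                          truth_origin, "gene"),
    contig = truth_contig,
    start = truth_start)
  structure(list(reads = reads, truth = truth, abundance = abund,
                 config = cfg), class = "sim_reads")
}

#' Expected tag class for each simulated read
#'
#' Maps the generator's truth origins onto the four alignment classes:
#' gene tags are expected `unique`, rRNA/mito tags `rrna_mito`, duplicated
#' segment tags `repeat` and background tags `nomatch`.
#'
#' @param truth The `truth` data frame of a `sim_reads` object.
#' @return Character vector of expected classes, named by read id.
#' @export
truth_tag_class <- function(truth) {
  cls <- c(gene = "unique", rrna = "rrna_mito", mito = "rrna_mito",
           `repeat` = "repeat", background = "nomatch")
  stats::setNames(unname(cls[truth$origin_class]), truth$read_id)
}

#' Write a simulated dataset to disk
#'
#' Writes genome FASTA plus ref-class sidecar, annotation BED12, reads as
#' FASTA or FASTQ (constant quality `I`), and the truth table as TSV.
#'
#' @param sim A `sim_genome`.
#' @param reads A `sim_reads`.
#' @param dir Output directory (created if missing).
#' @param format `"fasta"` or `"fastq"` for the reads.
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, reads, dir, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             classes = file.path(dir, "genome.classes.tsv"),
             annotation = file.path(dir, "annotation.bed"),
             reads = file.path(dir, paste0("reads.", substr(format, 1, 2),
                                           if (format == "fasta") "" else "q")),
             truth = file.path(dir, "truth.tsv"))
  paths[["reads"]] <- file.path(dir, if (format == "fasta") "reads.fa" else "reads.fq")
  write_genome(sim$contigs, paths[["genome"]], paths[["classes"]])
  write_annotation(sim$annotation, paths[["annotation"]])
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads$reads, paths[["reads"]])
  } else {
    q <- Biostrings::BStringSet(strrep("I", S4Vectors::width(reads$reads)))
    Biostrings::writeXStringSet(reads$reads, paths[["reads"]], format = "fastq",
                                qualities = q)
  }
  utils::write.table(reads$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
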