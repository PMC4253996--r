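#' Build a transcript set
#'
#' The package represents a set of transcripts as a [GenomicRanges::GRangesList]
#' of exons, one element per transcript, named by transcript id, with
#' `gene_id` and `biotype` metadata columns on the list. Exons within a
#' transcript are sorted by start, pairwise non-overlapping, and share one
#' chromosome and strand. Strand `"*"` is a first-class value meaning
#' "no strand information" (the cascade's first filter removes such
#' transcripts).
#'
#' @param exons `GRangesList` of exons, names are transcript ids.
#' @param gene_id character vector of gene ids, one per transcript.
#' @param biotype character vector, one of `"known_mRNA"`, `"TE_mRNA"`,
#'   `"candidate"`.
#' @return A validated `GRangesList` with `gene_id` and `biotype` mcols.
#' @export
transcript_set <- function(exons, gene_id, biotype = "candidate") {
  if (!methods::is(exons, "GRangesList")) {
    exons <- methods::as(exons, "GRangesList")
  }
  n <- length(exons)
  gene_id <- rep_len(gene_id, n)
  biotype <- rep_len(biotype, n)
  exons <- methods::as(lapply(exons, function(g) sort(g, ignore.strand = TRUE)),
                       "GRangesList")
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(gene_id = gene_id,
                                                  biotype = biotype)
  validate_transcripts(exons)
  exons
}

#' Validate a transcript set
#'
#' Checks the invariants listed in [transcript_set()]. Stops with an
#' informative error on the first violation.
#'
#' @param tx transcript set (`GRangesList`).
#' @return `tx`, invisibly.
#' @export
validate_transcripts <- function(tx) {
  if (is.null(names(tx)) || anyDuplicated(names(tx)))
    stop("transcript ids must be unique and non-empty")
  if (any(lengths(tx) < 1)) stop("every transcript needs >= 1 exon")
  bad_bt <- setdiff(unique(S4Vectors::mcols(tx)$biotype),
                    c("known_mRNA", "TE_mRNA", "candidate"))
  if (length(bad_bt)) stop("unknown biotype: ", paste(bad_bt, collapse = ", "))
  chrom_per_tx <- lengths(unique(GenomicRanges::seqnames(tx)))
  if (any(chrom_per_tx != 1)) stop("exons of one transcript must share a chromosome")
  strand_per_tx <- lengths(unique(GenomicRanges::strand(tx)))
  if (any(strand_per_tx != 1)) stop("exons of one transcript must share a strand")
  ok <- vapply(seq_along(tx), function(i) {
    g <- tx[[i]]
    if (length(g) == 1) return(TRUE)
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    all(diff(s) > 0) && all(s[-1] > e[-length(e)])
  }, logical(1))
  if (!all(ok))
    stop("exons overlap or are unsorted in: ",
         paste(names(tx)[!ok], collapse = ", "))
  invisible(tx)
}

#' Transcript accessors
#'
#' Small helpers over a transcript set: ids, spans (one `GRanges` of the
#' genomic extent per transcript, metadata carried over), strands, exon
#' counts and spliced lengths (sum of exon widths).
#'
#' @param tx transcript set.
#' @return `tx_ids()`: character; `tx_spans()`: `GRanges`; `tx_strand()`:
#'   character; `tx_n_exons()`, `tx_lengths()`: integer.
#' @export
tx_ids <- function(tx) names(tx)

#' @rdname tx_ids
#' @export
tx_spans <- function(tx) {
  # exons are validated sorted and non-overlapping, so the span is simply
  # first exon start to last exon end (much cheaper than range() per element)
  ex <- unlist(tx, use.names = FALSE)
  last <- cumsum(lengths(tx))
  first <- last - lengths(tx) + 1L
  sp <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(ex))[first],
    IRanges::IRanges(GenomicRanges::start(ex)[first],
                     GenomicRanges::end(ex)[last]),
    strand = as.character(GenomicRanges::strand(ex))[first])
  names(sp) <- names(tx)
  S4Vectors::mcols(sp) <- S4Vectors::mcols(tx)
  sp
}

#' @rdname tx_ids
#' @export
tx_strand <- function(tx) {
  # first exon's strand; the validator guarantees one strand per transcript
  first <- cumsum(lengths(tx)) - lengths(tx) + 1L
  as.character(GenomicRanges::strand(unlist(tx, use.names = FALSE)))[first]
}

#' @rdname tx_ids
#' @export
tx_n_exons <- function(tx) unname(lengths(tx))

#' @rdname tx_ids
#' @export
tx_lengths <- function(tx) unname(sum(GenomicRanges::width(tx)))

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in transcript order and reverse-complements
#' minus-strand transcripts, yielding the 5'-to-3' spliced sequence.
#' Unstranded transcripts are read off the plus strand.
#'
#' @param tx transcript set.
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @return `DNAStringSet` named by transcript id.
#' @export
spliced_seqs <- function(tx, genome) {
  strands <- tx_strand(tx)
  chrom_chars <- lapply(genome, as.character)  # decode each chromosome once
  out <- vapply(seq_along(tx), function(i) {
    g <- tx[[i]]
    chrom <- as.character(GenomicRanges::seqnames(g))[1]
    if (!chrom %in% names(chrom_chars))
      stop("chromosome not in genome: ", chrom)
    chrom_seq <- chrom_chars[[chrom]]
    if (max(GenomicRanges::end(g)) > nchar(chrom_seq))
      stop("exon outside genome bounds for transcript ", names(tx)[i])
    s <- paste(substring(chrom_seq, GenomicRanges::start(g),
                         GenomicRanges::end(g)), collapse = "")
    if (strands[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  names(out) <- names(tx)
  Biostrings::DNAStringSet(out)
}

# ---------------------------------------------------------------------------
# Readers / writers. GTF and BED parsing is delegated to rtracklayer, which
# normalizes the 1-based-inclusive (GTF) and 0-based-half-open (BED/bedGraph)
# dialects onto GRanges. Chromosome names are matched by exact string equality
# throughout; no "chr" prefix normalization is attempted.
# ---------------------------------------------------------------------------

#' Read transcripts from a GTF file
#'
#' Exon records are grouped by `transcript_id` into a transcript set.
#' Strand `"."` is preserved as `"*"` (unstranded). Transcripts are ordered
#' deterministically by (chromosome, start, id).
#'
#' @param path GTF file path.
#' @return transcript set (see [transcript_set()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    empty <- GenomicRanges::GRangesList()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(gene_id = character(0),
                                                    biotype = character(0))
    return(empty)
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF exon records missing transcript_id in ", path)
  biotype <- if (!is.null(gr$biotype)) gr$biotype else rep("candidate", length(gr))
  split_id <- factor(gr$transcript_id, levels = unique(gr$transcript_id))
  exons <- GenomicRanges::split(granges_only(gr), split_id)
  meta_first <- !duplicated(gr$transcript_id)
  tx <- transcript_set(exons,
                       gene_id = gr$gene_id[meta_first],
                       biotype = biotype[meta_first])
  sort_transcripts(tx)
}

granges_only <- function(gr) {
  S4Vectors::mcols(gr) <- NULL
  gr
}

sort_transcripts <- function(tx) {
  sp <- tx_spans(tx)
  ord <- order(as.character(GenomicRanges::seqnames(sp)),
               GenomicRanges::start(sp), names(tx))
  tx[ord]
}

#' Write transcripts to a GTF file
#'
#' Emits one exon record per exon, 1-based inclusive, with `transcript_id`,
#' `gene_id` and `biotype` attributes, in deterministic
#' (chromosome, start, id) order.
#'
#' @param tx transcript set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path) {
  tx <- sort_transcripts(tx)
  gr <- unlist(tx, use.names = FALSE)
  per_tx <- lengths(tx)
  gr$source <- "ricelnc"
  gr$type <- "exon"
  gr$transcript_id <- rep(names(tx), per_tx)
  gr$gene_id <- rep(S4Vectors::mcols(tx)$gene_id, per_tx)
  gr$biotype <- rep(S4Vectors::mcols(tx)$biotype, per_tx)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Sequences are uppercased; multi-line records are concatenated; headers are
#' trimmed to their first whitespace-delimited token. Duplicate headers are an
#' error.
#'
#' @param path FASTA path.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA header in ", path)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' @rdname read_fasta
#' @param seqs `DNAStringSet`/`RNAStringSet` or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED's 0-based half-open records become 1-based closed `GRanges`.
#'
#' @param path BED path.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param gr `GRanges` to write.
#' @export
write_bed <- function(gr, path) {
  gr <- sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Per-base conservation track
#'
#' A conservation track stores, per chromosome, one score in `[0, 1]` per
#' base, with `NA` meaning "position not aligned in the multiple-genome
#' alignment". `cons_track()` builds one from a named list of numeric
#' vectors; `read_bedgraph()` expands a bedGraph file (0-based half-open
#' intervals) onto per-base vectors, leaving uncovered positions `NA`;
#' `write_bedgraph()` is its inverse (NA runs are omitted).
#'
#' @param scores named list of numeric vectors (`NA` = unaligned).
#' @return object of class `cons_track`.
#' @export
cons_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  for (chrom in names(scores)) {
    v <- scores[[chrom]]
    if (!is.numeric(v)) stop("track for ", chrom, " must be numeric")
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) stop("conservation score outside [0,1] on ", chrom)
  }
  structure(scores, class = "cons_track")
}

#' @rdname cons_track
#' @param path bedGraph path.
#' @param seqlengths named integer vector of chromosome lengths.
#' @export
read_bedgraph <- function(path, seqlengths) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && (min(gr$score) < 0 || max(gr$score) > 1))
    stop("bedGraph score outside [0,1] in ", path)
  out <- lapply(names(seqlengths), function(chrom) {
    v <- rep(NA_real_, seqlengths[[chrom]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (length(g)) {
      if (max(GenomicRanges::end(g)) > length(v))
        stop("bedGraph record beyond chromosome end on ", chrom)
      w <- GenomicRanges::width(g)
      pos <- sequence(w) + rep(GenomicRanges::start(g), w) - 1L
      v[pos] <- rep(g$score, w)
    }
    v
  })
  names(out) <- names(seqlengths)
  cons_track(out)
}

#' @rdname cons_track
#' @param track `cons_track`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    v[is.na(v)] <- -1  # sentinel: rle cannot compare NA runs
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values >= 0
    if (any(keep))
      writeLines(paste(chrom, starts[keep] - 1L, ends[keep],
                       formatC(r$values[keep], format = "g", digits = 15),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write an FPKM expression matrix
#'
#' Tab-separated, one header row of sample ids, first column `transcript_id`.
#' Values are non-negative FPKM. Duplicate transcript rows are an error.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = transcript ids, colnames = sample ids.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "transcript_id")
    stop("expression table must start with a transcript_id column")
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript row in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  if (any(m < 0)) stop("negative FPKM in ", path)
  m
}

#' @rdname read_expression
#' @param m expression matrix.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap length of two genomic intervals
#'
#' Number of shared bases between two `GRanges` (recycled pairwise).
#' Intervals on different chromosomes overlap by 0 bases. With
#' `stranded = TRUE`, intervals on different (or unknown) strands overlap by
#' 0 bases.
#'
#' @param a,b `GRanges`.
#' @param stranded require equal, known strands for a non-zero overlap.
#' @return integer vector of overlap lengths in bases.
#' @export
interval_overlap <- function(a, b, stranded = FALSE) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  w <- pmax(0L, pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
              pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L)
  w[as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))] <- 0L
  if (stranded) {
    sa <- as.character(GenomicRanges::strand(a))
    sb <- as.character(GenomicRanges::strand(b))
    w[sa != sb | sa == "*" | sb == "*"] <- 0L
  }
  w
}

#' Format a count as a percentage the way summaries report it
#'
#' `100 * count / total`, rounded to `digits` decimals with R's
#' round-half-even rule (the convention used in all summary tables).
#'
#' @param count,total numeric.
#' @param digits decimals to keep (default 1).
#' @return numeric percentage.
#' @export
percent_of <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}
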