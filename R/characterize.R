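# Genomic, sequence and conservation statistics over feature sets.

#' Exon-structure statistics for a transcript set
#'
#' @param tx non-empty transcript set.
#' @return list: `exon_count_table` (counts per exon number), `mean_exons`,
#'   `median_exon_length`, `median_tx_length`, `spliced_fraction`
#'   (proportion of transcripts with >= 2 exons).
#' @export
exon_stats <- function(tx) {
  if (!length(tx)) stop("empty transcript set")
  ne <- tx_n_exons(tx)
  exon_lens <- GenomicRanges::width(unlist(tx, use.names = FALSE))
  list(exon_count_table = table(ne),
       mean_exons = mean(ne),
       median_exon_length = stats::median(exon_lens),
       median_tx_length = stats::median(tx_lengths(tx)),
       spliced_fraction = mean(ne >= 2))
}

#' A/U content of sequences
#'
#' Fraction of A plus T/U over sequence length, computed on the transcribed
#' sense (supply spliced sequences from [spliced_seqs()], which
#' reverse-complements minus-strand transcripts). `N` bases are excluded
#' from both numerator and denominator.
#'
#' @param seqs `DNAStringSet`/`RNAStringSet` or character vector.
#' @return numeric vector of fractions in `[0, 1]`, one per sequence.
#' @export
au_content <- function(seqs) {
  s <- toupper(as.character(seqs))
  vapply(s, function(x) {
    ch <- strsplit(x, "")[[1]]
    ch <- ch[ch != "N"]
    if (!length(ch)) stop("sequence has zero length after N removal")
    mean(ch %in% c("A", "T", "U"))
  }, numeric(1), USE.NAMES = !is.null(names(s)))
}

#' Repeat overlap of a transcript set
#'
#' Transcript fraction: proportion of transcripts with at least one exonic
#' base inside a repeat. Base fraction: overlapped exonic bases (union
#' semantics) over all exonic bases. Both strand-agnostic, since repeat
#' annotations are usually strandless.
#'
#' @param tx transcript set.
#' @param repeats `GRanges` of repeat loci.
#' @return list: `transcript_fraction`, `base_fraction`.
#' @export
repeat_overlap <- function(tx, repeats) {
  repeats <- GenomicRanges::reduce(granges_only(repeats), ignore.strand = TRUE)
  per_tx_bases <- vapply(seq_along(tx), function(i) {
    ov <- GenomicRanges::intersect(granges_only(tx[[i]]), repeats,
                                   ignore.strand = TRUE)
    sum(GenomicRanges::width(ov))
  }, integer(1))
  list(transcript_fraction = mean(per_tx_bases > 0),
       base_fraction = sum(per_tx_bases) / sum(tx_lengths(tx)))
}

#' Small-RNA locus overlap of a transcript set
#'
#' A transcript "generates sRNAs" iff at least one exonic base overlaps an
#' sRNA locus. Strand-agnostic by default; set `stranded = TRUE` to require
#' the locus on the transcript's strand (sRNA derivation is
#' strand-informative when the loci carry strands).
#'
#' @param tx transcript set.
#' @param srna_loci `GRanges` of sRNA-producing loci.
#' @param stranded require same-strand overlap.
#' @return list: `count`, `fraction`, `percent` (1 decimal).
#' @export
srna_overlap <- function(tx, srna_loci, stranded = FALSE) {
  if (!length(tx)) stop("empty transcript set")
  if (!length(srna_loci)) {
    return(list(count = 0L, fraction = 0, percent = 0))
  }
  ex <- unlist(tx, use.names = FALSE)
  ex$tx_idx <- rep(seq_along(tx), lengths(tx))
  hits <- GenomicRanges::findOverlaps(ex, srna_loci, ignore.strand = TRUE)
  keep <- rep(TRUE, length(hits))
  if (stranded) {
    sa <- as.character(GenomicRanges::strand(ex))[S4Vectors::queryHits(hits)]
    sb <- as.character(GenomicRanges::strand(srna_loci))[S4Vectors::subjectHits(hits)]
    keep <- sa == sb & sa != "*" & sb != "*"
  }
  n <- length(unique(ex$tx_idx[S4Vectors::queryHits(hits)[keep]]))
  list(count = n, fraction = n / length(tx),
       percent = percent_of(n, length(tx)))
}

track_values <- function(regions, track) {
  # per-base scores (NA = unaligned / beyond track) for a GRanges
  unlist(lapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    v <- track[[chrom]]
    if (is.null(v))
      return(rep(NA_real_, GenomicRanges::width(regions)[i]))
    idx <- GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]
    out <- rep(NA_real_, length(idx))
    inside <- idx >= 1 & idx <= length(v)
    out[inside] <- v[idx[inside]]
    out
  }), use.names = FALSE)
}

#' Fraction of region bases aligned in the conservation track
#'
#' "Aligned" means the position carries a score in the supplied per-base
#' track; positions outside the track are treated as unaligned.
#'
#' @param regions `GRanges`.
#' @param track `cons_track`.
#' @return fraction of bases with a present score.
#' @export
aligned_fraction <- function(regions, track) {
  v <- track_values(regions, track)
  if (!length(v)) stop("empty region set")
  mean(!is.na(v))
}

#' Per-feature mean conservation score
#'
#' For each feature (an element of a `GRangesList`, e.g. the exons of one
#' transcript, or a single `GRanges` interval) returns the mean score over
#' aligned bases, `NA` if the feature has no aligned base. The cumulative
#' distribution is computed over non-missing features.
#'
#' @param features `GRangesList` (region set per feature) or `GRanges`.
#' @param track `cons_track`.
#' @return list: `mean_scores` (named numeric, `NA` = no aligned base),
#'   `cdf` (an [stats::ecdf] over non-missing features, `NULL` if none).
#' @export
mean_conservation <- function(features, track) {
  if (methods::is(features, "GRanges"))
    features <- methods::as(S4Vectors::split(features, seq_along(features)),
                            "GRangesList")
  ms <- vapply(seq_along(features), function(i) {
    v <- track_values(features[[i]], track)
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  names(ms) <- names(features)
  list(mean_scores = ms,
       cdf = if (any(!is.na(ms))) stats::ecdf(ms[!is.na(ms)]) else NULL)
}

#' Conserved elements within regions
#'
#' Maximal runs of at least `min_len` consecutive bases, each aligned with a
#' score `>= min_score`, restricted to the supplied regions. The thresholds
#' (15 bp, 0.8) define "short conserved region" for this package and are
#' configurable.
#'
#' @param regions `GRanges` to scan.
#' @param track `cons_track`.
#' @param min_len minimum run length in bases.
#' @param min_score minimum per-base score.
#' @return `GRanges` of non-overlapping elements, sorted.
#' @export
conserved_elements <- function(regions, track, min_len = 15, min_score = 0.8) {
  stopifnot(min_len > 0, min_score > 0)
  regions <- GenomicRanges::reduce(granges_only(regions), ignore.strand = TRUE)
  out <- GenomicRanges::GRanges()
  for (i in seq_along(regions)) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    v <- track_values(regions[i], track)
    good <- !is.na(v) & v >= min_score
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_len)
    if (length(hit)) {
      off <- GenomicRanges::start(regions)[i] - 1L
      out <- c(out, GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts[hit] + off, ends[hit] + off)))
    }
  }
  sort(out, ignore.strand = TRUE)
}

#' Summarize the characterization statistics of one feature set
#'
#' Convenience wrapper producing one row of summary statistics for a named
#' transcript set, as used by the pipeline report.
#'
#' @param tx transcript set.
#' @param genome named `DNAStringSet`.
#' @param repeats,srna_loci `GRanges` (optional).
#' @param track `cons_track` (optional).
#' @return one-row data.frame of the headline statistics.
#' @export
characterize_set <- function(tx, genome, repeats = NULL, srna_loci = NULL,
                             track = NULL) {
  es <- exon_stats(tx)
  au <- mean(au_content(spliced_seqs(tx, genome)))
  row <- data.frame(n = length(tx),
                    mean_exons = es$mean_exons,
                    median_exon_length = es$median_exon_length,
                    median_tx_length = es$median_tx_length,
                    spliced_pct = percent_of(sum(tx_n_exons(tx) >= 2), length(tx)),
                    mean_au = au)
  if (!is.null(repeats)) {
    ro <- repeat_overlap(tx, repeats)
    row$repeat_tx_pct <- percent_of(round(ro$transcript_fraction * length(tx)),
                                    length(tx))
    row$repeat_base_fraction <- ro$base_fraction
  }
  if (!is.null(srna_loci)) {
    so <- srna_overlap(tx, srna_loci)
    row$srna_count <- so$count
    row$srna_pct <- so$percent
  }
  if (!is.null(track)) {
    ex <- unlist(tx, use.names = FALSE)
    row$aligned_fraction <- aligned_fraction(ex, track)
    mc <- mean_conservation(tx, track)
    row$mean_cons <- mean(mc$mean_scores, na.rm = TRUE)
  }
  row
}
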