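# The identification filter cascade. Each filter is a pure predicate over the
# full candidate set, so the final kept set is order-independent; the report's
# "first failed filter" follows the fixed cascade order below.

FILTER_ORDER <- c("strand", "sense_overlap", "length", "expression",
                  "proximity", "coding")

#' Filter: discard transcripts without strand information
#'
#' @param tx candidate transcript set.
#' @return named logical vector, `TRUE` = kept.
#' @export
filter_strandless <- function(tx) {
  keep <- tx_strand(tx) %in% c("+", "-")
  stats::setNames(keep, names(tx))
}

#' Filter: discard candidates overlapping known genes in sense
#'
#' A candidate is discarded iff at least one of its exons shares >= 1 base
#' with an exon of any known (annotated) gene on the same strand. Antisense
#' overlap does not discard (those candidates are the lncNAT pool).
#' Unstranded features never count as same-strand.
#'
#' @param tx candidate transcript set.
#' @param known annotated transcript set (including TE-related mRNAs).
#' @return named logical vector, `TRUE` = kept.
#' @export
filter_sense_overlap <- function(tx, known) {
  cand_ex <- unlist(tx, use.names = FALSE)
  cand_ex$tx_idx <- rep(seq_along(tx), lengths(tx))
  known_ex <- unlist(known, use.names = FALSE)
  hits <- GenomicRanges::findOverlaps(cand_ex, known_ex, ignore.strand = TRUE)
  sa <- as.character(GenomicRanges::strand(cand_ex))[S4Vectors::queryHits(hits)]
  sb <- as.character(GenomicRanges::strand(known_ex))[S4Vectors::subjectHits(hits)]
  sense <- sa == sb & sa != "*" & sb != "*"
  bad <- unique(cand_ex$tx_idx[S4Vectors::queryHits(hits)[sense]])
  keep <- rep(TRUE, length(tx))
  keep[bad] <- FALSE
  stats::setNames(keep, names(tx))
}

#' Filter: discard short transcripts
#'
#' Transcript length is the sum of exon lengths; transcripts shorter than
#' `min_len` nucleotides are discarded (length exactly `min_len` is kept).
#'
#' @param tx candidate transcript set.
#' @param min_len minimum spliced length in nucleotides (default 200).
#' @return named logical vector, `TRUE` = kept.
#' @export
filter_length <- function(tx, min_len = 200) {
  stats::setNames(tx_lengths(tx) >= min_len, names(tx))
}

#' Filter: discard infrequently expressed transcripts
#'
#' Multi-exon candidates are kept iff their maximum FPKM across samples is
#' `>= multi_min` (default 0.5); single-exon candidates need `>= single_min`
#' (default 2). "Below threshold in all samples" and "maximum across samples
#' below threshold" are the same predicate; it is implemented once as a
#' max-over-samples test.
#'
#' @param tx candidate transcript set.
#' @param fpkm expression matrix (see [read_expression()]).
#' @param multi_min,single_min FPKM thresholds.
#' @return named logical vector, `TRUE` = kept.
#' @export
filter_expression <- function(tx, fpkm, multi_min = 0.5, single_min = 2) {
  missing <- setdiff(names(tx), rownames(fpkm))
  if (length(missing))
    stop("candidates absent from expression matrix: ",
         paste(missing, collapse = ", "))
  mx <- apply(fpkm[names(tx), , drop = FALSE], 1, max)
  thr <- ifelse(tx_n_exons(tx) >= 2, multi_min, single_min)
  stats::setNames(unname(mx) >= thr, names(tx))
}

#' Filter: discard single-exon candidates close to other transcripts
#'
#' A single-exon candidate is discarded iff any other transcript (annotated
#' gene or other candidate) on the same strand overlaps it or lies within
#' `window` bases of it. "Sense direction" is read as same-strand: assembly
#' fragments of one transcript share its strand. Multi-exon candidates are
#' unaffected.
#'
#' @param tx candidate transcript set.
#' @param all_tx transcript set of everything the gap is measured against
#'   (annotation plus all candidates; a candidate is never compared with
#'   itself).
#' @param window maximum gap in bases (default 500).
#' @return named logical vector, `TRUE` = kept.
#' @export
filter_single_exon_proximity <- function(tx, all_tx, window = 500) {
  gaps <- min_sense_gap(tx, all_tx)
  single <- tx_n_exons(tx) == 1
  keep <- !(single & !is.na(gaps) & gaps <= window)
  stats::setNames(keep, names(tx))
}

#' Minimum gap to the nearest same-strand transcript
#'
#' Gap in bases between transcript spans (0 when overlapping or adjacent),
#' `NA` when no same-strand transcript exists on the chromosome. A candidate
#' present in `all_tx` under the same id is not compared with itself.
#'
#' @inheritParams filter_single_exon_proximity
#' @return named numeric vector of gaps.
#' @export
min_sense_gap <- function(tx, all_tx) {
  sp <- tx_spans(tx)
  all_sp <- tx_spans(all_tx)
  # plain-vector arithmetic: gap = bases strictly between the two spans
  q_chr <- as.character(GenomicRanges::seqnames(sp))
  q_str <- as.character(GenomicRanges::strand(sp))
  q_s <- GenomicRanges::start(sp); q_e <- GenomicRanges::end(sp)
  a_chr <- as.character(GenomicRanges::seqnames(all_sp))
  a_str <- as.character(GenomicRanges::strand(all_sp))
  a_s <- GenomicRanges::start(all_sp); a_e <- GenomicRanges::end(all_sp)
  vapply(seq_along(sp), function(i) {
    if (!q_str[i] %in% c("+", "-")) return(NA_real_)
    same <- a_str == q_str[i] & a_chr == q_chr[i] & names(all_sp) != names(sp)[i]
    if (!any(same)) return(NA_real_)
    min(pmax(0L, pmax(a_s[same] - q_e[i], q_s[i] - a_e[same]) - 1L))
  }, numeric(1)) |> stats::setNames(names(tx))
}

#' Longest open reading frame, in codons
#'
#' Scans the three forward frames of a sequence for ATG-initiated reading
#' frames; an ORF runs from ATG to the first in-frame stop (codons counted
#' excluding the stop) or, if no stop follows, to the end of the sequence
#' (an "open" ORF). Returns the maximum codon count over all frames, 0 if
#' no ATG exists.
#'
#' @param seq character or `DNAString` (the transcript's sense sequence).
#' @return integer, length of the longest ORF in codons.
#' @export
longest_orf_codons <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  best <- 0L
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    starts_at <- f + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, starts_at, starts_at + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(stops)) {
      nxt_idx <- findInterval(atg, stops) + 1L
      nxt <- c(stops, NA_integer_)[pmin(nxt_idx, length(stops) + 1L)]
    } else {
      nxt <- rep(NA_integer_, length(atg))
    }
    len <- ifelse(is.na(nxt), ncod - atg + 1L, nxt - atg)
    best <- max(best, len)
  }
  as.integer(best)
}

#' Filter: discard transcripts with protein-coding potential
#'
#' With an external score table (e.g. from a coding-potential classifier),
#' any transcript scoring > 0 is discarded, and any transcript listed in
#' `pfam_hits` (protein-domain matches) is additionally discarded. Without
#' external scores, a built-in surrogate discards transcripts whose spliced
#' sequence carries an ORF of `min_orf_codons` or more codons (default 100,
#' the conventional lncRNA cutoff) on the transcript strand.
#'
#' @param tx candidate transcript set.
#' @param genome named `DNAStringSet`.
#' @param cpc_scores optional named numeric vector of external coding scores.
#' @param pfam_hits optional character vector of transcript ids with protein
#'   domain hits.
#' @param min_orf_codons surrogate ORF threshold in codons.
#' @return named logical vector, `TRUE` = kept.
#' @export
coding_potential_filter <- function(tx, genome, cpc_scores = NULL,
                                    pfam_hits = NULL, min_orf_codons = 100) {
  if (!is.null(cpc_scores)) {
    sc <- cpc_scores[names(tx)]
    if (anyNA(sc))
      stop("external coding scores missing for: ",
           paste(names(tx)[is.na(sc)], collapse = ", "))
    keep <- sc <= 0
  } else {
    seqs <- spliced_seqs(tx, genome)
    orf <- vapply(as.character(seqs), longest_orf_codons, integer(1))
    keep <- orf < min_orf_codons
  }
  if (!is.null(pfam_hits)) keep <- keep & !(names(tx) %in% pfam_hits)
  stats::setNames(unname(keep), names(tx))
}

#' Run the full lncRNA identification cascade
#'
#' Applies, in order: strand filter, sense-overlap filter against the
#' annotation (including TE-related mRNAs), length filter, expression filter,
#' single-exon proximity filter, and coding-potential filter. Every filter is
#' evaluated on the full candidate set, so the kept set does not depend on
#' the order; the per-transcript report records the first failed filter in
#' cascade order, plus the values each filter looked at.
#'
#' @param candidates candidate transcript set (assembled transcriptome).
#' @param annotation annotated transcript set (`known_mRNA` and `TE_mRNA`).
#' @param genome named `DNAStringSet`.
#' @param fpkm expression matrix covering all candidates.
#' @param min_len,multi_min,single_min,window,min_orf_codons thresholds, see
#'   the individual filters.
#' @param cpc_scores,pfam_hits optional external coding-potential evidence.
#' @param disable character vector of filter names to switch off (used for
#'   ablation studies); subset of strand, sense_overlap, length, expression,
#'   proximity, coding.
#' @return list with `lncrna` (kept transcript set) and `report`
#'   (data.frame: id, verdict, discarding_filter, length, n_exons, max_fpkm,
#'   min_sense_gap, orf_codons).
#' @export
run_identification <- function(candidates, annotation, genome, fpkm,
                               min_len = 200, multi_min = 0.5, single_min = 2,
                               window = 500, min_orf_codons = 100,
                               cpc_scores = NULL, pfam_hits = NULL,
                               disable = character()) {
  bad <- setdiff(disable, FILTER_ORDER)
  if (length(bad)) stop("unknown filter name: ", paste(bad, collapse = ", "))
  if (!length(candidates)) {
    return(list(lncrna = candidates,
                report = data.frame(id = character(0), verdict = character(0),
                                    discarding_filter = character(0))))
  }
  all_tx <- suppressWarnings(c(annotation, candidates))
  gaps <- min_sense_gap(candidates, all_tx)
  single <- tx_n_exons(candidates) == 1
  orf <- if (is.null(cpc_scores)) {
    vapply(as.character(spliced_seqs(candidates, genome)),
           longest_orf_codons, integer(1))
  } else rep(NA_integer_, length(candidates))
  coding_keep <- if (is.null(cpc_scores)) {
    keep <- unname(orf) < min_orf_codons
    if (!is.null(pfam_hits)) keep <- keep & !(names(candidates) %in% pfam_hits)
    stats::setNames(keep, names(candidates))
  } else {
    coding_potential_filter(candidates, genome, cpc_scores, pfam_hits,
                            min_orf_codons)
  }
  verdicts <- list(
    strand = filter_strandless(candidates),
    sense_overlap = filter_sense_overlap(candidates, annotation),
    length = filter_length(candidates, min_len = min_len),
    expression = filter_expression(candidates, fpkm, multi_min, single_min),
    proximity = stats::setNames(!(single & !is.na(gaps) & gaps <= window),
                                names(candidates)),
    coding = coding_keep
  )
  for (f in disable) verdicts[[f]][] <- TRUE
  keep_mat <- do.call(cbind, verdicts[FILTER_ORDER])
  kept <- rowSums(!keep_mat) == 0
  first_fail <- apply(keep_mat, 1, function(row) {
    i <- which(!row)[1]
    if (is.na(i)) "" else FILTER_ORDER[i]
  })
  report <- data.frame(
    id = names(candidates),
    verdict = ifelse(kept, "kept", "discarded"),
    discarding_filter = unname(first_fail),
    length = tx_lengths(candidates),
    n_exons = tx_n_exons(candidates),
    max_fpkm = unname(apply(fpkm[names(candidates), , drop = FALSE], 1, max)),
    min_sense_gap = unname(gaps),
    orf_codons = unname(orf),
    stringsAsFactors = FALSE
  )
  attr(report, "filter_order") <- setdiff(FILTER_ORDER, disable)
  list(lncrna = candidates[kept], report = report)
}
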