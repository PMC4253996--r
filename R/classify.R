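# lincRNA / lncNAT classification and lincRNA-neighbor geometry.

#' Classify lncRNAs as lincRNA or lncNAT
#'
#' A lncRNA is a lncNAT iff at least one of its exons shares >= 1 base with
#' an exon of a (non-TE) protein-coding mRNA on the opposite strand;
#' otherwise it is a lincRNA. The overlap fraction is the base-union of
#' antisense-overlapped lncRNA exonic bases divided by the lncRNA's exonic
#' length, so fragmented mRNA exons are counted once. Intron-only antisense
#' nesting does not make a lncNAT.
#'
#' @param lnc lncRNA transcript set (survivors of the cascade).
#' @param mrna protein-coding transcript set; TE-related mRNAs must already
#'   be excluded.
#' @return data.frame: id, lnc_class (`"lincRNA"`/`"lncNAT"`),
#'   overlap_fraction in `[0, 1]`.
#' @export
classify_lnc <- function(lnc, mrna) {
  mrna_ex <- GenomicRanges::reduce(unlist(mrna, use.names = FALSE))
  lens <- tx_lengths(lnc)
  ov_bases <- vapply(seq_along(lnc), function(i) {
    ex <- lnc[[i]]
    s <- as.character(GenomicRanges::strand(ex))[1]
    if (!s %in% c("+", "-")) return(0L)
    anti <- mrna_ex[as.character(GenomicRanges::strand(mrna_ex)) ==
                      setdiff(c("+", "-"), s)]
    if (!length(anti)) return(0L)
    ov <- GenomicRanges::intersect(granges_only(ex), granges_only(anti),
                                   ignore.strand = TRUE)
    sum(GenomicRanges::width(ov))
  }, integer(1))
  frac <- ov_bases / lens
  data.frame(id = names(lnc),
             lnc_class = ifelse(frac > 0, "lncNAT", "lincRNA"),
             overlap_fraction = frac,
             stringsAsFactors = FALSE)
}

#' Closest protein-coding neighbor and mutual orientation
#'
#' For each query transcript, finds the closest coding gene on the same
#' chromosome by span gap, ignoring strand (purely positional search), ties
#' broken by the lexicographically smaller gene id. Orientation of the pair:
#' `tandem` when both features share a strand, `divergent` when the 5' ends
#' face each other across the gap (head-to-head), `convergent` when the 3'
#' ends face (tail-to-tail), and `overlapping` when the spans intersect.
#' With no coding gene on the chromosome, the neighbor is reported missing.
#'
#' @param query transcript set (typically lincRNAs) or a `GRanges` of spans.
#' @param coding transcript set of coding genes or a `GRanges` of spans.
#' @return data.frame: id, closest_gene, distance (gap in bases; 0 when
#'   overlapping or adjacent), orientation.
#' @export
neighbor_orientation <- function(query, coding) {
  qsp <- if (methods::is(query, "GRangesList")) tx_spans(query) else query
  gsp <- if (methods::is(coding, "GRangesList")) tx_spans(coding) else coding
  if (is.null(names(qsp)) || is.null(names(gsp)))
    stop("query and coding spans must be named")
  out <- lapply(seq_along(qsp), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(qsp))[i]
    on_chrom <- which(as.character(GenomicRanges::seqnames(gsp)) == chrom)
    if (!length(on_chrom))
      return(data.frame(id = names(qsp)[i], closest_gene = NA_character_,
                        distance = NA_real_, orientation = NA_character_,
                        stringsAsFactors = FALSE))
    d <- GenomicRanges::distance(qsp[i], gsp[on_chrom], ignore.strand = TRUE)
    best <- on_chrom[d == min(d)]
    best <- best[order(names(gsp)[best])][1]
    data.frame(id = names(qsp)[i], closest_gene = names(gsp)[best],
               distance = min(d),
               orientation = pair_orientation(qsp[i], gsp[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

pair_orientation <- function(a, b) {
  sa <- as.character(GenomicRanges::strand(a))
  sb <- as.character(GenomicRanges::strand(b))
  if (GenomicRanges::start(b) <= GenomicRanges::end(a) &&
      GenomicRanges::end(b) >= GenomicRanges::start(a))
    return("overlapping")
  if (sa == sb) return("tandem")
  if (!all(c(sa, sb) %in% c("+", "-"))) return(NA_character_)
  b_left <- GenomicRanges::end(b) < GenomicRanges::start(a)
  # 5' ends face each other <=> the left feature runs leftward (-) and the
  # right feature runs rightward (+)
  left_strand <- if (b_left) sb else sa
  if (left_strand == "-") "divergent" else "convergent"
}
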