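# Mapping insertional-mutant flanking sequence tags (FSTs) to lincRNA
# bodies and 1-kb upstream (promoter-proxy) regions.

#' Percent identity of the optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with unit match/mismatch scores (+1/-1)
#' and a linear gap penalty of -2 (the target space is small, so exact
#' alignment is affordable); identity is matches over alignment columns,
#' in percent. Symmetric in the order of its arguments and invariant under
#' reverse-complementing both.
#'
#' @param a,b character or `DNAString` sequences.
#' @return list: `identity` (percent), `score`, `pattern_range`,
#'   `subject_range` (aligned coordinate ranges on `a` and `b`).
#' @export
fst_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(a)),
    Biostrings::DNAString(as.character(b)),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 0, gapExtension = 2)
  list(identity = Biostrings::pid(aln, type = "PID1"),
       score = BiocGenerics::score(aln),
       pattern_range = c(start(Biostrings::pattern(aln)),
                         end(Biostrings::pattern(aln))),
       subject_range = c(start(Biostrings::subject(aln)),
                         end(Biostrings::subject(aln))))
}

#' Read flanking sequence tags with database labels
#'
#' FASTA whose description carries a `db=<label>` token (the mutant
#' database the tag came from).
#'
#' @param path FASTA path.
#' @return `DNAStringSet` named by mutant id with a `database` metadata
#'   column.
#' @export
read_fsts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  full <- names(seqs)
  ids <- sub("\\s.*$", "", full)
  db <- ifelse(grepl("db=", full), sub(".*db=(\\S+).*", "\\1", full),
               NA_character_)
  names(seqs) <- ids
  S4Vectors::mcols(seqs)$database <- db
  seqs
}

#' Map flanking sequence tags to lincRNAs and their upstream regions
#'
#' Each lincRNA contributes one genomic search stretch: its span extended by
#' `upstream_len` bases on its 5' side (promoter proxy). Each FST is aligned
#' locally against every stretch in both orientations; hits are retained
#' when percent identity strictly exceeds `min_identity` and the alignment
#' covers at least `min_coverage` of the FST (a short perfect k-mer match is
#' 100% identical but is not an insertion-site hit). A hit is `internal`
#' when the FST's 5'-end genomic position falls inside the transcript span
#' and `upstream` when it falls in the upstream interval; hits spanning the
#' boundary are classified by the 5' end alone. One FST may hit several
#' lincRNAs; all hits are reported.
#'
#' @param fsts `DNAStringSet` from [read_fsts()] (or any named
#'   `DNAStringSet`; database labels default to `NA`).
#' @param linc stranded lincRNA transcript set.
#' @param genome named `DNAStringSet`.
#' @param upstream_len upstream region length (default 1000).
#' @param min_identity identity threshold, percent, strict (default 90).
#' @param min_coverage minimum aligned fraction of the FST (default 0.8).
#' @return data.frame: mutant_id, database, lincrna_id, region, identity,
#'   aln_start, aln_end (genomic), orientation.
#' @export
map_fst <- function(fsts, linc, genome, upstream_len = 1000,
                    min_identity = 90, min_coverage = 0.8) {
  sp <- tx_spans(linc)
  strands <- tx_strand(linc)
  if (any(!strands %in% c("+", "-")))
    stop("FST mapping requires stranded lincRNAs")
  db <- S4Vectors::mcols(fsts)$database
  if (is.null(db)) db <- rep(NA_character_, length(fsts))
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  fst_fwd <- Biostrings::DNAStringSet(stats::setNames(as.character(fsts),
                                                      names(fsts)))
  fst_rev <- Biostrings::reverseComplement(fst_fwd)
  fl <- Biostrings::width(fst_fwd)
  hits <- list()
  for (j in seq_along(linc)) {
    chrom <- as.character(GenomicRanges::seqnames(sp))[j]
    span <- c(GenomicRanges::start(sp)[j], GenomicRanges::end(sp)[j])
    if (strands[j] == "+") {
      stretch <- c(max(1L, span[1] - upstream_len), span[2])
      up_iv <- c(stretch[1], span[1] - 1L)
    } else {
      chrom_len <- length(genome[[chrom]])
      stretch <- c(span[1], min(chrom_len, span[2] + upstream_len))
      up_iv <- c(span[2] + 1L, stretch[2])
    }
    subject <- Biostrings::subseq(genome[[chrom]], stretch[1], stretch[2])
    for (ori in c("+", "-")) {
      pats <- if (ori == "+") fst_fwd else fst_rev
      aln <- Biostrings::pairwiseAlignment(pats, subject, type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 0, gapExtension = 2)
      idn <- Biostrings::pid(aln, type = "PID1")
      p_s <- start(Biostrings::pattern(aln)); p_e <- end(Biostrings::pattern(aln))
      cov <- (p_e - p_s + 1) / fl
      for (i in which(idn > min_identity & cov >= min_coverage)) {
        s_rng <- stretch[1] - 1L +
          c(start(Biostrings::subject(aln))[i],
            end(Biostrings::subject(aln))[i])
        # genomic position of the FST 5' end, extrapolated past any clipped
        # leading bases
        five_prime <- if (ori == "+") s_rng[1] - (p_s[i] - 1L)
                      else s_rng[2] + (p_s[i] - 1L)
        region <- if (five_prime >= span[1] && five_prime <= span[2])
          "internal"
        else if (five_prime >= up_iv[1] && five_prime <= up_iv[2])
          "upstream"
        else next
        hits[[length(hits) + 1L]] <- data.frame(
          mutant_id = names(fsts)[i], database = db[i],
          lincrna_id = names(sp)[j], region = region,
          identity = idn[i], aln_start = s_rng[1], aln_end = s_rng[2],
          orientation = ori, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(mutant_id = character(0), database = character(0),
                      lincrna_id = character(0), region = character(0),
                      identity = numeric(0), aln_start = integer(0),
                      aln_end = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  # keep the better orientation when both pass for the same pair
  out <- out[order(out$mutant_id, out$lincrna_id, -out$identity), ]
  out <- out[!duplicated(out[, c("mutant_id", "lincrna_id")]), ]
  rownames(out) <- NULL
  out[order(out$mutant_id, out$lincrna_id), , drop = FALSE]
}

#' Per-database mutant counts
#'
#' Summarizes FST hits the way mutant-resource tables report them: per
#' database, the number of distinct mutants and distinct lincRNAs, split
#' into transcribed-region (internal) and promoter-region (upstream) hits.
#'
#' @param hits data.frame from [map_fst()].
#' @param databases optional character vector fixing the rows (defaults to
#'   the databases present).
#' @return data.frame, one row per database plus a `total` row.
#' @export
tabulate_mutants <- function(hits, databases = NULL) {
  if (is.null(databases)) databases <- sort(unique(hits$database))
  count <- function(df)
    c(mutants = length(unique(df$mutant_id)),
      lincRNAs = length(unique(df$lincrna_id)))
  rows <- lapply(databases, function(d) {
    h <- hits[!is.na(hits$database) & hits$database == d, , drop = FALSE]
    int <- count(h[h$region == "internal", , drop = FALSE])
    ups <- count(h[h$region == "upstream", , drop = FALSE])
    data.frame(database = d,
               mutants_internal = int[["mutants"]],
               lincRNAs_internal = int[["lincRNAs"]],
               mutants_upstream = ups[["mutants"]],
               lincRNAs_upstream = ups[["lincRNAs"]],
               mutants_total = length(unique(h$mutant_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(database = character(0), mutants_internal = integer(0),
                      lincRNAs_internal = integer(0),
                      mutants_upstream = integer(0),
                      lincRNAs_upstream = integer(0),
                      mutants_total = integer(0), stringsAsFactors = FALSE)
  tot <- data.frame(database = "total",
                    mutants_internal = length(unique(
                      hits$mutant_id[hits$region == "internal"])),
                    lincRNAs_internal = length(unique(
                      hits$lincrna_id[hits$region == "internal"])),
                    mutants_upstream = length(unique(
                      hits$mutant_id[hits$region == "upstream"])),
                    lincRNAs_upstream = length(unique(
                      hits$lincrna_id[hits$region == "upstream"])),
                    mutants_total = length(unique(hits$mutant_id)),
                    stringsAsFactors = FALSE)
  rbind(out, tot)
}
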