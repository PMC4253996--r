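# miRNA decoy (endogenous target mimic) site prediction. A decoy site pairs
# a miRNA along its whole length, antiparallel, with a short unpaired bulge
# on the target side opposite the miRNA's central region: the bulge prevents
# cleavage while the flanking pairing sequesters the miRNA.

#' Decoy (target-mimic) pairing rules
#'
#' Constants of the mimicry rule engine, all configurable: a `bulge_len`-nt
#' bulge on the target side, inserted opposite the miRNA central region
#' (after miRNA position `g` for `g` in `bulge_between`, counted from the
#' miRNA 5' end, default 9-11 i.e. the bulge sits between positions 9-12);
#' perfect Watson-Crick pairing at miRNA seed positions `seed_range`
#' (default 2-8); at most `max_edits` combined mismatches and G:U wobbles
#' elsewhere; no other insertions or deletions. Set `gu_as_match = TRUE`
#' to exempt G:U wobbles from the edit cap.
#'
#' @param bulge_len bulge length on the target, nt.
#' @param bulge_between miRNA positions after which the bulge may sit.
#' @param seed_range miRNA positions requiring perfect pairing.
#' @param max_edits cap on mismatches + wobbles outside the seed.
#' @param gu_as_match treat G:U as a full match.
#' @return list of rule constants.
#' @export
decoy_rules <- function(bulge_len = 3, bulge_between = 9:11,
                        seed_range = 2:8, max_edits = 3,
                        gu_as_match = FALSE) {
  stopifnot(bulge_len >= 1, all(bulge_between >= 1), max_edits >= 0)
  list(bulge_len = as.integer(bulge_len),
       bulge_between = as.integer(bulge_between),
       seed_range = as.integer(seed_range),
       max_edits = as.integer(max_edits),
       gu_as_match = isTRUE(gu_as_match))
}

to_rna <- function(x) {
  nm <- names(x)
  out <- chartr("Tt", "Uu", toupper(as.character(x)))
  names(out) <- nm
  out
}

# pair class of target base t vs miRNA base q (both 5'->3' sense):
# 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
pair_class <- function(t, q) {
  wc <- (q == "A" & t == "U") | (q == "U" & t == "A") |
    (q == "G" & t == "C") | (q == "C" & t == "G")
  gu <- (q == "G" & t == "U") | (q == "U" & t == "G")
  ifelse(wc, 2L, ifelse(gu, 1L, 0L))
}

# target window positions paired with miRNA positions 1..m for bulge after g:
# miRNA pos i pairs window pos L - i + 1 for i <= g, and L - i + 1 - b after
# the bulge; window positions L-g-b+1 .. L-g are the bulge.
window_map <- function(m, b, g) {
  i <- seq_len(m)
  L <- m + b
  ifelse(i <= g, L - i + 1L, L - i + 1L - b)
}

#' Predict miRNA decoy sites on lncRNA sequences
#'
#' Scans every window of length `|miRNA| + bulge` of each lncRNA (5'->3'
#' spliced sequence) and every admissible bulge placement, evaluating
#' antiparallel pairing under the supplied rules. One site is reported per
#' admissible window (the bulge placement with fewest mismatches + wobbles;
#' 5'-most on ties); overlapping windows are all reported. DNA input is
#' transcribed to RNA automatically.
#'
#' @param seqs named character vector / `DNAStringSet` / `RNAStringSet` of
#'   lncRNA spliced sequences.
#' @param mirnas named character vector / `RNAStringSet` of mature miRNA
#'   sequences, 5'->3', 19-24 nt.
#' @param rules rule constants from [decoy_rules()].
#' @return data.frame: lncrna_id, mirna_id, start, end (1-based positions on
#'   the spliced lncRNA), bulge_after (miRNA position preceding the bulge),
#'   bulge_seq, mismatches, wobbles, diagram (three-line pairing diagram).
#' @export
predict_decoy_sites <- function(seqs, mirnas, rules = decoy_rules()) {
  seqs <- to_rna(seqs)
  mirnas <- to_rna(mirnas)
  if (is.null(names(seqs)) || is.null(names(mirnas)))
    stop("seqs and mirnas must be named")
  if (any(nchar(mirnas) < 19))
    stop("miRNA shorter than 19 nt: ",
         paste(names(mirnas)[nchar(mirnas) < 19], collapse = ", "))
  bad <- grepl("[^ACGU]", mirnas)
  if (any(bad)) stop("miRNA sequence outside the A/C/G/U alphabet: ",
                     paste(names(mirnas)[bad], collapse = ", "))
  b <- rules$bulge_len
  res <- list()
  for (mi in names(mirnas)) {
    mir <- strsplit(mirnas[[mi]], "")[[1]]
    m <- length(mir)
    L <- m + b
    maps <- lapply(rules$bulge_between, function(g) window_map(m, b, g))
    seed_target <- L - rules$seed_range + 1L  # seed lies 3' of any bulge
    for (sid in names(seqs)) {
      sq <- strsplit(seqs[[sid]], "")[[1]]
      n <- length(sq)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      # vectorized seed pre-screen; only valid when every admissible bulge
      # sits 5' of the seed's window positions (the default geometry)
      seed_ok <- rep(TRUE, length(starts))
      if (min(rules$bulge_between) >= max(rules$seed_range)) {
        for (k in seq_along(rules$seed_range)) {
          i <- rules$seed_range[k]
          seed_ok <- seed_ok &
            pair_class(sq[starts + seed_target[k] - 1L], mir[i]) == 2L
        }
      }
      for (s in starts[seed_ok]) {
        w <- sq[s:(s + L - 1L)]
        best <- NULL
        for (gi in seq_along(rules$bulge_between)) {
          map <- maps[[gi]]
          cls <- pair_class(w[map], mir)
          non_seed <- setdiff(seq_len(m), rules$seed_range)
          if (any(cls[rules$seed_range] != 2L)) next
          mm <- sum(cls[non_seed] == 0L)
          wb <- sum(cls[non_seed] == 1L)
          edits <- if (rules$gu_as_match) mm else mm + wb
          if (edits > rules$max_edits) next
          if (is.null(best) || mm + wb < best$mm + best$wb) {
            g <- rules$bulge_between[gi]
            best <- list(g = g, mm = mm, wb = wb, cls = cls, map = map)
          }
        }
        if (!is.null(best)) {
          bulge_pos <- (L - best$g - b + 1L):(L - best$g)
          res[[length(res) + 1L]] <- data.frame(
            lncrna_id = sid, mirna_id = mi,
            start = s, end = s + L - 1L,
            bulge_after = best$g,
            bulge_seq = paste(w[bulge_pos], collapse = ""),
            mismatches = best$mm, wobbles = best$wb,
            diagram = pairing_diagram(w, mir, best$map, best$cls, bulge_pos),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      start = integer(0), end = integer(0),
                      bulge_after = integer(0), bulge_seq = character(0),
                      mismatches = integer(0), wobbles = integer(0),
                      diagram = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$lncrna_id, out$mirna_id, out$start), , drop = FALSE]
}

pairing_diagram <- function(w, mir, map, cls, bulge_pos) {
  L <- length(w)
  top <- paste(w, collapse = " ")
  mid <- rep(" ", L)
  bot <- rep(" ", L)
  mid[map] <- c("X", "o", "|")[cls + 1L]
  bot[map] <- mir
  mid[bulge_pos] <- "."
  bot[bulge_pos] <- "-"
  paste0("5' ", top, " 3'  (target)\n   ",
         paste(mid, collapse = " "), "\n3' ",
         paste(bot, collapse = " "), " 5'  (miRNA)")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a sequence preserving its exact dinucleotide
#' counts (Altschul-Erikson Euler-path shuffle): transition edges between
#' nucleotides are walked in random order, with the last-edge set
#' constrained to reach the terminal nucleotide. Used to build null
#' sequences for decoy-site false-positive controls.
#'
#' @param seq character (one sequence).
#' @param seed optional integer seed.
#' @return shuffled sequence, same length and dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(s)
  if (n <= 3) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- lapply(stats::setNames(verts, verts),
                  function(v) s[which(s[-n] == v) + 1L])
  last <- s[n]
  repeat {
    # pick a random final edge for every non-terminal vertex, then require
    # that following final edges from any vertex reaches the terminal one
    finals <- vapply(verts, function(v) {
      if (v == last) NA_character_ else sample(edges[[v]], 1)
    }, character(1))
    ok <- vapply(verts, function(v) {
      seen <- character(0)
      while (v != last && !(v %in% seen)) {
        seen <- c(seen, v)
        v <- finals[[v]]
      }
      v == last
    }, logical(1))
    if (all(ok)) break
  }
  shuffled <- lapply(stats::setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v == last) return(sample(e))
    fi <- match(finals[[v]], e)
    rest <- e[-fi]
    c(if (length(rest)) sample(rest) else character(0), finals[[v]])
  })
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  v <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Extract the 1-kb upstream (promoter-proxy) region of a transcript
#'
#' For a plus-strand transcript the upstream region is the `length` bases
#' preceding the span start; for a minus-strand transcript, the `length`
#' bases following the span end, reverse-complemented. Regions are truncated
#' at chromosome boundaries and flagged when truncated.
#'
#' @param tx stranded transcript set.
#' @param genome named `DNAStringSet`.
#' @param length upstream length in bases (default 1000).
#' @return list: `seqs` (`DNAStringSet`, 5'->3' on the transcript strand),
#'   `regions` (`GRanges` of the genomic intervals), `truncated` (logical).
#' @export
extract_upstream <- function(tx, genome, length = 1000) {
  sp <- tx_spans(tx)
  strands <- tx_strand(tx)
  if (any(!strands %in% c("+", "-")))
    stop("upstream extraction requires stranded transcripts")
  chroms <- as.character(GenomicRanges::seqnames(sp))
  chrom_len <- vapply(chroms, function(ch) length(genome[[ch]]), integer(1))
  up_start <- ifelse(strands == "+",
                     pmax(1L, GenomicRanges::start(sp) - length),
                     GenomicRanges::end(sp) + 1L)
  up_end <- ifelse(strands == "+",
                   GenomicRanges::start(sp) - 1L,
                   pmin(chrom_len, GenomicRanges::end(sp) + length))
  truncated <- (up_end - up_start + 1L) < length
  regions <- GenomicRanges::GRanges(chroms,
                                    IRanges::IRanges(up_start,
                                                     pmax(up_end, up_start - 1L)),
                                    strand = strands)
  names(regions) <- names(sp)
  seqs <- vapply(seq_along(regions), function(i) {
    if (GenomicRanges::width(regions)[i] == 0) return("")
    s <- as.character(Biostrings::subseq(genome[[chroms[i]]],
                                         GenomicRanges::start(regions)[i],
                                         GenomicRanges::end(regions)[i]))
    if (strands[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  names(seqs) <- names(sp)
  list(seqs = Biostrings::DNAStringSet(seqs), regions = regions,
       truncated = stats::setNames(truncated, names(sp)))
}
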