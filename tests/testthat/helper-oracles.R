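# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# per-base set intersection of two 1-based closed intervals
overlap_oracle <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(0L)
  length(intersect(seq.int(s1, e1), seq.int(s2, e2)))
}

# overlapped-base count of a set of query intervals against subject intervals,
# union semantics, on one chromosome (matrices of start/end rows)
covered_bases_oracle <- function(query, subject) {
  qb <- unique(unlist(apply(query, 1, function(r) seq.int(r[1], r[2]),
                            simplify = FALSE)))
  sb <- unique(unlist(apply(subject, 1, function(r) seq.int(r[1], r[2]),
                            simplify = FALSE)))
  length(intersect(qb, sb))
}

# longest ATG-initiated reading frame in codons, by walking every ATG
orf_oracle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (paste(s[i:(i + 2)], collapse = "") != "ATG") next
    j <- i
    len <- 0L
    repeat {
      if (j + 2 > n) break
      codon <- paste(s[j:(j + 2)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) break
      len <- len + 1L
      j <- j + 3L
    }
    best <- max(best, len)
  }
  best
}

# direct evaluation of the per-tissue specificity score 1 - sqrt(JSD(p, e_t))
js_oracle <- function(v) {
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p <- v / sum(v)
  vapply(seq_along(p), function(t) {
    e <- rep(0, length(p))
    e[t] <- 1
    m <- (p + e) / 2
    1 - sqrt(H(m) - (H(p) + H(e)) / 2)
  }, numeric(1))
}

# Smith-Waterman with unit match/mismatch and linear gap -2, with traceback;
# returns score and percent identity (matches / alignment columns)
sw_oracle <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (A[i] == B[j]) 1 else -1
      cand <- c(H[i, j] + sc, H[i, j + 1] - 2, H[i + 1, j] - 2, 0)
      k <- which.max(cand)
      H[i + 1, j + 1] <- cand[k]
      P[i + 1, j + 1] <- if (cand[k] == 0) 0L else k
      if (H[i + 1, j + 1] > best) {
        best <- H[i + 1, j + 1]; bi <- i + 1L; bj <- j + 1L
      }
    }
  }
  if (best == 0) return(list(score = 0, identity = NA_real_))
  i <- bi; j <- bj; matches <- 0L; cols <- 0L
  while (i > 1 && j > 1 && P[i, j] != 0L) {
    cols <- cols + 1L
    if (P[i, j] == 1L) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (P[i, j] == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = best, identity = 100 * matches / cols)
}

# exhaustive decoy enumeration: every window x bulge placement, naive pairing
decoy_oracle <- function(seq, mir, bulge_len = 3, bulge_between = 9:11,
                         seed_range = 2:8, max_edits = 3) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  sq <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  mi <- strsplit(chartr("T", "U", toupper(mir)), "")[[1]]
  m <- length(mi)
  L <- m + bulge_len
  out <- NULL
  if (length(sq) < L) return(out)
  for (s in 1:(length(sq) - L + 1)) {
    w <- sq[s:(s + L - 1)]
    for (g in bulge_between) {
      mm <- 0L; wb <- 0L; seed_ok <- TRUE
      for (i in seq_len(m)) {
        tpos <- if (i <= g) L - i + 1 else L - i + 1 - bulge_len
        t <- w[tpos]; q <- mi[i]
        is_wc <- identical(unname(comp[q]), t)
        is_gu <- (q == "G" && t == "U") || (q == "U" && t == "G")
        if (i %in% seed_range) {
          if (!is_wc) { seed_ok <- FALSE; break }
        } else if (!is_wc) {
          if (is_gu) wb <- wb + 1L else mm <- mm + 1L
        }
      }
      if (seed_ok && mm + wb <= max_edits)
        out <- rbind(out, data.frame(start = s, gap = g, mm = mm, wb = wb))
    }
  }
  out
}

# brute conserved-run scan over an explicit score vector
runs_oracle <- function(v, min_len, min_score) {
  good <- !is.na(v) & v >= min_score
  out <- NULL
  i <- 1
  while (i <= length(v)) {
    if (good[i]) {
      j <- i
      while (j < length(v) && good[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out <- rbind(out, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}
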