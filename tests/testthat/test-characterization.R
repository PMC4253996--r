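test_that("exon statistics summarize structure as specified", {
  tx <- make_tx(list(
    t1 = list(chrom = "chr1", strand = "+", exons = ex(1, 100, 201, 400))))
  s <- exon_stats(tx)
  expect_equal(s$mean_exons, 2)
  expect_equal(s$median_exon_length, 150)
  expect_equal(s$median_tx_length, 300)
  expect_equal(s$spliced_fraction, 1.0)
  singles <- make_tx(list(
    a = list(chrom = "chr1", strand = "+", exons = ex(1, 300)),
    b = list(chrom = "chr1", strand = "+", exons = ex(1000, 1400))))
  expect_equal(exon_stats(singles)$spliced_fraction, 0)
  expect_error(exon_stats(singles[0]), "empty")
})

test_that("generated lincRNAs hit the target exon-count mean", {
  b <- get_bundle()
  linc <- b$candidates[b$truth$transcript_id[b$truth$role == "true_lincRNA"]]
  expect_lt(abs(exon_stats(linc)$mean_exons - 2.2), 0.3)
})

test_that("A/U content counts T as U and excludes N", {
  expect_equal(unname(au_content("ATAT")), 1.0)
  expect_equal(unname(au_content("GCGC")), 0.0)
  expect_equal(unname(au_content("ATGNNC")), 0.5)
  expect_equal(unname(au_content(Biostrings::RNAStringSet("AUAU"))), 1.0)
  expect_error(au_content("NNN"), "zero length")
})

test_that("lncRNAs are planted A/U-richer than coding transcripts", {
  b <- get_bundle()
  lnc_au <- mean(au_content(spliced_seqs(get_ident()$lncrna, b$genome)))
  cod_au <- mean(au_content(spliced_seqs(get_mrna(), b$genome)))
  expect_gt(lnc_au - cod_au, 0.05)
})

test_that("repeat overlap reports transcript and base fractions", {
  tx <- make_tx(list(
    a = list(chrom = "chr1", strand = "+", exons = ex(1, 100)),
    b = list(chrom = "chr1", strand = "+", exons = ex(1000, 1099)),
    c = list(chrom = "chr1", strand = "+", exons = ex(2000, 2099)),
    d = list(chrom = "chr1", strand = "+", exons = ex(3000, 3099))))
  reps <- GRanges("chr1", IRanges(100, 100))  # one base of one transcript
  ro <- repeat_overlap(tx, reps)
  expect_equal(ro$transcript_fraction, 0.25)
  half <- GRanges("chr1", IRanges(1, 50))
  ro2 <- repeat_overlap(tx["a"], half)
  expect_equal(ro2$base_fraction, 0.5)
  # fragmented repeats never exceed a base fraction of 1 (union semantics)
  frag <- GRanges("chr1", IRanges(c(1, 20, 40, 1), c(60, 80, 100, 100)))
  expect_equal(repeat_overlap(tx["a"], frag)$base_fraction, 1.0)
})

test_that("repeat base fractions match the per-base oracle on random input", {
  set.seed(51)
  for (k in 1:200) {
    es <- sort(sample(1:1500, 4))
    exons <- rbind(c(es[1], es[2]), c(es[3], es[4]))
    rs <- sort(sample(1:1500, 4))
    reps <- rbind(c(rs[1], rs[2]), c(rs[3], rs[4]))
    tx <- make_tx(list(t = list(chrom = "chr1", strand = "+", exons = exons)))
    got <- repeat_overlap(tx, GRanges("chr1", IRanges(reps[, 1], reps[, 2])))
    want <- covered_bases_oracle(exons, reps) / sum(tx_lengths(tx))
    expect_equal(got$base_fraction, want)
  }
})

test_that("sRNA overlap counts transcripts with any exonic overlap", {
  tx <- make_tx(list(
    a = list(chrom = "chr1", strand = "+", exons = ex(1, 100)),
    b = list(chrom = "chr1", strand = "-", exons = ex(1000, 1099))))
  loci <- GRanges("chr1", IRanges(c(50, 1050), c(70, 1070)),
                  strand = c("+", "+"))
  so <- srna_overlap(tx, loci)
  expect_equal(so$count, 2L)
  expect_equal(so$percent, 100)
  so_str <- srna_overlap(tx, loci, stranded = TRUE)
  expect_equal(so_str$count, 1L)   # the minus-strand transcript drops out
  expect_equal(srna_overlap(tx, GRanges())$count, 0L)
})

test_that("aligned fraction counts present scores only", {
  tr <- cons_track(list(chr1 = c(rep(0.5, 50), rep(NA, 150))))
  regions <- GRanges("chr1", IRanges(1, 200))
  expect_equal(aligned_fraction(regions, tr), 0.25)
  expect_equal(aligned_fraction(GRanges("chr1", IRanges(1, 50)), tr), 1.0)
  # region beyond the track is treated as unaligned
  expect_equal(aligned_fraction(GRanges("chr1", IRanges(151, 250)), tr), 0)
})

test_that("planted conservation orders coding above lincRNA", {
  b <- get_bundle()
  linc <- b$candidates[b$truth$transcript_id[b$truth$role == "true_lincRNA"]]
  cod_ex <- unlist(get_mrna(), use.names = FALSE)
  linc_ex <- unlist(linc, use.names = FALSE)
  expect_gt(aligned_fraction(cod_ex, b$track),
            aligned_fraction(linc_ex, b$track))
  mc_cod <- mean_conservation(get_mrna(), b$track)$mean_scores
  mc_linc <- mean_conservation(linc, b$track)$mean_scores
  expect_gt(mean(mc_cod, na.rm = TRUE), mean(mc_linc, na.rm = TRUE))
})

test_that("per-feature conservation means handle missing data", {
  tr <- cons_track(list(chr1 = c(0.2, 0.4, NA, NA)))
  mc <- mean_conservation(GRanges("chr1", IRanges(c(1, 3), c(3, 4))), tr)
  expect_equal(unname(mc$mean_scores), c(0.3, NA))
  set.seed(61)
  v <- round(runif(500), 3)
  v[sample(500, 100)] <- NA
  tr2 <- cons_track(list(chr1 = v))
  feats <- GRanges("chr1", IRanges(sample(1:400, 100), width = 50))
  mc2 <- mean_conservation(feats, tr2)$mean_scores
  for (i in seq_along(feats)) {
    seg <- v[start(feats)[i]:end(feats)[i]]
    want <- if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
    expect_equal(unname(mc2[i]), want)
  }
})

test_that("conserved elements are maximal qualifying runs", {
  v <- c(rep(0.2, 10), rep(0.9, 20), rep(0.2, 5), rep(0.9, 14), rep(NA, 10))
  tr <- cons_track(list(chr1 = v))
  regions <- GRanges("chr1", IRanges(1, length(v)))
  el <- conserved_elements(regions, tr)
  expect_equal(length(el), 1L)          # the 14-run is below min_len
  expect_equal(start(el), 11)
  expect_equal(end(el), 30)
  set.seed(71)
  for (k in 1:200) {
    v <- round(runif(120), 2)
    v[sample(120, 25)] <- NA
    tr <- cons_track(list(chr1 = v))
    got <- conserved_elements(GRanges("chr1", IRanges(1, 120)), tr,
                              min_len = 5, min_score = 0.6)
    want <- runs_oracle(v, 5, 0.6)
    expect_equal(length(got), NROW(want))
    if (NROW(want)) {
      expect_equal(start(got), want[, 1])
      expect_equal(end(got), want[, 2])
    }
  }
})
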