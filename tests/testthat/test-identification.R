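test_that("strand filter keeps exactly the stranded transcripts", {
  tx <- make_tx(list(
    a = list(chrom = "chr1", strand = "+", exons = ex(1, 300)),
    b = list(chrom = "chr1", strand = "*", exons = ex(1000, 1300)),
    c = list(chrom = "chr1", strand = "-", exons = ex(2000, 2300))))
  keep <- filter_strandless(tx)
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE))
})

test_that("sense-overlap filter is exon-level and strand-aware", {
  known <- make_tx(list(
    g = list(chrom = "chr1", strand = "+", exons = ex(100, 200, 500, 600))),
    biotype = "known_mRNA")
  cand <- make_tx(list(
    same = list(chrom = "chr1", strand = "+", exons = ex(150, 420)),
    anti = list(chrom = "chr1", strand = "-", exons = ex(150, 420)),
    intronic = list(chrom = "chr1", strand = "+", exons = ex(250, 450)),
    far = list(chrom = "chr1", strand = "+", exons = ex(5000, 5400))))
  keep <- filter_sense_overlap(cand, known)
  expect_false(keep[["same"]])     # same-strand exon overlap discards
  expect_true(keep[["anti"]])      # antisense overlap is the lncNAT pool
  expect_true(keep[["intronic"]])  # intron-only sense nesting survives
  expect_true(keep[["far"]])
})

test_that("sense-overlap verdicts match a per-base exon oracle", {
  set.seed(5)
  for (k in 1:200) {
    ks <- sort(sample(1:2000, 4))
    known_ex <- rbind(c(ks[1], ks[2]), c(ks[3], ks[4]))
    cs <- sort(sample(1:2000, 2))
    cand_strand <- sample(c("+", "-"), 1)
    known <- make_tx(list(g = list(chrom = "chr1", strand = "+",
                                   exons = known_ex)), biotype = "known_mRNA")
    cand <- make_tx(list(c1 = list(chrom = "chr1", strand = cand_strand,
                                   exons = rbind(cs))))
    expected <- !(cand_strand == "+" &&
                    covered_bases_oracle(rbind(cs), known_ex) > 0)
    expect_equal(unname(filter_sense_overlap(cand, known)), expected)
  }
})

test_that("length filter keeps the >= 200 nt boundary", {
  tx <- make_tx(list(
    short = list(chrom = "chr1", strand = "+", exons = ex(1, 199)),
    edge = list(chrom = "chr1", strand = "+", exons = ex(1000, 1199)),
    median_like = list(chrom = "chr1", strand = "+", exons = ex(2000, 2851))))
  keep <- filter_length(tx)
  expect_equal(unname(keep[c("short", "edge", "median_like")]),
               c(FALSE, TRUE, TRUE))
  expect_equal(unname(tx_lengths(tx)), c(199L, 200L, 852L))
})

test_that("expression filter applies 0.5 / 2 FPKM thresholds by exon count", {
  tx <- make_tx(list(
    me_low = list(chrom = "chr1", strand = "+", exons = ex(1, 100, 201, 300)),
    me_edge = list(chrom = "chr1", strand = "+", exons = ex(1000, 1100, 1201, 1300)),
    se_low = list(chrom = "chr1", strand = "+", exons = ex(2000, 2300)),
    se_edge = list(chrom = "chr1", strand = "+", exons = ex(3000, 3300))))
  fpkm <- rbind(me_low = c(0.0, 0.4), me_edge = c(0.0, 0.5),
                se_low = c(1.9, 1.9), se_edge = c(2.0, 0.0))
  colnames(fpkm) <- c("s1", "s2")
  keep <- filter_expression(tx, fpkm)
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(filter_expression(tx, fpkm[1:2, , drop = FALSE]), "absent")
})

test_that("proximity filter discards single-exon transcripts near same-strand neighbors", {
  # neighbor [400,900)+ and single-exon [1000,1200)+: gap 100 -> discarded
  all_tx <- make_tx(list(
    nb = list(chrom = "chr1", strand = "+", exons = ex(401, 900)),
    nb_minus = list(chrom = "chr2", strand = "-", exons = ex(401, 900)),
    se = list(chrom = "chr1", strand = "+", exons = ex(1001, 1200)),
    se_anti = list(chrom = "chr2", strand = "+", exons = ex(1001, 1200)),
    me = list(chrom = "chr1", strand = "+", exons = ex(1001, 1100, 1150, 1200))))
  cand <- all_tx[c("se", "se_anti", "me")]
  keep <- filter_single_exon_proximity(cand, all_tx)
  expect_false(keep[["se"]])      # same strand, gap 100
  expect_true(keep[["se_anti"]])  # neighbor on the opposite strand
  expect_true(keep[["me"]])       # multi-exon never tested
})

test_that("proximity boundary at gap 500/501 matches a brute-force scan", {
  for (gap in c(499, 500, 501, 502)) {
    nb_end <- 900
    se_start <- nb_end + gap + 1
    all_tx <- make_tx(list(
      nb = list(chrom = "chr1", strand = "+", exons = ex(401, nb_end)),
      se = list(chrom = "chr1", strand = "+",
                exons = ex(se_start, se_start + 250))))
    keep <- filter_single_exon_proximity(all_tx["se"], all_tx)
    # brute force: bases strictly between the two spans
    brute_gap <- se_start - nb_end - 1
    expect_equal(unname(keep), brute_gap > 500)
    expect_equal(unname(min_sense_gap(all_tx["se"], all_tx)), gap)
  }
})

test_that("ORF finder matches exhaustive enumeration and the codon threshold", {
  # 103 codons then a stop: discarded at the 100-codon threshold
  orf <- paste0("ATG", paste(rep("GCT", 102), collapse = ""), "TAA")
  seq <- paste0(rand_dna(20), orf, rand_dna(21))
  expect_equal(longest_orf_codons(orf), 103L)
  expect_gte(longest_orf_codons(seq), 103L)
  set.seed(21)
  for (k in 1:150) {
    s <- rand_dna(sample(30:400, 1))
    expect_equal(longest_orf_codons(s), orf_oracle(s), info = s)
  }
})

test_that("coding filter uses external scores when given, ORF surrogate otherwise", {
  g <- make_genome(chr1 = paste0(
    strrep("T", 100),
    "ATG", paste(rep("GCT", 102), collapse = ""), "TAA",  # 103-codon ORF
    strrep("T", 100)))
  tx <- make_tx(list(
    coding = list(chrom = "chr1", strand = "+", exons = ex(101, 412)),
    inert = list(chrom = "chr1", strand = "+", exons = ex(1, 100))))
  keep <- coding_potential_filter(tx, g)
  expect_equal(unname(keep), c(FALSE, TRUE))
  # external evidence overrides the surrogate entirely
  keep_ext <- coding_potential_filter(tx, g,
                                      cpc_scores = c(coding = -0.5, inert = 1.2))
  expect_equal(unname(keep_ext), c(TRUE, FALSE))
  keep_pfam <- coding_potential_filter(
    tx, g, cpc_scores = c(coding = -0.5, inert = -2), pfam_hits = "coding")
  expect_equal(unname(keep_pfam), c(FALSE, TRUE))
})

test_that("cascade recovers exactly the planted lncRNAs (seed 42)", {
  ident <- get_ident()
  truth <- get_bundle()$truth
  kept <- names(ident$lncrna)
  expect_setequal(kept, true_ids())        # sensitivity and specificity 1.0
  noise <- truth[!truth$transcript_id %in% true_ids(), ]
  rep <- ident$report
  got <- rep$discarding_filter[match(noise$transcript_id, rep$id)]
  expect_equal(got, role_filter(noise$role))
  # report invariants: one verdict per transcript, kept <=> no filter named
  expect_setequal(rep$id, names(get_bundle()$candidates))
  expect_true(all((rep$verdict == "discarded") ==
                    (rep$discarding_filter != "")))
})

test_that("empty candidate set yields an empty, valid result", {
  b <- get_bundle()
  empty <- b$candidates[0]
  out <- run_identification(empty, b$annotation, b$genome, b$fpkm)
  expect_equal(length(out$lncrna), 0L)
  expect_equal(nrow(out$report), 0L)
})

test_that("disabling one filter admits exactly that role's noise transcripts", {
  b <- get_bundle()
  truth <- b$truth
  for (f in c("strand", "length", "expression", "proximity", "coding")) {
    out <- run_identification(b$candidates, b$annotation, b$genome, b$fpkm,
                              disable = f)
    role <- names(which(c(noise_short = "length", noise_lowFPKM = "expression",
                          noise_strandless = "strand",
                          noise_single_exon_proximal = "proximity",
                          noise_coding_orf = "coding") == f))
    expected <- c(true_ids(), truth$transcript_id[truth$role == role])
    expect_setequal(names(out$lncrna), expected)
  }
})
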