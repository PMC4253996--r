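revcomp_dna <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# a perfect decoy site for `mir` (RNA, 5'->3') with a 3-nt target bulge
# inserted between the bases pairing miRNA positions g and g+1
perfect_site <- function(mir, g, bulge = "CTC") {
  mirc <- revcomp_dna(chartr("U", "T", mir))
  m <- nchar(mir)
  paste0(substr(mirc, 1, m - g), bulge, substr(mirc, m - g + 1, m))
}

test_that("a constructed perfect mimic yields exactly one clean site", {
  set.seed(201)
  mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
  site <- perfect_site(mir, g = 10)
  seq <- paste0(rand_dna(150), site, rand_dna(150))
  hits <- predict_decoy_sites(c(lnc = seq), c(m1 = mir))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 151L)
  expect_equal(hits$end, 151L + 23L)
  expect_equal(hits$mismatches + hits$wobbles, 0L)
  expect_equal(hits$bulge_after, 10L)
  expect_equal(hits$bulge_seq, "CUC")
})

test_that("seed-region mismatches kill a site; edits elsewhere are capped", {
  set.seed(202)
  mir <- paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE),
               collapse = "")
  site <- perfect_site(mir, g = 10)
  L <- nchar(site)
  # corrupt the target bases pairing miRNA seed positions 2-5
  broken <- strsplit(site, "")[[1]]
  for (i in 2:5) broken[L - i + 1] <- chartr("U", "T",
                                             substr(mir, i, i))
  broken <- paste(broken, collapse = "")
  seq <- paste0(rand_dna(60), broken, rand_dna(60))
  expect_equal(nrow(predict_decoy_sites(c(l = seq), c(m = mir))), 0L)
  # four non-seed mismatches exceed the cap of three; miRNA positions >= 12
  # pair target position L - i + 1 - bulge under every admissible placement
  b4 <- strsplit(site, "")[[1]]
  for (i in c(14, 16, 18, 19)) b4[L - i + 1 - 3] <- chartr("U", "T",
                                                           substr(mir, i, i))
  seq4 <- paste0(rand_dna(60), paste(b4, collapse = ""), rand_dna(60))
  expect_equal(nrow(predict_decoy_sites(c(l = seq4), c(m = mir))), 0L)
  # three stay admissible
  b3 <- strsplit(site, "")[[1]]
  for (i in c(14, 16, 18)) b3[L - i + 1 - 3] <- chartr("U", "T",
                                                       substr(mir, i, i))
  seq3 <- paste0(rand_dna(60), paste(b3, collapse = ""), rand_dna(60))
  got <- predict_decoy_sites(c(l = seq3), c(m = mir))
  expect_equal(nrow(got), 1L)
  expect_equal(got$mismatches + got$wobbles, 3L)
  expect_error(predict_decoy_sites(c(l = seq3), c(m = "ACGUACGUACGUACGUAC")),
               "19")
})

test_that("planted decoy sites are recovered exactly on the bundle", {
  b <- get_bundle()
  hits <- predict_decoy_sites(get_lnc_seqs(),
                              setNames(as.character(b$mirnas),
                                       names(b$mirnas)))
  want <- b$truth_decoys
  expect_equal(nrow(hits), nrow(want))
  got_key <- paste(hits$lncrna_id, hits$mirna_id, hits$start)
  want_key <- paste(want$lncrna_id, want$mirna_id, want$start)
  expect_setequal(got_key, want_key)
  expect_true(all(hits$mismatches + hits$wobbles == 0))
})

test_that("dinucleotide shuffle preserves composition and kills all sites", {
  s <- paste0(rand_dna(300))
  sh <- dinucleotide_shuffle(s, seed = 5)
  dinucs <- function(x) {
    v <- strsplit(x, "")[[1]]
    table(paste0(v[-length(v)], v[-1]))
  }
  expect_equal(nchar(sh), nchar(s))
  expect_equal(dinucs(sh), dinucs(s))
  b <- get_bundle()
  seqs <- get_lnc_seqs()
  set.seed(7)
  shuffled <- vapply(seqs[1:20], dinucleotide_shuffle, character(1))
  names(shuffled) <- paste0("shuf_", seq_along(shuffled))
  hits <- predict_decoy_sites(shuffled,
                              setNames(as.character(b$mirnas),
                                       names(b$mirnas)))
  expect_equal(nrow(hits), 0L)
})

test_that("scanner equals exhaustive window-by-bulge enumeration", {
  b <- get_bundle()
  seqs <- get_lnc_seqs()
  hosts <- unique(b$truth_decoys$lncrna_id)[1:2]
  others <- setdiff(names(seqs), b$truth_decoys$lncrna_id)[1:3]
  test_seqs <- seqs[c(hosts, others)]
  test_seqs <- test_seqs[nchar(test_seqs) <= 2000]
  mir <- setNames(as.character(b$mirnas), names(b$mirnas))
  for (mi in names(mir)) {
    for (sid in names(test_seqs)) {
      got <- predict_decoy_sites(test_seqs[sid], mir[mi])
      want <- decoy_oracle(test_seqs[[sid]], mir[[mi]])
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        # the scanner reports one site per admissible window, keeping the
        # minimal-edit bulge placement
        agg <- aggregate(cbind(mm, wb) ~ start, data = want, FUN = min)
        expect_setequal(got$start, agg$start)
        expect_equal(got$mismatches + got$wobbles,
                     (agg$mm + agg$wb)[match(got$start, agg$start)])
      }
    }
  }
})

test_that("upstream extraction follows strand and truncates at boundaries", {
  g <- make_genome(chr1 = rand_dna(8000))
  tx <- make_tx(list(
    plus = list(chrom = "chr1", strand = "+", exons = ex(5001, 6000)),
    minus = list(chrom = "chr1", strand = "-", exons = ex(5001, 6000)),
    near_edge = list(chrom = "chr1", strand = "+", exons = ex(301, 800))))
  up <- extract_upstream(tx, g)
  expect_equal(start(up$regions["plus"]), 4001)
  expect_equal(end(up$regions["plus"]), 5000)
  expect_equal(start(up$regions["minus"]), 6001)
  expect_equal(end(up$regions["minus"]), 7000)
  expect_equal(as.character(up$seqs[["minus"]]),
               revcomp_dna(substr(as.character(g[["chr1"]]), 6001, 7000)))
  expect_equal(start(up$regions["near_edge"]), 1)
  expect_equal(end(up$regions["near_edge"]), 300)
  expect_equal(unname(up$truncated), c(FALSE, FALSE, TRUE))
})
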