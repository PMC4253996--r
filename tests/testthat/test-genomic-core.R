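test_that("GTF coordinates convert to 1-based closed GRanges on read", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr2\tsrc\texon\t11\t60\t.\t.\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  tx <- read_gtf(gtf)
  expect_setequal(names(tx), c("t1", "t2"))
  # GTF line start=101 end=200 is the half-open interval [100, 200): 100 bases
  expect_equal(start(tx[["t1"]]), c(101, 301))
  expect_equal(end(tx[["t1"]]), c(200, 400))
  expect_equal(width(tx[["t1"]]), c(100, 100))
  # two exon lines sharing transcript_id collapse into one transcript
  expect_equal(tx_n_exons(tx[c("t1", "t2")]), c(2L, 1L))
  # strand "." survives as unstranded
  expect_equal(tx_strand(tx)[match("t2", names(tx))], "*")
})

test_that("GTF read/write round trip is lossless on a generated set", {
  tx <- get_bundle()$candidates[1:50]
  f <- tempfile(fileext = ".gtf")
  write_gtf(tx, f)
  back <- read_gtf(f)
  expect_setequal(names(back), names(tx))
  back <- back[names(tx)[order(names(tx))]]
  tx2 <- tx[order(names(tx))]
  expect_identical(unname(start(back)), unname(start(tx2)))
  expect_identical(unname(end(back)), unname(end(tx2)))
  expect_identical(tx_strand(back), tx_strand(tx2))
  expect_identical(S4Vectors::mcols(back)$gene_id,
                   S4Vectors::mcols(tx2)$gene_id)
})

test_that("malformed GTF and invalid transcripts are rejected", {
  f <- tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g";', f)
  expect_error(read_gtf(f), "transcript_id")
  bad <- GRangesList(t1 = GRanges("chr1", IRanges(c(1, 50), c(60, 100)), "+"))
  expect_error(transcript_set(bad, "g"), "overlap")
  two_chrom <- GRangesList(t1 = GRanges(c("chr1", "chr2"),
                                        IRanges(c(1, 200), c(100, 300)), "+"))
  expect_error(transcript_set(two_chrom, "g"), "chromosome")
})

test_that("FASTA reader uppercases, concatenates, and rejects duplicates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", "ACGT"), f)
  g <- read_fasta(f)
  expect_equal(as.character(g[["chr1"]]), "ACGTACGT")
  writeLines(character(0), f)
  expect_equal(length(read_fasta(f)), 0L)
  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate")
  seqs <- make_genome(chr1 = rand_dna(100), chr2 = rand_dna(50))
  f2 <- tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  expect_equal(as.character(read_fasta(f2)), as.character(seqs))
})

test_that("interval_overlap matches the spec's half-open examples", {
  # [100,200) vs [150,250) -> 50 shared bases
  a <- GRanges("chr1", IRanges(101, 200))
  b <- GRanges("chr1", IRanges(151, 250))
  expect_equal(interval_overlap(a, b), 50L)
  expect_equal(interval_overlap(b, a), 50L)
  # [100,200) vs [200,300): adjacency, zero overlap
  expect_equal(interval_overlap(a, GRanges("chr1", IRanges(201, 300))), 0L)
  # different chromosomes -> 0, not an error
  expect_equal(interval_overlap(a, GRanges("chr2", IRanges(101, 200))), 0L)
  # stranded mode zeroes out opposite or unknown strands
  ap <- GRanges("chr1", IRanges(101, 200), strand = "+")
  am <- GRanges("chr1", IRanges(151, 250), strand = "-")
  expect_equal(interval_overlap(ap, am, stranded = TRUE), 0L)
  expect_equal(interval_overlap(ap, ap, stranded = TRUE), 100L)
})

test_that("interval_overlap agrees with a per-base set oracle on 1000 pairs", {
  set.seed(11)
  for (k in 1:1000) {
    c1 <- sample(c("chr1", "chr2"), 1)
    c2 <- sample(c("chr1", "chr2"), 1)
    s1 <- sample(1:500, 1); e1 <- s1 + sample(0:100, 1)
    s2 <- sample(1:500, 1); e2 <- s2 + sample(0:100, 1)
    got <- interval_overlap(GRanges(c1, IRanges(s1, e1)),
                            GRanges(c2, IRanges(s2, e2)))
    expect_identical(got, overlap_oracle(c1, s1, e1, c2, s2, e2))
  }
})

test_that("BED and bedGraph readers respect 0-based half-open input", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", f)
  gr <- read_bed(f)
  expect_equal(start(gr), 11)
  expect_equal(end(gr), 20)
  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t0.5", bg)
  tr <- read_bedgraph(bg, c(chr1 = 6L))
  expect_equal(tr$chr1, c(0.5, 0.5, 0.5, NA, NA, NA))
  writeLines("chr1\t0\t3\t1.5", bg)
  expect_error(read_bedgraph(bg, c(chr1 = 6L)), "outside")
})

test_that("bedGraph and expression writers round trip losslessly", {
  tr <- cons_track(list(chr1 = c(NA, 0.25, 0.25, NA, 0.8, 1, 0),
                        chr2 = rep(NA_real_, 4)))
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, c(chr1 = 7L, chr2 = 4L))
  expect_equal(back$chr1, tr$chr1)
  expect_equal(back$chr2, tr$chr2)
  m <- matrix(c(0, 0.5381, 2.25, 19), 2, 2,
              dimnames = list(c("t1", "t2"), c("anther", "leaf")))
  fe <- tempfile(fileext = ".tsv")
  write_expression(m, fe)
  expect_identical(read_expression(fe), m)
  writeLines(c("transcript_id\ta", "t1\t1", "t1\t2"), fe)
  expect_error(read_expression(fe), "duplicate")
  writeLines(c("transcript_id\ta", "t1\t-1"), fe)
  expect_error(read_expression(fe), "negative")
})

test_that("cons_track validates score range", {
  expect_error(cons_track(list(chr1 = c(0.5, 1.2))), "outside")
  expect_silent(cons_track(list(chr1 = c(NA, 0, 1))))
})

test_that("spliced sequences concatenate exons and respect strand", {
  g <- make_genome(chr1 = "AAACGTACGTTTTTGGGCCC")
  tx <- make_tx(list(
    tp = list(chrom = "chr1", strand = "+", exons = ex(4, 7, 16, 18)),
    tm = list(chrom = "chr1", strand = "-", exons = ex(4, 7, 16, 18))))
  # chr1[4:7] = CGTA, chr1[16:18] = GGC
  s <- spliced_seqs(tx, g)
  expect_equal(as.character(s[["tp"]]), "CGTAGGC")
  expect_equal(as.character(s[["tm"]]),
               as.character(reverseComplement(DNAString("CGTAGGC"))))
  out_of_bounds <- make_tx(list(t = list(chrom = "chr1", strand = "+",
                                         exons = ex(15, 30))))
  expect_error(spliced_seqs(out_of_bounds, g), "bounds")
})

test_that("percent formatting rounds half-even to one decimal", {
  expect_equal(percent_of(122, 1624), 7.5)
  expect_equal(percent_of(44, 600), 7.3)
  expect_equal(percent_of(1, 3, digits = 1), 33.3)
  expect_error(percent_of(1, 0), "positive")
})
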