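# Small fixture builders shared across test files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# one transcript set from a list of exon coordinate matrices
# spec: list(id = list(chrom, strand, exons = rbind(c(start, end), ...)))
make_tx <- function(spec, gene_id = NULL, biotype = "candidate") {
  grl <- GRangesList(lapply(spec, function(s)
    GRanges(s$chrom, IRanges(s$exons[, 1], s$exons[, 2]), strand = s$strand)))
  names(grl) <- names(spec)
  if (is.null(gene_id)) gene_id <- names(spec)
  transcript_set(grl, gene_id = gene_id, biotype = biotype)
}

ex <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  m
}

make_genome <- function(...) {
  DNAStringSet(c(...))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
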