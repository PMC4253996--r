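# The default synthetic bundle (seed 42) and results derived from it are
# expensive enough to build once per test run and share.

.cache <- new.env()

get_bundle <- function() {
  if (is.null(.cache$bundle)) {
    dir <- file.path(tempdir(), "ricelnc-bundle42")
    .cache$bundle <- generate_bundle(seed = 42, out_dir = dir)
  }
  .cache$bundle
}

get_ident <- function() {
  if (is.null(.cache$ident)) {
    b <- get_bundle()
    .cache$ident <- run_identification(b$candidates, b$annotation,
                                       b$genome, b$fpkm)
  }
  .cache$ident
}

get_mrna <- function() {
  b <- get_bundle()
  b$annotation[S4Vectors::mcols(b$annotation)$biotype == "known_mRNA"]
}

get_calls <- function() {
  if (is.null(.cache$calls))
    .cache$calls <- classify_lnc(get_ident()$lncrna, get_mrna())
  .cache$calls
}

get_lnc_seqs <- function() {
  if (is.null(.cache$lnc_seqs)) {
    b <- get_bundle()
    .cache$lnc_seqs <- as.character(spliced_seqs(get_ident()$lncrna,
                                                 b$genome))
  }
  .cache$lnc_seqs
}

get_fst_hits <- function() {
  if (is.null(.cache$fst_hits)) {
    b <- get_bundle()
    calls <- get_calls()
    linc <- get_ident()$lncrna[calls$id[calls$lnc_class == "lincRNA"]]
    .cache$fst_hits <- map_fst(b$fsts, linc, b$genome)
  }
  .cache$fst_hits
}

true_ids <- function() {
  tr <- get_bundle()$truth
  tr$transcript_id[tr$role %in% c("true_lincRNA", "true_lncNAT")]
}
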