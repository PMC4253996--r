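Package: ricelnc
Title: Discovery and Characterization of Long Non-Coding RNAs from Assembled
    Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification of long
    non-coding RNAs (lncRNAs) from an assembled transcriptome: a filter
    cascade (strand, novelty, length, expression, single-exon proximity,
    coding potential) that turns candidate transcripts into reliably
    expressed lncRNAs; classification into long intergenic ncRNAs (lincRNAs)
    and long non-coding natural antisense transcripts (lncNATs); genomic,
    sequence and conservation characterization; Jensen-Shannon
    tissue-specificity scoring with reproductive/vegetative categorization;
    miRNA decoy (endogenous target mimic) site prediction; and mapping of
    insertional-mutant flanking sequence tags to lincRNA bodies and
    promoters. Ships a seeded synthetic-transcriptome generator with a
    planted truth table so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
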