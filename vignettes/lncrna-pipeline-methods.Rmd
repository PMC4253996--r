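---
title: "Methods: lncRNA discovery, classification and functional annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, classification and functional annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`ricelnc`, in the order the pipeline applies them, together with the design
decisions that were genuinely open and how the synthetic-data generator
supports validation.

## Coordinates and containers

Transcripts are `GRangesList`s of exons (one element per transcript, with
`gene_id` and `biotype` metadata), so all coordinates inside the package are
1-based closed, the Bioconductor convention. GTF (1-based inclusive) and
BED/bedGraph (0-based half-open) are converted at the I/O boundary by
rtracklayer. Strand `"*"` is a first-class "no strand information" value:
the cascade's first filter removes such transcripts, and `"*"` never counts
as *same strand* in any overlap or proximity rule. Chromosome names are
matched by exact string equality; no `chr`-prefix normalization is
attempted, and a mismatch surfaces as a clear "chromosome not in genome"
error rather than a silent empty result.

## The identification cascade

Six filters turn assembled candidates into reliably expressed lncRNAs. Each
is a *pure predicate on the full candidate set* — the kept set is therefore
independent of filter order, while the report's "first failed filter"
follows the fixed order (strand, sense overlap, length, expression,
proximity, coding) and is documented as order-dependent.

* **Strand** — keep only `+`/`-` transcripts.
* **Sense overlap** — discard on ≥ 1 bp exon-to-exon overlap with any
  annotated gene (including TE-related mRNAs) on the same strand. The rule
  is exon-level: a candidate lying entirely within an annotated intron in
  sense survives, and antisense overlap never discards (it defines the
  lncNAT pool).
* **Length** — spliced length (sum of exon widths) ≥ 200 nt. The two
  published phrasings of this cutoff ("longer than 200" vs "shorter than
  200 discarded") disagree at the boundary; we keep 200 exactly and pin the
  boundary in a test fixture.
* **Expression** — max FPKM across samples ≥ 0.5 (multi-exon) or ≥ 2
  (single-exon). "Below threshold in all samples" and "maximum below
  threshold" are the same predicate; it is implemented once.
* **Single-exon proximity** — a single-exon candidate within 500 bp
  (span gap; 0 when overlapping) of another transcript *on the same strand*
  is discarded as a likely assembly fragment. "Sense direction" could also
  be read as "downstream of the 3' end only"; we adopt the same-strand
  reading because fragments of one transcript share its strand regardless
  of which side they fall on.
* **Coding potential** — when external classifier scores are supplied, any
  score > 0 discards, and transcripts on the protein-domain hit list are
  additionally discarded, reproducing an external CPC + Pfam screen
  bit-for-bit. Without external evidence, a built-in surrogate discards
  transcripts whose spliced sequence (transcript strand only, three frames)
  contains an ATG-initiated frame of ≥ 100 codons — the conventional lncRNA
  ORF cutoff. ORFs are counted up to but excluding the stop codon, and an
  ATG-to-end run without a stop also counts (conservative: discards more
  coding-like transcripts).

Candidates equal to or contained in known non-coding annotation are not
treated specially; they flow through the cascade like any other candidate.

## Classification and neighbors

A surviving lncRNA is a **lncNAT** iff ≥ 1 base of its exons overlaps an
exon of a non-TE protein-coding mRNA on the opposite strand; otherwise it
is a **lincRNA**. The overlap fraction is the *base union* of overlapped
lncRNA exonic bases divided by the lncRNA's exonic length, so fragmented or
redundant mRNA exons are never double-counted and the fraction cannot
exceed 1. Intron-only antisense nesting stays lincRNA.

The closest-gene search for lincRNAs is purely positional (strand-ignorant)
with lexicographic tie-breaks. Orientation labels: `tandem` (same strand),
`divergent` (5' ends face each other across the gap), `convergent` (3' ends
face), `overlapping` (spans intersect; excluded from the
divergent/convergent/tandem tally).

## Characterization

A/U content is computed on the transcribed sense (minus-strand transcripts
reverse-complemented), with `N` excluded from numerator and denominator.
Repeat and sRNA overlaps are strand-agnostic by default because repeat
annotations are usually strandless; a stranded mode exists for sRNA loci
since small-RNA derivation is strand-informative. Conservation statistics
consume a per-base score track in [0, 1] where missing positions mean "not
aligned in the multiple-genome alignment": the aligned fraction equates
"aligned" with "score present", per-feature means average present scores
only, and **conserved elements** are maximal runs of ≥ 15 consecutive bases
each scoring ≥ 0.8 — thresholds of this package's choosing (no published
definition exists for "short conserved region") and configurable.
Percentages in summary tables are reported to 1 decimal, round-half-even.

## Tissue specificity and categories

For a transcript's expression vector normalized to a distribution $p$ over
$T$ tissues, the per-tissue specificity is

$$s_t = 1 - \sqrt{\mathrm{JSD}(p, e_t)}, \qquad
\mathrm{JSD}(p,q) = H\!\left(\tfrac{p+q}{2}\right) - \tfrac{H(p)+H(q)}{2}$$

with base-2 entropy and $0\log 0 \equiv 0$; the JS score is
$\max_t s_t$. Under base-2 logs JSD lies in [0, 1], so scores do too; the
score is scale-invariant and equals 1 exactly when expression is confined
to one tissue. This is the csSpecificity convention of cufflinks-era
expression tooling, adopted here as the normative formula since the score
is usually named but not spelled out.

Categorization assigns the tissue group (reproductive / vegetative / other
tissues) of the argmax-specificity tissue when the JS score reaches the
floor (default 0.5), and "other" below it. This specificity-based argmax
grouping deliberately replaces graph-based expression clustering (CLICK),
which has no published parameterization; it yields the same three
categories and is exactly recoverable on planted data. For the
expression-level comparison between sets, each transcript is summarized by
its **max** FPKM across samples (a cross-sample mean erases
tissue-specific transcripts); a mean summary and a t-test variant are
available by flag, with the default location test rank-based because FPKM
is heavy-tailed.

The lincRNA–neighbor expression analysis reports the mean Spearman
correlation over (lincRNA, closest gene) pairs and calibrates it against
positional shuffles: lincRNA spans are re-placed uniformly in intergenic
space (complement of coding gene bodies), closest genes recomputed, and the
mean correlation recollected `n_shuffles` times (default 1000) under a
fixed seed. Pairs with constant expression vectors have undefined rank
correlation; they are excluded and counted.

## miRNA decoy (target mimic) scanning

The rule engine treats all constants as parameters, defaulting to the
plant endogenous-target-mimic convention: a 3-nt bulge on the target side
inserted opposite the miRNA central region (between positions 9–12 from the
miRNA 5' end), perfect Watson-Crick pairing at seed positions 2–8, at most
3 combined mismatches and G:U wobbles elsewhere, and no other indels. G:U
counts as a wobble (capped with mismatches) by default, with a flag to
treat it as a full match; bulges on the miRNA side are not modeled. The
scan enumerates every window of length |miRNA| + bulge and every admissible
bulge placement; one site per admissible window is reported (the placement
with fewest edits, 5'-most on ties), and the exhaustive window × placement
enumeration is retained as the test oracle. Dinucleotide-preserving
shuffles (Altschul–Erikson Euler-walk) provide the false-positive control.

## FST mutant mapping

Each lincRNA contributes one genomic search stretch: its span extended
1 kb on its 5' side (the promoter proxy). FSTs are aligned against every
stretch in both orientations with exact Smith-Waterman (match +1, mismatch
−1, linear gap −2) — the target space is small, so exactness is affordable
and directly testable against a DP oracle. Percent identity is matches over
alignment columns; the published wording ("similarity scores > 90%") is
ambiguous between identity and a score ratio, and we implement identity
with a *strict* > 90 threshold (90.0 exactly is rejected). Optimal local
alignments are not always unique: co-optimal tracebacks can trade a
mismatch column against a clipped end and differ by a fraction of a
percentage point in identity while sharing the optimal score, so the score
is the exactly reproducible quantity and identity is reproducible up to
co-optimality (the retained hits sit far from the 90% boundary, so the
threshold decision is unaffected). Because a short
perfect k-mer match is 100% identical without being an insertion-site hit,
retained hits must additionally cover ≥ 80% of the FST. A hit is `internal`
when the FST's 5'-end genomic position (extrapolated past clipped leading
bases) falls inside the transcript span, `upstream` when it falls in the
1-kb interval; boundary-spanning hits are classified by the 5' end alone.
One FST may hit several lincRNAs and all hits are reported, with
per-database tabulation of distinct mutants and lincRNAs.

## The synthetic-data generator

`generate_bundle()` emulates the study conditions at desk scale: a 2-Mb
genome on 2 chromosomes carrying 60 coding genes, 10 TE-mRNAs, 40
lincRNAs, 20 lncNATs and 15 noise transcripts per role, a 13-tissue FPKM
matrix (7 reproductive organs, 5 vegetative, 1 extra), a conservation
track, repeat and sRNA loci, 2 miRNAs × 3 planted decoy sites, and 20 FSTs
at a 2% substitution rate. All randomness flows through one seeded RNG
stream, and the same (config, seed) reproduces the bundle byte for byte.

Choices a scientist would recognize as the controlled conditions:

* **Each noise role violates exactly one filter.** Intergenic spacing is
  ≥ 1500 nt except for the planted proximity pairs, so the 500-bp rule only
  fires where intended; lncRNA-like sequences are redrawn until their
  longest ORF is below 80 codons (a safety margin under the 100-codon
  cutoff), while planted coding sequences carry ≥ 110 codons.
* **Exon counts are drawn by quota** (e.g. 18/10/6/3/2/1 lincRNAs with
  1–6 exons), fixing the mean exon count at ≈ 2.1 deterministically — a
  mean near 2.2 with about half the transcripts spliced, the structure
  typical of plant lncRNA catalogs.
* **Transcript lengths** are log-normal around a median of ~850 nt,
  clipped to [210, 2800]; lncRNA base composition is drawn at A/U 0.62
  against ~0.47 for coding transcripts, planting the A/U gap the
  characterization stage measures. Because the base distribution is
  strand-symmetric (P(A)=P(T), P(C)=P(G)), free lncNAT bases can be
  written on the forward strand without biasing composition.
* **Expression**: tissue-specific transcripts put a dominant share drawn
  from U(0.75, 0.90) of their mass on one tissue (anther-weighted, 35%,
  mirroring strong male-gametophyte enrichment), which yields JS scores of
  ≈ 0.65–0.77 for T = 13 — safely above the 0.5 floor; about 12% are
  planted broadly expressed ("other", JS verified ≤ 0.45). Expressed
  plantings keep max FPKM at ≥ 2× their threshold so filter boundaries are
  never decided by noise; boundary behavior is tested with explicit
  fixtures instead.
* **lncNATs** are anchored antisense over the last exon of a host coding
  gene with overlap fractions drawn in (0.03, 0.28); the overlapped bases
  are the host's (reverse-complemented), only the free bases are redrawn.
* **Conservation** is piecewise-constant in 10–30 nt blocks: coding exons
  fully aligned at 0.55–0.9 (half the genes also carry a planted 20-bp run
  ≥ 0.85), lncRNA exons aligned with probability 0.5 at 0.05–0.35, plus
  sparse intergenic blocks — planting both the aligned-fraction and
  mean-score orderings the tests check.

What the generator does **not** emulate: read-level noise and assembly
artifacts beyond the five planted families, isoform structure, genome-scale
repeat content, realistic phylogenetic correlation in the conservation
track, or biological covariance between expression and sequence features.
Passing the planted-truth suite therefore demonstrates the correctness of
the decision rules and numerics, not the field performance of the
thresholds on real assemblies.

## Numerical and degenerate-input conventions

All-zero expression vectors are an error (specificity undefined), as are
empty transcript sets for summary statistics. Features with no aligned base
report a missing conservation mean and are excluded from cumulative
distributions. JSD values are clamped to [0, 1] before the square root to
absorb floating-point negatives. Ties: closest-gene and decoy-placement
ties break deterministically (lexicographic gene id; 5'-most bulge
placement), and all writers emit deterministic orderings so reruns are
byte-comparable.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default bundle (135 candidates, 70 annotated genes, 2-Mb genome), 1000-case
oracle sweeps for the interval and specificity kernels, a 100-pair
alignment oracle, and 100-shuffle correlation controls — sizes chosen so
the whole suite completes in a few minutes on one CPU while still
exercising every rule at its boundaries.

## Known limitations

The coding-potential surrogate is an ORF-length rule, not a trained
classifier; users reproducing a published CPC/Pfam screen should supply
external scores, which the filter honors verbatim. The decoy rule engine
expresses the common published variants but not free-energy scoring. FST
mapping assumes FSTs are genomic (contiguous) sequences; tags spanning
splice junctions of the transcript would align only partially. The
single-exon proximity rule's "sense direction" reading and the
identity-vs-score-ratio ambiguity of the mutant screen are documented
choices, both configurable at the call site.
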