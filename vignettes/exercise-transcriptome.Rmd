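---
title: "Methods: unigene clusters, filtered SNV discovery, voting DEGs and isoform switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unigene clusters, filtered SNV discovery, voting DEGs and isoform switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

exertome re-implements, as a tested and reusable package, the
post-alignment analysis of a paired exercise-physiology RNA-Seq design: six
animals, two tissues (blood and muscle), each sampled before and after
exercise — 24 samples in all. Four analyses run downstream of alignment and
per-sample transcript assembly:

1. **Unigene clustering** (`cluster_transcripts()`): transcript models from
   all samples are pooled and grouped into *unigene clusters* (UCs),
   classified as annotated or novel against a reference annotation, with a
   six-frame ORF length filter over novel cluster sequences.
2. **Variant discovery** (`call_variants()` and friends): SNVs and short
   indels are called from per-sample site observations under stringent
   depth/allele-fraction gates plus an exon–intron boundary misalignment
   filter, merged non-redundantly, compared against two SNP databases, and
   annotated for coding effects.
3. **Differential expression** (`call_degs()`): expression is quantified as
   FPKM and features are called differentially expressed by a per-animal
   fold-change voting rule.
4. **Isoform switches** (`detect_switches()`): genes whose two splice forms
   reverse their expression dominance after exercise, consistently across
   animals.

A synthetic-data generator (`sim_study()`) produces a fully self-contained
toy corpus — genome, annotation, 24 samples, SNP databases — with complete
ground-truth tables, so every stage is testable end to end without any
external download.

## Unigene clusters

With transcript models assembled independently per sample (and without a
guiding annotation), the same locus surfaces 24 times under 24 different
transcript ids. The UC is the pooled unit of analysis: a **maximal set of
same-contig, same-strand transcripts connected — transitively — by at least
one base of exonic overlap**. Clusters are the connected components of the
exonic-overlap graph, computed by reducing all exons to merged blocks and
joining transcripts that share a block (the transitive closure of pairwise
exonic overlap).

Two decisions here were genuinely open:

* **Overlap unit: exonic bases, not genomic span.** Span overlap would fuse
  a gene nested inside another gene's intron with its host; exonic overlap
  does not. Strands never merge, so antisense transcription stays separate.
* **Canonical ordering.** Cluster ids are assigned by (contig, footprint
  start, strand), which makes the output invariant to input row order — a
  property the test suite checks against a brute-force pairwise union-find
  oracle.

A cluster is *annotated* iff its footprint shares an exonic base, same
strand, with an annotated gene; otherwise *novel*. Novel cluster footprint
sequences pass through a six-frame ORF filter: kept iff any reading frame on
either strand contains a complete ATG-to-stop frame of at least
`min_orf_nt` nucleotides (stop codon included). The threshold is
configurable with a default of 300 nt (100 codons), a conventional cutoff
for distinguishing plausible coding sequences from spurious short frames;
the filter result is reported as an annotation on novel clusters rather
than silently discarding them.

"Expressed in a tissue" means FPKM above `min_fpkm` in at least one sample
of that tissue; the default is 0 (any positive evidence), because any
stricter notion of "expressed" is a study-level choice the user should make
explicitly.

## Variant discovery

Per-sample site observations (base counts per position) pass three gates:
depth ≥ `min_depth` (4), alternate reads ≥ `min_alt_reads` (2), and
alternate fraction ≥ `min_alt_fraction` (0.2). Genotypes are heterozygous
below `hom_fraction` (0.8), homozygous at or above. Multi-allelic sites
decompose into one record per alternate allele. These defaults describe a
typical stringent RNA-Seq calling regime and are all exposed as parameters.

The distinctive step is the **exon–intron boundary misalignment filter**:
spliced reads misaligned across a splice junction pile up spurious
alternate alleles immediately adjacent to exon ends, so every candidate
within `window_bp` (10) of an annotated or cluster-model exon boundary is
removed. The filter is a pure positional predicate — it commutes with the
calling gates and is monotone in the window, both verified by tests.

Merging keys variants by (contig, position, reference, alternate). A
variant is *individual-specific* iff all carrying samples belong to one
animal; this is judged on called presence only, ignoring coverage dropout —
a caveat inherent to call-set comparison. Database matching requires full
allele identity, not mere position, since positional matching inflates
overlap. Coding effects rebuild the affected codon strand-aware from the
annotated CDS (spliced CDS supported), substitute the alternate base and
translate: synonymous iff the amino acid is unchanged; indels inside a CDS
are counted non-synonymous; exonic variants outside any CDS are non-coding.
CDS models whose length is not a multiple of three are flagged and their
variants marked `NA` rather than guessed.

## FPKM and the voting DEG rule

FPKM is `count * 1e9 / (length * total)` — fragments per kilobase of exon
model per million mapped fragments. The transformation is exactly
invertible, which the tests exploit (reconstruction to relative error
below 1e-12).

Differential expression follows a replicate-voting rule rather than a
model-based test: per animal, the fold change between the after and before
samples of a tissue is computed on FPKM, and a feature is an up-regulated
DEG iff its fold exceeds the threshold (strictly, `> 2`) in at least
`min_horses` (4 of 6) animals; down-regulation mirrors this with
`fold < 1/2`. With a quorum above half the animals the up and down sets are
provably disjoint. Design choices:

* **Pseudocount 0.1** added to both timepoints before dividing. Zero
  expression would otherwise produce unbounded or undefined folds; the
  pseudocount bounds them and is configurable. With it, folds are no longer
  exactly invariant to library-size rescaling (without it they are — a
  property the tests check at pseudocount 0).
* **Strict inequality** — "more than two-fold" is read literally.
* Both a **raw per-tissue total** and a **deduplicated total** across
  tissues are reported, because a feature can respond in both tissues and
  the two totals genuinely differ.
* Correlation matrices are computed on `log(FPKM + 1)`: raw FPKM
  correlations are dominated by a handful of extreme features.

The rule's failure mode is worth naming: it is a composition-sensitive
statistic. When a large fraction of the library changes in one direction,
the per-million normalisation shifts every other feature's fold in the
opposite direction. No correction is applied, faithfully to the original
procedure; the synthetic corpus is therefore designed so that planted
effects are a realistic minority of the library (below).

## Isoform switches

For an isoform pair (a, b) of one gene and one animal, a switch holds iff a
dominates before (`fpkm_a > min_ratio * fpkm_b`) and b dominates after, with
the dominant isoform at least `min_fpkm` (1 FPKM) at both timepoints. An
event is reported for a gene and tissue iff at least `min_horses` (4)
animals agree on the same orientation — the same voting spirit as the DEG
rule, since the original description of the pattern is qualitative
(consistent crossing line plots across animals) without numeric criteria.
One event per gene is kept: the pair with most support, ties broken by
lexicographic isoform ids. Only pairwise comparisons are made, because the
phenomenon of interest is two splice forms trading places, not a full
ranking.

## The synthetic corpus

`sim_study()` emulates the 24-sample design with planted, fully recorded
truths. What it generates:

* **Genome and annotation**: random-sequence contigs carrying
  non-overlapping gene loci (2–8 exons, 1–3 transcripts sharing a strand),
  each with a valid planted CDS (starts ATG, ends with a stop, length a
  multiple of three, no internal stops) lying inside one exon. A fraction
  of loci (default 25%) is withheld from the reference annotation: their
  transcripts are genuinely novel and, by construction, outside every
  annotated footprint.
* **Counts**: each gene has a log-normal baseline mean; observed counts are
  the mean times mean-preserving log-normal noise at coefficient of
  variation `cv` (default 0.1), rounded. Setting `cv = 0` gives exactly the
  means — the noiseless limit the oracle tests anchor on. This deliberately
  avoids a negative-binomial machinery: the closed-form expectations make
  test assertions exact.
* **Planted DEGs**: "after" means of affected genes are multiplied by the
  effect (default 4-fold) in the affected tissue for all animals. Defaults
  plant 13 DEG slots among 120 genes (~11% of features). Keeping the
  planted fraction modest is a realism constraint: per-million
  normalisation makes fold changes composition-sensitive, and a corpus in
  which half the library is differentially expressed would not resemble any
  real study (the emulated design's own DEG fraction is a few percent).
* **Sites**: true variant sites sit in exon interiors (more than
  `window_bp + 2` from any boundary) with per-animal genotypes; artifact
  sites sit within `window_bp` of an exon boundary at 20–40% allele
  fraction and appear only in samples expressing the owning gene —
  mimicking the junction misalignment the filter targets. Depth is
  Poisson(30), base errors 1% spread uniformly over the other three bases:
  a typical RNA-Seq pileup regime at desk scale.
* **SNP databases**: two VCFs each independently containing a configurable
  fraction of the truth substitutions plus decoy sites.
* **Switches**: in selected multi-isoform genes (default three muscle, one
  blood), the two heaviest isoforms trade dominance after exercise at ratio
  5; non-switch genes get dominance-separated isoform weights (factor 2.5
  between ranks) so that noise alone cannot reverse an order consistently
  in four animals.

Everything derives from one seed; the same seed reproduces the corpus
byte-identically on disk.

**What passing tests do and do not show.** The generator has no read-level
error structure, no alignment ambiguity, no coverage-expression coupling at
variant sites, no dispersion trends, and its transcript models are
identical across the samples expressing them. Recovery of planted truths
therefore validates the *logic* of each stage — the clustering rule, the
filter cascade, the voting arithmetic — not performance on real alignments.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout, matching GTF/VCF; all
  interval arithmetic is delegated to IRanges/GenomicRanges, which removes
  any off-by-one ambiguity.
* Percentages are rounded half away from zero at two decimals
  (`percentage()`), so printed counts and percentages stay mutually
  consistent; base `round()` would round half to even.
* Malformed transcript records (mixed contigs/strands, self-overlapping
  exons) are dropped per record with a warning, never fatally.
* Constant expression columns make Pearson correlations undefined; they are
  reported `NA`, not imputed.
* Animals missing a timepoint error by default; `allow_missing = TRUE`
  excludes them with a warning, and the quorum then counts available
  animals only.
* Quantiles use linear interpolation (type 7, the R default).

## Problem sizes

The test suite and the acceptance script run, by design, at desk scale: the
default corpus is three 200-kb contigs with 120 genes, 300 variant sites,
60 junction artifacts; recovery checks use 2,000 features for the DEG rule,
1,000 sites for variant calling and 500 planted coding substitutions for
effect annotation. These sizes keep the full suite in the low minutes while
leaving every rate estimate (sensitivity, precision, concordance) with
enough events to be meaningful.

## Known limitations

* The voting DEG rule has no error model and no multiple-testing control;
  it is a faithful re-implementation, not a recommendation. For model-based
  inference use DESeq2/edgeR/limma on the same count tables.
* Individual-specific variant status conflates "not called" with "not
  covered".
* The ORF filter scans the concatenated footprint of a cluster, which can
  bridge exons that no single transcript joins; with merged-exon cluster
  models this is the only sequence available.
* Database comparison assumes both databases share the reference
  coordinates of the call set; no liftover is attempted.
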