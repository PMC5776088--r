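---
title: "Methods: detecting and characterizing an RNA editome from matched DNA and RNA evidence"
author: "editomescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing an RNA editome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomescan)
```

## The problem

RNA editing — predominantly adenosine-to-inosine (A-to-I) deamination by
ADAR enzymes, read as A-to-G by sequencers — alters transcripts relative to
the DNA that encodes them. Detecting editing from sequencing data therefore
amounts to finding *RNA–DNA differences* (RDDs): positions where the RNA
evidence of an individual contradicts that same individual's DNA genotype.
The difficulty is that almost everything else also produces apparent
RDDs: germline polymorphism, caller artifacts, misalignment near read
ends, and plain sequencing error. The pipeline implemented here is a
filtering cascade designed to strip those away, followed by a
characterization layer: where do the surviving sites fall in gene models,
which of the 12 substitution types are they on the transcribed strand,
how do they distribute across a four-sample tumor-progression design
(non-cancerous liver NL, primary tumor PT, intrahepatic metastasis IM,
portal vein tumor thrombus PTVV), and what are their likely functional
consequences.

## Detection model

Per sample, variants are taken from two callers per modality:

* **DNA**: the two caller sets are **merged by union** — for genotyping the
  germline, missing a real variant is worse than carrying a
  caller-specific one, since DNA variants only ever *remove* editing
  candidates.
* **RNA**: the two caller sets are **intersected** — RNA variant calls are
  artifact-prone and only sites confirmed by both callers proceed.

Where both callers report a DNA site, depth and support take the maximum
and the genotype comes from the deeper caller.

A merged RNA variant becomes a candidate editing site iff:

1. its RNA genotype differs from the DNA genotype at that position. The
   DNA genotype is the called one if a DNA variant exists there, else
   homozygous reference — but only if DNA covers the position at the
   depth threshold; without adequate DNA coverage the genotype is unknown
   and the site is discarded rather than assumed reference.
2. the RNA evidence does not display more than one non-reference base
   type. This rule is evaluated on alternate alleles with at least
   `min_alt_reads` supporting observations, not on single stray reads: a
   true editing site should not be disqualified by one sequencing error.
   (Whether the original cascade applied this at the raw-read or
   called-allele level is not determinable; the supported-allele reading
   is the one under which the rule coexists with a realistic error rate.)

Candidates then pass four evidence filters on the RNA pileup, with
defaults `filter_config()`:

| filter | default | meaning |
|---|---|---|
| `min_base_qual` | 20 | minimum Phred quality among variant-supporting observations |
| `min_depth` | 5 | total observations at the site |
| `min_end_distance` | 15 | minimum, over supporting observations, of the distance to the *nearer* read end |
| `min_alt_reads` | 2 | variant-supporting observations |

The end-distance statistic is a site-level **minimum over all supporting
reads**, using the nearer of the two ends per read — the conservative
reading of "distance of a site to its supporting reads' ends", and the
one under which a single end-proximal supporting read disqualifies a
site. Survival is a conjunction, so it is order-independent; for audit
purposes a removed candidate is charged to the first filter it fails in
the order quality, depth, end distance, support. Finally, any site at a
position present in a supplied known-SNP table is removed
(allele-agnostic matching — position collision with known polymorphism
is disqualifying regardless of allele).

## Annotation and patterns

Sites are annotated against transcript models: a site must overlap at
least one transcript, and all overlapping transcripts must agree on
strand; otherwise it is discarded as unannotated or strand-ambiguous.
Among same-strand overlaps, coding models take precedence over lncRNA,
then the region label follows the precedence CDS > UTR3 > UTR5 > Exon >
Intron. (The choice to resolve biotype before region is this package's;
single-label per-site counting requires *some* tie rule, and annotating a
site as the intron of a coding gene rather than the exon of an
overlapping lncRNA keeps the coding gene's identity attached to it.)
Variant types are resolved on the transcribed strand — a genomic T-to-C
on a minus-strand transcript is an A-to-G event — giving 12 possible
types. Repeat context is Alu if the site falls in any Alu interval,
repetitive non-Alu if in any other repeat, else non-repetitive.

Presence across the four samples classifies each site into seven
patterns: ALL (all four), STN (2–3 samples including NL), ST (2–3 tumor
samples without NL), or the four sample-unique labels. These rules
partition the 15 non-empty presence subsets exactly; the stage-specific
fraction is the proportion of sites with pattern ≠ ALL.

## Functional impact

* **miRNA-target enrichment.** For 3'UTR sites, the test asks whether
  sites hit miRNA target intervals more than uniform placement would
  predict. The universe is base-resolution: N = all 3'UTR bases, K =
  target-covered 3'UTR bases, n = sites, k = sites in targets, and the
  p-value is the hypergeometric upper tail P[X ≥ k]. Base resolution is
  the natural null for positional overlap: each 3'UTR base is one trial.
  miRNAs are ranked by distinct edited sites in their targets (ties
  lexicographic); a site in several miRNAs' targets counts once for k
  but once per miRNA in the ranking.
* **Recoding.** CDS sites are located in the spliced CDS of their
  transcript (minus-strand CDS read on the reverse complement, codons
  spanning exon junctions handled by spliced coordinates), the
  substitution applied, and both codons translated with the standard
  genetic code table (no initiator special-casing). Equal amino acids ⇒
  synonymous. External damaging/tolerated labels are joined by position
  when provided; prediction itself is out of scope.
* **Expression change.** For each tumor sample, transcripts edited in
  that sample but *not* in NL are compared against the background of all
  transcripts on log2((FPKM_tumor + 0.01) / (FPKM_NL + 0.01)), per
  category (UTR5, CDS, miRNA-target UTR3, non-target UTR3, Intron), with
  a two-sample two-sided asymptotic Kolmogorov–Smirnov test. The 0.01
  pseudo-count admits zero-expression transcripts while keeping ratios
  finite; sidedness and the pseudo-count are this package's choices as
  the quantity "expression change" is conventionally a shifted log
  ratio.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the
four-sample design at desk scale, with full ground truth. Defaults
(`simulation_config()`): 2 chromosomes x 100 kb, 40 transcripts (25%
lncRNA), 60 Alu and 30 non-Alu repeats, 150 germline SNPs (70% het), 200
planted editing events with per-sample editing rates drawn from
U(0.3, 0.9), 30x DNA and RNA depth, 90-bp reads, 0.5% sequencing error,
and pattern weights putting 7% of events in ALL so that roughly 93% of
planted events are stage specific. 80% of planted events are A-to-G on
the transcribed strand; minus-strand events are written as T-to-C in
genome coordinates. Placement samples a region class first (3'UTR 0.45,
intron 0.30, CDS 0.20, 5'UTR 0.05 within coding models) because editing
concentrates in 3'UTR secondary structure rather than uniformly over the
gene body. miRNA target intervals tile roughly half of each coding
3'UTR.

Pileups are generated directly rather than via read simulation: each
observation carries a uniform read offset, so the distance to the nearer
read end varies and the end-distance filter has real bite. Per-position
depth is Poisson. Base qualities are coupled to error status — correct
bases ~N(34, 5), erroneous bases ~N(12, 6), clipped to [2, 40] — because
a Phred score *is* an error-probability estimate; a simulator that
assigns high quality to wrong bases would make the quality filter
vacuously pass everything. Caller VCF pairs are derived from the same
pileup with different sensitivity: caller A calls any alternate with ≥2
supporting reads; caller B additionally requires allele fraction ≥ 0.1,
so the union/intersection merge rules have observable effect. One RNG
stream per output file, all derived from the master seed, makes the
whole dataset byte-reproducible.

What the generator does **not** emulate: alignment and mapping error,
indels, strand-specific library artifacts, hyper-edited read clusters,
realistic quality-score autocorrelation along reads, and poly(A)+/−
fractionation (one RNA library per sample). Passing tests on synthetic
data therefore validate the *logic* of the cascade — set semantics,
threshold boundaries, strand handling, bookkeeping — not robustness to
alignment artifacts on real data.

### Ground truth and what "recovery" means

Under the site-level minimum end-distance rule, a site with k supporting
reads passes only if *all* k land ≥15 bp from both read ends — at 30x
and editing rates 0.3–0.9 that has probability (1 − r/3)^depth, a few
percent per site-sample. This is the faithful consequence of the
thresholds: most planted events are *not* expected to survive, exactly
as most true editing in tissue does not clear a stringent cascade.
Recovery is therefore measured against the generator's per-site-sample
`detectable_*` flags — an independent re-evaluation, over the realized
pileups, of every detection condition (both callers fire, single
alternate allele, DNA covered with a differing genotype, four filters).
Sensitivity is recovered/detectable; precision is true/reported; both
use the vacuous-truth convention (1.0) on an empty denominator. Pattern
agreement is likewise checked against the detectable presence set, since
a site planted in three samples but threshold-satisfying in one can only
ever be observed as sample-unique.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; BED is converted on read.
* Genotypes are unordered allele pairs; phasing is ignored.
* Hypergeometric p-values use `phyper` (upper tail via `k - 1`), checked
  in tests against direct probability-mass summation to 1e-12.
* A CDS whose spliced length is not divisible by 3 flags the transcript
  and skips its sites with a warning rather than failing the run.
* An empty candidate set, empty SNP tables, zero planted sites, or an
  enrichment call with n = 0 all degrade gracefully (identity, empty
  outputs, or an NA result with a warning, respectively).
* Filter-audit attribution is deterministic (first failing filter in the
  listed order); survival itself is order-independent.

## Problem sizes

The shipped tests run the full pipeline on datasets of 40–200 planted
events over 60–200 kb of genome, and the acceptance script uses 400
planted events; at these sizes a complete simulate–detect–annotate–
classify–analyze run takes a few seconds on one CPU. All sizes are
configuration, not code: `simulation_config()` scales every axis
independently.

## Known limitations

* The detection layer consumes caller VCFs; it does not re-run GATK or
  VarScan, and caller-specific quirks (e.g. VarScan's minimum variant
  frequency) belong to the inputs.
* Catalog comparison (DARNED-style), GO enrichment and enrichment-map
  rendering are deliberately external; the pipeline emits the gene lists
  those tools consume.
* Strand assignment relies entirely on the transcript annotation; sites
  in unannotated or doubly-stranded regions are discarded, not rescued
  by read-level strand evidence.
* The multi-allele removal rule and the end-distance statistic both have
  alternative readings; this package fixes one of each (supported-allele
  counting; site-level minimum over nearer ends) and documents them
  here.
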