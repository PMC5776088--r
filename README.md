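# editomescan

Detection and characterization of RNA editing sites from matched DNA and
RNA sequencing evidence of the same individual, across a four-sample
liver-cancer progression design: non-cancerous liver (NL), primary tumor
(PT), intrahepatic metastasis (IM) and portal vein tumor thrombus (PTVV).

RNA editing — chiefly ADAR-mediated A-to-I deamination, read as A-to-G —
is found by looking for *RNA–DNA differences*: positions where RNA
variant evidence contradicts the individual's DNA genotype. Because
germline polymorphism, caller artifacts, read-end misalignment and
sequencing error all masquerade as RDDs, the package implements a
stringent filtering cascade and then characterizes what survives.

## What the package does

Per sample, for variant call sets from two callers per modality:

1. **Merge** — DNA calls by union, RNA calls by intersection.
2. **RDD identification** — keep RNA variants whose genotype differs
   from the DNA genotype (homozygous reference where no DNA variant was
   called and DNA coverage suffices); remove sites displaying more than
   one supported alternate allele.
3. **Evidence filters** — on the RNA pileup: minimum Phred quality of
   supporting bases ≥ 20, depth ≥ 5, distance of the site to the nearer
   end of every supporting read ≥ 15, supporting reads ≥ 2.
4. **Germline subtraction** — drop sites at known-SNP positions.

Surviving sites are annotated against gene models (UTR5/CDS/Intron/UTR3
for coding, Exon/Intron for lncRNA; strand-ambiguous and intergenic
sites discarded), typed on the transcribed strand (12 substitution
types), given repeat context (Alu / repetitive non-Alu /
non-repetitive), and classified by presence across the four samples into
seven patterns (ALL, STN, ST, NL, PT, IM, PTVV). Functional impact:
hypergeometric enrichment of 3'UTR sites in miRNA target intervals
(base-resolution universe), synonymous/non-synonymous recoding of CDS
sites via spliced-codon translation, and Kolmogorov–Smirnov comparison
of expression changes of edited transcripts against background.

A first-class synthetic-data generator (`generate_dataset()`) produces a
self-consistent toy dataset — genome, gene models, repeats, germline
SNPs, planted editing events with per-sample presence patterns, pileups,
two-caller VCFs, expression and annotation tables — with known ground
truth, so every stage of the cascade is testable at desk scale.

## Worked example

```r
library(editomescan)

cfg <- simulation_config(seed = 7)     # 200 planted events, 30x, 4 samples
res <- run_pipeline("run7", config = cfg)
evaluate_recovery(res)
#> $sensitivity         [1] 1
#> $precision           [1] 1
#> $n_detectable        [1] 4
#> $n_detected          [1] 4
#> $n_true_positive     [1] 4
#> $n_germline_reported [1] 0

res$patterns
#>   chrom   pos ref alt presence pattern
#> 1  chr2 18820   T   C       NL      NL
#> 2  chr2 19296   T   C       IM      IM
#> 3  chr2 32989   A   G       PT      PT
#> 4  chr2 46017   A   G       PT      PT
```

Reading the output: of 200 planted editing events, exactly 4 site–sample
events satisfied every detection threshold on their realized read
evidence (`n_detectable`) — the dominant attrition is the read-end
distance rule, which requires *every* supporting read to carry the site
at least 15 bp from both ends — and the pipeline recovered all 4 with no
false positives and no germline SNP reported as editing. The two T-to-C
sites sit on minus-strand transcripts, i.e. they are A-to-G events on
the transcribed strand. The per-sample funnel is in the manifest, e.g.
for PT: 241 merged RNA variants → 90 RDD candidates → 2 after the four
filters (8 removed by base quality, 80 by end distance) → 2 after
germline subtraction.

Stage tables (`sites_<sample>.tsv`, `patterns.tsv`, `venn_counts.tsv`,
`annotated_sites.tsv`, `region_distribution.tsv`, `mirna_enrichment.tsv`,
`recoding.tsv`, `ks_expression.tsv`, per-sample damaging gene lists) and
`manifest.json` are written to the output directory; all tables are TSV
with a `#`-prefixed header.

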