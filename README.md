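# teflank

Full-site vs empty-site analysis of heterochromatin spreading from
transposable-element (TE) insertions.

## The problem

Retrotransposons such as mouse IAP endogenous retroviruses are silenced
by repressive chromatin (H3K9me3, H4K20me3, DNA methylation), and that
silencing can spread into flanking genomic DNA — potentially affecting
nearby genes.  Demonstrating spreading requires separating what the
element *induces* from what its neighbourhood already was.  The clean
design compares two strains that are **insertionally polymorphic**: the
same locus carries the element in one genome (the *full site*) and not
in the other (the *empty site*), while *common* copies present in both
genomes act as matched controls.  `teflank` is for epigenomics groups
who have per-line ChIP-seq/MeDIP-seq alignments, a table of polymorphic
insertions, and want the comparative flank analysis done reproducibly.

## The statistic

Enrichment of a region in each line is its RPKM,

    RPKM = n / (L_kb * N_millions)

(`n` fractional reads in the region, `L_kb` region length in kb,
`N_millions` filtered library size in millions), and the two lines are
compared by the **RPKM asymmetry**

    A = (RPKM_A - RPKM_B) / (RPKM_A + RPKM_B + eps)

bounded in [-1, 1]: 0 for equal enrichment, +1 for enrichment only in
the full-site line, -1 only in the empty-site line.  Per-copy asymmetry
distributions over oriented flank distance windows (<1 kb, 1–2.5 kb,
2.5–5 kb by default), their skewness, Kruskal–Wallis/Dunn tests across
windows, per-copy flank heatmaps, a mappability filter, a gene-impact
filter (TSS proximity + full-site-only promoter enrichment + reduced
expression), and a genome-wide differential-asymmetry scan complete the
pipeline.  A synthetic two-line cohort generator with ground truth
(`sim_config()` / `simulate_cohort()`) makes every stage testable
without external data.

## Worked example

Simulate a cohort with 8-fold flank enrichment spreading 1 kb from each
polymorphic element, then measure the spreading:

```r
library(teflank)

cfg <- sim_config(seed = 42, n_chroms = 2, chrom_len_bp = 5e6,
                  n_common_copies = 20, n_polymorphic_copies = 60,
                  flank_fold = 8, spreading_len_bp = 1000, n_genes = 10)
cohort <- simulate_cohort(cfg)

reads_a <- filter_reads(cohort$reads_a)   # mapq >= 7, unique, dedup
reads_b <- filter_reads(cohort$reads_b)
N_a <- nrow(reads_a); N_b <- nrow(reads_b)
masked_a <- mask_te_reads(reads_a, cohort$te_table, 150, cohort$chrom_sizes)
masked_b <- mask_te_reads(reads_b, cohort$te_table, 150, cohort$chrom_sizes)

poly <- cohort$te_table[cohort$te_table$status == "polymorphic", ]
rec <- windowed_asymmetry(masked_a, masked_b, poly, N_a = N_a, N_b = N_b,
                          chrom_sizes = cohort$chrom_sizes)
aggregate(asymmetry ~ window_label, rec, median)
#>   window_label  asymmetry
#> 1         <1kb  0.7591253
#> 2      1-2.5kb -0.0149315
#> 3      2.5-5kb -0.0780697

summarize_distribution(rec[rec$window_label == "<1kb", ])
#> n = 60, median = 0.7591, skewness = -0.3566

kd <- kruskal_dunn(split(rec$asymmetry, rec$window_label))
round(c(H = kd$H, p = kd$p_kw), 4)
#>       H       p
#> 123.024   0.000
```

Reading the numbers: the first kilobase of flank is strongly and almost
uniformly more enriched at full sites (median asymmetry 0.76, left-tailed
distribution — skewness −0.36 with the mass piled towards +1), while
beyond 1 kb the two lines are indistinguishable (medians near 0), exactly
the planted 1-kb spreading length; the Kruskal–Wallis test confirms the
windows differ (p < 0.001).

The full pipeline is also scriptable:

```sh
Rscript inst/scripts/teflank.R all --seed 7 --outdir out/
```

which chains simulate → profile → asymmetry → spreading → scan →
gene-impact, writing TSV/BED/bedGraph artifacts plus run logs.

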