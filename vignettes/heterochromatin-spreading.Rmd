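---
title: "Quantifying heterochromatin spreading from TE insertions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterochromatin spreading from TE insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The comparison this package implements

Young endogenous retroviruses such as mouse IAP elements are silenced by
repressive chromatin (H3K9me3, H4K20me3, DNA methylation), and that
silencing can spread outward into flanking genomic DNA.  Measuring such
spreading from a single genome is confounded: an element's flanks may be
heterochromatic for reasons that have nothing to do with the element.
The clean design is the *full-site / empty-site* comparison: take two
strains (here, two ES cell lines) that are insertionally polymorphic —
the element is present in one genome and absent at the orthologous locus
of the other — and compare the same flanking sequence with and without
the insertion.  Copies present in both genomes ("common") serve as the
matched negative control.

`teflank` implements that comparison end to end: I/O for the standard
formats, read filtering, fragment coverage, strand-aware flank
profiles, the RPKM-asymmetry statistic with its skewness summary,
distance-windowed spreading estimation with Kruskal–Wallis/Dunn tests,
per-copy heatmap matrices, a mappability filter, a gene-impact filter,
a genome-wide differential-asymmetry scan, and a synthetic two-line
cohort generator with ground truth.

## The statistic

For a region of interest, each line's enrichment is summarized as

\[ \mathrm{RPKM} = \frac{n}{L_{kb}\,N_{M}} \]

with \(n\) the fractional number of reads assigned to the region,
\(L_{kb}\) the region length in kilobases and \(N_M\) the total
filtered library size in millions.  The two lines are compared by the
**RPKM asymmetry**

\[ A = \frac{\mathrm{RPKM}_A - \mathrm{RPKM}_B}
           {\mathrm{RPKM}_A + \mathrm{RPKM}_B + \epsilon} \]

bounded in \([-1, 1]\): 0 means equal enrichment, +1 enrichment only in
the full-site line (A), −1 only in the empty-site line (B).  \(\epsilon\)
(default `1e-9`, configurable) only guards the 0/0 case; for any signal
of RPKM magnitude ≥ 1 its effect is below 1e-9.  Distributions of
per-copy asymmetries are summarized by their median, a histogram, and
the adjusted Fisher–Pearson skewness
\(G_1 = \frac{n^2}{(n-1)(n-2)}\, m_3 / s^3\) — the convention used by
common desktop statistics packages, so published values computed that
way are directly comparable.  Skewness values are convention-dependent;
this is why the convention is pinned and tested against an independent
moment computation.

## Pipeline conventions and tunable parameters

* **Coordinates** are 0-based half-open internally (BED native).
  Published TE tables are 1-based inclusive and are converted on read.
* **Read filtering** (`filter_reads`): mapping quality ≥ 7 (the BWA
  quality cutoff used for the original libraries), multi-mapping reads
  dropped, positional duplicates (same chromosome, 5′ position, strand)
  counted once.
* **Fragment extension** (`extend_read`): reads are extended
  directionally from the 5′ end to a *total* length of 150 bp — native
  ChIP of mono-nucleosomes makes the fragment itself ≈ 150 bp, so
  "extended by 150 bp" is read as "to 150 bp total".  The parameter is
  per-assay (use ≈ 200 bp for MeDIP-style libraries); the alternative
  reading (read length + 150) can be had by passing
  `fragment_len = read_len + 150`.
* **TE masking** (`mask_te_reads`): whole reads whose extended fragment
  overlaps any element body by ≥ 1 bp are excluded from flank analyses,
  so element-internal signal cannot leak into flank statistics.  The
  gene-impact enrichment filter is the deliberate exception: detecting
  signal *at the copy itself* requires unmasked tracks.
* **Flank windows**: per-copy asymmetry uses the oriented distance
  bands `[0,1) kb`, `[1,2.5) kb`, `[2.5,5) kb` by default, pooling the
  5′ and 3′ flanks into one region per copy (one asymmetry per copy, as
  in the per-copy distribution figures; per-side mode is kept for
  heatmaps).  The band boundaries are configurable; the defaults
  reconcile a "<1 kb" near window with 1.5/2.5 kb outer windows.
* **Fractional counting**: a fragment contributes to a region by the
  proportion of its length inside the region (a "fractional number of
  reads"); 5′-end containment counting is available as
  `count_mode = "five_prime"`.
* **Windows truncated** at a chromosome edge are zero-padded for
  profiles but flagged and excluded from distribution summaries, to
  avoid length bias (whether the original analysis excluded them is
  not stated; we exclude and log).
* **Heatmap ordering**: rows sorted by total 5′-flank coverage in the
  full-site line, descending; the identical permutation is applied to
  the empty-site matrix.  Ties are broken lexicographically by copy id
  for determinism.
* **Dunn post-hoc**: the omnibus Kruskal–Wallis test is tie-corrected;
  Dunn z-statistics use the pooled tie-corrected rank variance and
  Bonferroni adjustment (the correction was not named in the source
  analysis; Bonferroni is the conservative default).
* **Gene impact**: polymorphic copies within 5 kb of a TSS; "enriched"
  is operationalized as ≥ `min_fold` (default 2) times the
  genome-median 1-kb window RPKM of that line's track — a scale-free
  criterion the source analysis left unspecified; promoter = TSS ± 1 kb
  (also unspecified there).  Expression comparison is a normalized
  RPKM ratio with a fold threshold, deliberately not a fitted
  differential-expression model, mirroring a direct comparison of
  RNA-seq read levels.
* **TSS distance** uses the gap convention of
  `GenomicRanges::distance` (bases strictly between the element and the
  TSS; 0 when overlapping or adjacent).

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per line, Poisson reads from a piecewise
rate landscape: background everywhere; `te_fold` × background inside
present element bodies; in the flanks, an extra `(flank_fold − 1)`
component shaped by a **step kernel** of length `spreading_len_bp`
(default: enrichment out to S bp, background beyond — chosen as the
default because windowed analyses of real spreading show a finite,
sharply bounded extent of roughly one kilobase) or an exponential
kernel for robustness checks.  Polymorphic copies contribute enrichment
only in line A; both lines' reads are emitted in the coordinates of the
insertion-carrying reference, as when both strains are aligned to the
reference that contains the full sites.  The central
`mappability_hole_frac` (default 0.5) of every body is non-uniquely
mappable; reads starting there carry `is_unique = FALSE` and die in
filtering — half-mappable bodies are a realistic middle ground for
young ERVs while keeping body enrichment detectable, as it is for a
mappable solo LTR.

Two library-size semantics are provided.  With `lib_size_* = NULL` the
strata are drawn at their stated rates, so moment identities like
E[body reads] = `background_rate × te_fold × te_len` hold exactly.
With targets set (e.g. equal sizes for both lines, emulating libraries
sequenced to matched depth — the real libraries differed by under 2%),
the whole landscape of a line is rescaled so its expected total matches
the target.  The default cohort genome (4 × 20 Mb) keeps TE-derived
reads a small fraction of each library, as in real data; on a genome
that is mostly TE flank, library normalization alone would shift
distal-window asymmetries — an artifact of desk scale, not of the
statistic.

A green test on synthetic cohorts establishes that the machinery
recovers planted effects of the stated sizes under Poisson sampling.
It does **not** establish robustness to what the generator omits:
non-uniform (GC- or accessibility-driven) backgrounds, fragment-length
variability, copy-to-copy heterogeneity of spreading, overlapping or
nested repeats, or alignment artifacts beyond the binary uniqueness
flag.

## Numerical and degenerate-input choices

* `rpkm()` refuses zero-length regions and zero-size libraries rather
  than returning infinities.
* Zero-variance asymmetry distributions have undefined skewness:
  `summarize_distribution()` warns and reports `NA` rather than a
  number.
* Fully off-chromosome windows count zero reads and are flagged;
  placement in the generator is rejection-sampled with a 5-kb flank
  margin and fails loudly after 1000 attempts per element if the
  genome is over-full.
* The scan recovers window read counts from coverage as
  `sum(values)/fragment_len`, exact for unclipped constant-length
  fragments; `min_rpkm` guards against high-asymmetry calls at
  negligible coverage.
* bedGraph output is written with `%.17g` so step-constant tracks
  round-trip bitwise.

## Known limitations

Single-end, constant-length fragments only; no peak calling and no
per-copy significance (distributions, not p-values, are the unit of
inference); empty-site loci are represented by the reference interval
of the full-site element, ignoring the ≤ 20 bp target-site-duplication
ambiguity at the true pre-insertion site; mappability is consumed, not
computed.
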