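---
title: "Comparing the methylome and transcriptome of a cultivar and its bud sport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the methylome and transcriptome of a cultivar and its bud sport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sportmethyl)
```

## The problem

Bud sports are spontaneous somatic mutations of woody perennials; a branch
with an improved trait (deeper fruit colour, earlier ripening) is propagated
clonally as a new cultivar. Because parent and sport are near-isogenic, much
of the phenotypic difference is expected to be epigenetic, and DNA methylation
is the prime suspect: cultivar pairs differing in peel colour repeatedly show
methylation differences over anthocyanin-pathway genes and their MYB
regulators. Testing that hypothesis genome-wide takes a small analysis stack:
quantify methylation per cytosine context from whole-genome bisulfite
sequencing (WGBS), find differentially methylated regions (DMRs) between the
two methylomes, find differentially expressed genes (DEGs) between the two
transcriptomes, and intersect the two along gene bodies and promoters.
`sportmethyl` implements that stack as reusable, tested functions, together
with a synthetic-data generator that plants known DMRs and DEGs so every
stage can be validated against ground truth.

## The statistics

**Methylation level.** For pooled read counts at a cytosine or over a region,

$$R_m(\%) = \frac{N_m}{N_m + N_{nm}} \times 100,$$

where $N_m$ and $N_{nm}$ are methylated and unmethylated read counts
(`methylation_level()`). Sites with zero coverage are undefined and excluded,
never imputed as zero. Contexts (CG, CHG, CHH with H ∈ {A, C, T}) are
assigned 5'→3' on the strand carrying the cytosine (`classify_context()`).

**DMR calling.** `call_dmrs()` slides windows (default 200 bp advancing by
50 bp) along each chromosome. Within a window and context it pools counts
over the sites covered in *both* samples — a site observable in only one
library cannot support a contrast — and a window is significant when it
holds at least 5 such sites, the pooled levels differ at least 2-fold, and a
two-sided Fisher exact test on the pooled 2×2 table gives $p \le 0.05$.
Overlapping or book-ended significant windows of one context and direction
are merged and all statistics recomputed on the merged span. Direction is
mutant-relative: *hyper* means the sport is the more methylated. The
accompanying effect descriptor is the degree of difference
$\log_2 R_{m1} / \log_2 R_{m2}$ on the percent scale, with a level of 0
adjusted to 0.001 before taking logs (`degree_of_difference()`).

**DEG calling.** `divergence_probability()` reimplements the nonparametric
(M, D)-versus-noise idea of NOISeq-style callers on FPKM-normalised counts:
per gene, $M = \log_2\frac{\bar x_2 + k}{\bar x_1 + k}$ and
$D = |\bar x_2 - \bar x_1|$ over the condition means; the noise distribution
collects the same pair from every within-condition replicate pair of every
gene; the divergence probability is the fraction of noise points strictly
dominated in both coordinates. `call_degs()` applies the published rule:
DEG ⇔ fold change ≥ 2 and probability ≥ 0.8.

**Integration and enrichment.** `associate_dmrs()` links DMRs to gene bodies
(any overlap with the gene span) and promoters (any overlap with the 2-kb
strand-aware interval upstream of the TSS); `cross_tabulate()` counts DEGs
per (up/down × hyper/hypo × body/promoter) cell;
`methylation_expression_contrast()` compares the M distribution of each DMR
gene class against the all-gene background with box-plot quartiles and a
two-sided Wilcoxon rank-sum test. `enrich_terms()` performs flat
hypergeometric gene-set enrichment with Bonferroni correction over the
tested terms — the same interface serves GO-style and pathway-style maps; no
ontology traversal is attempted.

**Bench-side formulas.** `anthocyanin_content()` is the pH-differential
quantification $\Delta A \times 5 \times 0.005 \times 1000 \times 449.2 /
(26{,}900 \times 0.5)$ mg/g FW with every constant (dilution, volume,
reference-pigment molecular weight and absorptivity, sample mass) exposed as
a parameter; `relative_expression()` is the qPCR $2^{-\Delta\Delta C_t}$
method. `score_bisulfite_clone()` scores bisulfite-PCR clones against their
reference (C → methylated, T → converted, otherwise mismatch).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_bp`, `step_bp` | 200, 50 bp | sliding-window geometry; the published rule fixes only the thresholds, so these are the conventional WGBS values |
| `min_sites` | 5 | shared covered context sites a window must hold |
| `min_fold` | 2 | fold change between pooled levels (percent scale, 0 → 0.001) |
| `alpha` | 0.05 | Fisher threshold; `fdr_mode = "BH"` optionally replaces the raw-p rule with Benjamini–Hochberg |
| `promoter_bp` | 2000 bp | promoter length upstream of the TSS |
| `min_depth` | 4 reads | site-level summary coverage filter; pooled statistics always use all reads |
| `pseudocount` | 1 FPKM | stabilises M at low expression |
| `min_prob` | 0.8 | divergence-probability threshold for DEGs |

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the benchmark conditions: context baselines
CG 52%, CHG 38%, CHH 15% (mid-range of published apple peel methylomes);
negative-binomial read depth with mean 20 (matching the reported 10–20×
coverage peak with a long tail); bisulfite conversion error 0.5% (reported
conversion rates were 99.4–99.6%); planted DMRs at 80% vs 10% levels; and
negative-binomial counts with three replicates per condition and planted
≥2-fold DEGs. A fully unmethylated control chromosome emulates the
spike-in used to estimate the conversion rate; being a spike-in it is
excluded from DMR calling and genome-wide summaries.

Deliberate simplifications:

* methylation is simulated independently per strand; symmetric-CG coupling
  is not modelled (no stage of the pipeline merges strands);
* no read-level errors, M-bias, PCR duplicates or mapping artefacts — only
  conversion error;
* base composition is i.i.d. at a set GC fraction, so there are no
  transposon-dense or CpG-island-like regions;
* DMR placement is uniform (rejected on overlap), half forced onto genes or
  promoters so annotation stages see positives, half intergenic.

Passing the planted-truth tests therefore demonstrates the correctness and
calibration of the *statistics*, not robustness to alignment artefacts or
genome structure that real libraries carry.

The expression side inherits a known property of per-sample FPKM (the
normalisation the pipeline deliberately sticks to, without TMM or quantile
steps): when a large fraction of the transcriptome is planted differential,
library totals shift and M estimates are compressed toward the majority
direction. With realistic DEG fractions (≤ 10% of genes) the effect is
negligible; simulations that plant most of the transcriptome will show it.

## Numerical and design choices

* **Fisher p.** Two-sided p is the sum of hypergeometric probabilities of
  all tables with the observed margins whose probability does not exceed the
  observed one, with a relative tolerance of 1e-7 on the comparison; an
  all-zero table gives p = 1. The test is on *pooled window counts* — the
  published criterion states one test per region, and pooling is the only
  reading consistent with that.
* **Zero levels.** The 0 → 0.001 substitution of the degree-of-difference
  formula is reused for fold changes, so an all-zero-versus-positive window
  can pass the fold filter. Both are computed on the percent scale exactly
  as the formulas are printed; the fraction scale would change the numbers,
  and the choice is stated here because the printed formula is ambiguous.
* **Degree of difference** is undefined when the adjusted denominator level
  equals 1 (log2 = 0); such values are returned as `NA` with a warning.
* **mC site call.** For mC-proportion summaries a covered site is a called
  methylcytosine when a one-sided binomial test against the conversion-error
  rate rejects at p < 0.05 (Lister-style practice); with error 0 this
  reduces to "any methylated read".
* **Multiple testing** defaults to the raw `p ≤ alpha` rule exactly as
  published; `fdr_mode = "BH"` is provided for stricter use and is
  deliberately off by default.
* **DEG rule.** The caller uses the divergence-probability criterion
  (fold ≥ 2 and probability ≥ 0.8) throughout; it does not offer a parametric
  p-value mode, since the noise-comparison probability is the procedure this
  rule defines. Noise ties count against the gene (strict inequalities).
  With single-library conditions, technical replicates are simulated by
  seeded multinomial resampling of the library (5 draws) for the noise set
  only.
* **Determinism.** One master seed; each generator stage derives a fixed
  sub-stream (+0 genome, +1 annotation, +2 methylomes, +3 expression), so
  identical configurations are byte-identical, including written files.

## Problem sizes used by the test-suite benchmarks

The recovery benchmarks run on a 2-Mb two-chromosome genome with 100 planted
1-kb CG DMRs at depth 20 (sensitivity ≥ 0.95 demanded, false-plant rate
≤ 0.10), a 0.5-Mb no-plant null for window calibration, and 1000–2000-gene
count matrices for DEG recovery (100 four-fold plants at mean 1000) and null
false-positive rates. These sizes were chosen as the smallest at which the
binomial and negative-binomial sampling errors are far below the tested
margins, and they complete in seconds to tens of seconds.

## Known limitations

* No smoothing-based DMR model (BSmooth/methylKit-style); windows are
  rectangular and merging is purely positional.
* Promoters are fixed-length upstream intervals; no annotation of UTRs,
  CpG islands or repeats.
* The enrichment module treats term maps as flat sets.
* FPKM is the only expression normalisation offered, by design.

## A short end-to-end run

```{r, eval = FALSE}
cfg <- sim_config(seed = 42, n_chrom = 1, chrom_length = 1e6, n_genes = 80,
                  n_dmrs = 10, n_degs = 12, deg_fold = 4)
sim <- simulate_comparison(cfg, "example_run")
parent <- sim$methylomes$parent
sport  <- sim$methylomes$sport

methylome_summary(parent, control_chrom = "chrC")
dmrs <- call_dmrs(parent[chrom != "chrC"], sport[chrom != "chrC"])
evaluate_dmr_recovery(dmrs, sim$methylomes$truth)

degs <- call_degs(divergence_probability(sim$expression$counts,
                                         sim$expression$gene_lengths,
                                         sim$expression$conditions))
assoc <- associate_dmrs(dmrs, sim$annotation$genes)
cross_tabulate(degs, assoc)
```

The same flow, file-based and manifest-logged, is available as
`run_comparison()` and the thin command-line wrapper in
`inst/scripts/run-comparison.R`.
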