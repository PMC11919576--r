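---
title: "Methods: case/control burden, CNV consensus and differential methylome analysis"
author: "icepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control burden, CNV consensus and differential methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icepipe)
```

# Overview

`icepipe` reimplements, as a tested pipeline, the three computational
case/control analyses used in rare-disease cohort studies that combine
whole-genome sequencing with genome-wide methylation profiling — the kind
of study design used for iridocorneal endothelial (ICE) syndrome, where a
small case cohort (tens of genomes) is compared against a small in-house
control cohort and a large summary-level population database:

1. **Rare-variant burden testing** under the dominant model, with
   quality-tranche calibration against a benign variant stratum
   (`run_burden_stage()`);
2. **Two-caller CNV consensus** with cross-sample recurrence and a
   region-level case/control frequency comparison (`run_cnv_stage()`);
3. **Differential methylome analysis** from per-CpG bisulfite counts:
   hypomethylated regions, cohort recurrence, region t-tests, gene
   mapping and set enrichment (`run_methylome_stage()`).

Because studies of this kind cannot deposit patient-level data, the
package ships a deterministic synthetic-cohort generator
(`simulation_config()`, `simulate_burden_cohort()`,
`simulate_cnv_callsets()`, `simulate_methylomes()`) that emulates the
statistical structure each stage assumes, with truth tables for recovery
testing. All intervals are held as `GRanges` (1-based, closed)
internally; BED, bedGraph, VCF and Bismark coverage files are converted
at the I/O boundary, so a BED line `chr19 15783859 15791329` has width
7470. (Some published CNV tables print `end - start - 1`, e.g. 7469 for
that interval; the package consistently reports `end - start`.)

# Burden testing

## Counting and the 2×2 table

A *qualifying variant* is defined per stratum (inclusive thresholds):

| stratum | rarity (max population AF) | functional rule |
|---|---|---|
| coding-altering | ≤ 0.01 | consequence missense or LoF |
| deleterious noncoding | ≤ 0.001 | deleterious by all of GERP++, GWAVA, CADD |
| benign coding (calibration) | ≤ 0.01 | synonymous |
| benign noncoding (calibration) | ≤ 0.001 | deleterious by none of the three |

Under the dominant model, the case count for a feature is the number of
distinct samples carrying ≥ 1 qualifying allele there
(`count_case_carriers()`; missing genotypes count as non-carriers and
are reported separately). Summary-level controls provide no genotypes,
so the control count is the sum of alternate allele counts over the
feature's qualifying sites, treating each allele as a distinct carrier
and capping at the cohort size (`estimate_control_carriers()`) — the
standard approximation when testing against population databases. The
one-sided p-value is the exact hypergeometric tail
$P(X \ge a)$ of the table $[[a, n_\text{case}-a], [c,
n_\text{ctl}-c]]$ (`fisher_one_sided()`), and significance is flagged at
the Bonferroni level $\alpha / \#\{\text{features tested}\}$ (the
denominator is reported; published thresholds such as
$8.3\times10^{-7}$ imply genome-wide feature counts and are
configurable via `bonferroni_n`).

Both cohorts are first restricted to bases where ≥ 90% of samples are
covered in each cohort (`build_callable_mask()`, inclusive) and purged
of low-complexity regions (`apply_region_filters()`).

## Inflation calibration: λ95 on mid-p values

Because case and control call sets are produced by different pipelines,
case-only genotyping artifacts inflate burden statistics. The
calibration statistic is

$$\lambda_{95} = \frac{\widehat{Q}_{0.95}\left(F^{-1}_{\chi^2_1}(1-p_i)\right)}{3.841459},$$

the ratio of the empirical 95th percentile (linear-interpolation
quantile) of chi-square-transformed p-values to the theoretical
$\chi^2_1$ 95th percentile. One design decision matters here: the exact
one-sided Fisher p-value is *discretely conservative* — on a perfectly
matched null cohort (51 cases vs 9197 summary controls, per-gene carrier
rate 0.2) its λ95 concentrates near 0.87, not 1. `burden_scan()`
therefore also reports the **mid-p** value
$P(X > a) + \tfrac12 P(X = a)$, which is the standard correction for
discrete tests, and the calibration path (`lambda95()` inside
`calibration_sweep()`) uses it; mid-p restores λ95 ≈ 0.98–1.01 on null
cohorts. Reported per-feature p-values remain the exact tail — the
worked example table (27/51 cases vs 62/350 controls) reproduces its
published p of 2.06×10⁻⁷.

`calibration_sweep()` scans a grid of quality-inclusion tranches: for
each tranche $q$ it keeps the top-$q$ fraction of case variants by the
site quality metric, runs the benign-stratum burden scan and computes
λ95; the chosen tranche is the **largest** $q$ whose λ95 falls inside
the tolerance band (more data preferred). The default band is
[0.9, 1.1]: with ~1000 features the λ95 estimator has sampling sd of
about 0.03–0.04, so a ±0.05 band would reject well-calibrated cohorts in
roughly a fifth of runs; ±0.1 gives sensible operating characteristics
at this feature count. Even so, selection remains a statistical decision
with a residual error rate of a few percent per cohort — an inherent
cost of estimating a tail quantile from 1000 features.

## Descriptive summaries

`mutations_per_mb()` computes per-sample, per-class variant rates
(count / class length in Mb), summarises mean ± sd per class and tests
each class against coding with two-sample t-tests under
Benjamini–Hochberg adjustment. `variant_sharing_summary()` reports the
fraction of qualifying variants private to a single case, plus the full
sharing histogram.

# CNV consensus

Per sample, same-type calls from the two callers are paired when their
**reciprocal overlap** — $\min(o/|A|, o/|B|)$ — is ≥ 0.5 (inclusive),
using greedy best-overlap matching so each call is used at most once;
the consensus call averages the two starts and the two ends (rounded
half up, for determinism). Opposite types (DEL vs DUP) never merge.
Cross-sample recurrent regions reuse the same 50% reciprocal rule as a
graph: same-type consensus calls are linked when they overlap
reciprocally ≥ 0.5 and connected components become regions whose
interval is the coordinate-wise mean of members and whose *patient
frequency* is the number of distinct supporting samples
(`cluster_across_samples()`; the result is input-order invariant and
idempotent). Regions are annotated with every gene overlapping ≥ 1 bp,
in genomic order.

The read-depth signal comparison used by dedicated CNV case/control
tools is out of the package's scope; region-level comparison is a
one-sided Fisher test of carrier frequencies per region with BH
adjustment (`compare_region_frequencies()`), with control support
counted as samples having a same-type consensus call at ≥ 50% reciprocal
overlap with the region (`count_region_support()`).

# Differential methylome

Per-CpG counts (Bismark coverage format) are filtered to coverage ≥ 5
reads (inclusive). HMR intake accepts external per-sample HMR intervals;
the built-in `call_hmrs_simple()` is a deliberately transparent
threshold segmenter, not an HMM: maximal runs of ≥ 4 consecutive CpGs
with beta ≤ 0.5, uninterrupted and with ≤ 500 bp between neighbours.
These defaults are exposed and should be tuned against a reference
segmentation when one is available.

`recurrence_scan()` discards non-focal HMRs (> 10 kb), tiles the genome
in non-overlapping 100-bp windows anchored at coordinate 0, marks a
window when ≥ 5% of samples (inclusive) have an overlapping HMR, and
merges maximal runs of adjacent qualifying windows. "Contiguous" means
adjacent tiles with no gap — a deterministic reading, since only the
window size is standard. Each region's recurrence is the fraction of
samples with any overlapping focal HMR. Regions are annotated by first
overlap in the precedence promoter > enhancer > dyadic, and
independently island > shore > shelf > open sea.

The DMR unit is the recurrent-HMR set computed on cases and controls
jointly — the pipeline tests exactly the regions it has already defined,
rather than inventing a separate windowing. Per region and sample,
methylation is the coverage-weighted mean beta of covered CpGs
(`region_methylation_matrix()`); the group comparison is the
pooled-variance two-sample Student t-test (a flag switches to Welch),
BH-adjusted, with DMRs at q ≤ 0.05 (`dmr_test()`). Regions with fewer
than two values per group, or zero variance in both groups with equal
means, are excluded and counted. Differential methylation is the
difference of group mean betas (case − control) on the [0, 1] scale;
`select_recurrent_differential()` applies the strict thresholds
recurrence > 0.10 (computed on cases; the joint fraction is also
reported) and delta < −0.1. Genes whose promoter, exon or intron parts
overlap a DMR are the differentially methylated genes, each reported
once; enrichment over user-supplied gene sets is the upper-tail
hypergeometric test with BH adjustment at q ≤ 0.05.

# The synthetic cohort

The generator's defaults are the study conditions the analyses assume:
51 WGS cases, 350 in-house controls with genotypes, 9197 summary-only
controls (AC/AN only, never materialised as genotypes), 48 case vs 45
control methylomes. The toy genome is 2 chromosomes × 5 Mb with 1000
genes (2 kb bodies) and 200 regulatory segments; the methylome lives on
a 3 Mb contig with a CpG every 60 bp. These sizes keep a full pipeline
run under two minutes on one CPU while leaving per-feature counts large
enough for the calibration statistics to be meaningful; the tests use
them directly (20-seed properties shrink the unused in-house cohort,
which does not enter the statistics under test).

Key modelling choices:

* **Carrier-level genotypes.** Each qualifying carrier receives exactly
  one heterozygous allele at one of 5 candidate sites per gene and
  class. At AF ≤ 0.01, homozygous alternates are effectively unobserved,
  and this makes the summary-control allele sum *exactly* the carrier
  count — so carrier counting (cases) and allele summing (controls) are
  matched under the null, which is what makes λ95 calibration
  interpretable. Rates: coding-altering 0.01 per gene per sample
  (risk genes: 0.3 in cases vs 0.01 in controls), rare synonymous 0.2
  (giving ~10 expected case carriers per gene — large enough that the
  mid-p distribution is nearly uniform), noncoding deleterious 0.01 and
  benign 0.1 per segment, plus one common (AF > 0.01) site per gene to
  exercise the rarity filters.
* **Artifact tranche.** With `artifact_rate > 0`, 35% of genes receive a
  case-only synonymous site carried at rate 0.2, with site quality in
  the extreme lower tail (below half the 5% quantile of the genuine
  quality distribution, which is Normal(20, 4) truncated at 0.5,
  quality-by-depth-like). The artifact mass is matched to the 5%
  tranche width deliberately: the 95% tranche then removes artifacts
  almost exclusively, restoring λ95 ≈ 1, while full inclusion is
  visibly inflated (λ95 ≈ 4) — the qualitative behaviour tranche
  sweeps exist to detect.
* **CNV noise.** 30 truth regions of 5 kb (77% deletions), case carrier
  frequencies uniform on [0.1, 0.8], control frequency 0.02. Each
  carried region is seen by each caller with probability 0.9, with
  Gaussian boundary jitter (sd 50 bp, resampled if the interval would
  collapse), plus Poisson(1) false positives per sample and caller
  (2–10 kb, random type). FP calls rarely replicate across callers, so
  consensus suppresses them.
* **Methylome.** Background beta 0.85; 300 null hypomethylated blocks
  (12 CpGs, beta 0.10) present per sample with block-specific
  probability drawn from [0.05, 0.8]; 300 differential regions at beta
  0.35 in controls, shifted by −0.2 in cases (90% of regions; the rest
  +0.2). The control level 0.35 keeps differential regions inside the
  HMR candidate set, so they are tested by the pipeline's own region
  definitions. Noise has two layers: a per-sample per-block Gaussian
  effect (sd 0.05, the region-scale biological variability the t-test
  sees) and per-CpG beta-binomial counts (overdispersion ρ = 0.05,
  ρ = 0 degenerates to binomial) at Poisson depth 30. Regulatory and
  CpG-context labels are assigned per block (promoter 40%, enhancer
  35%, dyadic 5%; island/shore/shelf 15/5/3%, leaving ~77% of recurrent
  territory in open sea), promoter blocks anchor toy gene models, and
  one gene set concentrates on differential-promoter genes so that
  enrichment has a planted positive.

All randomness flows from one root seed through named substreams (one
per emitted component), so identical configs give byte-identical files
and regenerating one component does not disturb the others. Direction
draws for differential regions are Bernoulli(0.9) per region, so the
realised hypomethylated fraction fluctuates with binomial sd ≈ 0.017
about 0.9.

What the generator does **not** emulate: linkage disequilibrium and
realistic site-frequency spectra, relatedness and ancestry structure,
sex chromosomes, read-level artifacts (only their site-quality
signature), caller-specific breakpoint biases, partially methylated
domains and cell-composition effects. Passing recovery tests therefore
demonstrate the correctness of the *procedures* under their stated
assumptions, not robustness to those real-data complications.

# Numerical choices and degenerate inputs

* Coordinate averaging and interval rounding use round-half-up
  (`floor(x + 0.5)`), never banker's rounding, for cross-platform
  determinism.
* `fisher_one_sided()` evaluates tails with `phyper(..., lower.tail =
  FALSE)` (log-space internals); p-values of exactly 0 fed to
  `lambda95()` are clipped to the smallest positive double with a
  warning.
* Quantiles (tranche cutoffs, λ95) use the type-7 linear-interpolation
  estimator; the tranche cut keeps `qual_metric >= threshold`, so the
  full-inclusion tranche keeps every variant including ties at the
  minimum.
* Tie-breaks: tranche selection prefers the largest inclusion; burden
  results order by (p, feature id); consensus matching orders by
  (overlap desc, call index) — all total orders, so outputs are
  permutation-invariant to input order.
* Degenerate inputs: empty BED files give empty range sets; features
  with no tested variants are reported with p = 1 and `tested = FALSE`;
  regions with no covered CpG anywhere are dropped with a warning;
  zero-variance-equal-mean regions are excluded from the t-test and
  counted; zero-length intervals and negative counts raise validation
  errors.

# Limitations

* The control-side carrier approximation (allele sums, capped) is exact
  in the generator by construction but only approximate on real
  population databases, where multi-allelic carriers and homozygotes
  deflate or inflate counts; published headline p-values computed from
  such tables may not be reproducible from the printed counts alone.
* λ95 estimated from 1000 features has sd ≈ 0.03–0.04; tranche
  selection inherits that noise. More features tighten it as
  $1/\sqrt{n}$.
* The threshold HMR caller is a stand-in; segmentations from an HMM
  caller can be supplied instead and everything downstream is unchanged.
* The recurrent-HMR window construction fixes window anchoring at
  coordinate 0 and treats "contiguous" as gap-free; alternative
  readings shift region boundaries by up to one window.
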