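---
title: "Methods: smoothed-FST selection-signature scans with driftscan"
author: "driftscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothed-FST selection-signature scans with driftscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftscan)
```

## The problem

Exterior defects such as capped hock — a bursa enlargement at the point of
the hock — make pedigree pigs unsalable without affecting performance, and
their genetic basis is usually studied in small within-breed samples where
a genome-wide association study is underpowered. A selection-signature
scan sidesteps per-animal phenotype modelling: animals are split into two
groups (defect present, group I; absent, group II), per-SNP differentiation
between the groups is measured with FST, the noisy per-SNP track is
smoothed over local windows, and regions whose smoothed differentiation is
extreme relative to the genome-wide background are reported and annotated
against gene models and QTL intervals.

driftscan implements that pipeline end to end for SNP-array genotypes in
the PLINK text and binary dialects, with every statistical step written
from first principles and testable against a matched synthetic-data
generator.

## The model

The scan's null model is *pure drift*: descendant-group allele frequencies
scatter around an ancestral frequency $\pi$ with variance
$c\,\pi(1-\pi)$, where $c \in (0,1)$ is the drift parameter. The
Balding–Nichols parameterization makes the group frequency a Beta draw

$$p_g \sim \mathrm{Beta}\!\left(\pi\frac{1-c}{c},\ (1-\pi)\frac{1-c}{c}\right),$$

which has mean $\pi$ and the stated variance. Genotypes are
$\mathrm{Binomial}(2, p_g)$ per diploid sample. A region under
group-differential selection looks like a locally elevated $c$ (or,
equivalently at small scale, a frequency shift between the groups).

### FST estimators

Two per-SNP estimators are provided (`fst_config(estimator = ...)`):

* **`weir_cockerham`** (default): the two-population variance-components
  point estimate $\hat\theta = a/(a+b+c)$ computed from observed genotype
  counts, including the heterozygosity correction terms. It is the field's
  standard unbiased-by-construction moment estimator, defined for unequal
  group sizes and missing calls.
* **`pure_drift_moment`**: a direct moment estimate of the drift parameter
  $c$. With group frequencies $\hat p_1, \hat p_2$ estimated from $2n_g$
  alleles each, the unweighted two-group sample variance
  $s^2 = (\hat p_1 - \hat p_2)^2/2$ has expectation
  $\pi(1-\pi)\left[c + (1-c)\,m\right]$ with
  $m = \tfrac12\left(\tfrac{1}{2n_1} + \tfrac{1}{2n_2}\right)$ the binomial
  sampling contribution; $\pi(1-\pi)$ is estimated without bias by
  $\bar p(1-\bar p) + s^2/2$, and the estimator solves for $c$:
  $$\tilde c = \frac{s^2/\left[\bar p(1-\bar p) + s^2/2\right] - m}{1 - m}.$$

Under simulation the two estimators correlate above 0.99 at equal,
moderately large group sizes, so the downstream smoothing/quantile
machinery is estimator-agnostic. `weir_cockerham` is the default because
its formulas are the community reference point and every value can be
checked against an independent transcription of them (the test suite does
exactly that, to 1e-12).

A caveat worth knowing: any per-variant estimate built on
$(\hat p_1-\hat p_2)^2$ has, under the null and even under a true constant
$c$, roughly the shape of a scaled $\chi^2_1$ variable — strongly
right-skewed, with median about 45% of the mean. Per-variant values are
therefore *mean*-unbiased for $c$ but not *median*-unbiased; summaries of
the per-SNP track should use means (or the smoothed track), never
per-variant medians. The test suite demonstrates both facts.

### Preconditions and clamping

A variant enters the track only if both groups have at least two called
samples and the variant is polymorphic over the pooled sample; others get
`NA` and drop out of smoothing with weight renormalization. Finite-sample
estimates can be negative; by default (`clamp_negative = TRUE`) they are
clamped to 0 *before* smoothing so that sampling noise cannot cancel a
genuine neighbouring signal inside a window, while the unclamped values
stay in the output for audit.

## Quality control

`run_qc()` applies, in order: per-variant missingness, Hardy–Weinberg
exact test, GRM-based relatedness pruning, removal of variants left
monomorphic by sample pruning, and sliding-window LD pruning. Defaults
(`qc_config()`): missing fraction strictly above 2% removes a variant;
HWE exact $p < 10^{-7}$ removes; no retained sample pair may exceed a GRM
entry of 0.75; LD pruning with a 50-SNP window, 5-SNP step and
$r^2 > 0.2$.

Details worth recording:

* The **HWE exact test** is the exact conditional test: given the allele
  counts, the probability of each attainable heterozygote count is
  computed in closed form and the p-value is the sum over counts no more
  probable than the observed one (no mid-p correction). It is tested
  exhaustively against an independent recurrence-based enumeration for
  every genotype configuration with up to 50 samples.
* The **GRM** is the VanRaden method-1 matrix
  $ZZ^\top / \left(2\sum_j p_j(1-p_j)\right)$ with dosages centered at
  $2p_j$ and missing entries mean-imputed; monomorphic variants contribute
  nothing and are excluded from the scale.
* **Relatedness pruning** is greedy: repeatedly drop the sample in the
  most over-cutoff pairs (ties: higher missingness, then lexicographically
  smaller id), which preserves sample size relative to dropping both
  members of each pair. The relatedness statistic is the GRM off-diagonal.
* **LD pruning** computes $r^2$ on mean-imputed, variance-standardized
  dosages (a zero-variance column counts as uncorrelated); windows advance
  in variant index and never span chromosomes; the later-positioned
  variant of a violating pair is removed. Re-running the pruner on its own
  output removes nothing (a tested fixed point).

One interaction deserves emphasis for users of the synthetic generator: a
*very* strong planted frequency shift induces pooled-sample LD between the
planted SNPs themselves (a Wahlund effect — at shift $\delta$ the induced
pairwise correlation is roughly $\delta^2$ over the pooled dosage
variance), so at $\delta \gtrsim 0.6$ the LD-pruning step starts thinning
the planted window before the scan ever sees it. At $\delta = 0.4$ the
induced $r^2$ (~0.06) is safely below the 0.2 threshold.

## Structure diagnostics

`svd_structure()` eigendecomposes the GRM (for a symmetric PSD matrix this
is its SVD); scores are eigenvectors scaled by root-eigenvalues so the full
component set reconstructs the matrix. Signs are fixed by making each
vector's largest-magnitude loading positive, which makes output
deterministic. `cluster_report()` summarizes components 1–2 with per-label
centroids and a mean-silhouette separation score for breed labels and for
group labels; the intended reading is *strong breed separation, no group
separation* — phenotype groups should not be confounded with structure.
The structure diagnostic is computed jointly across breeds, while the scan
itself runs per breed.

## Smoothing, outlier calling, regions

* **Smoothing**: a kernel-weighted mean over a window of
  `smooth_window_snps` SNPs centered on each SNP (uniform by default,
  triangular available), truncated at chromosome ends with weight
  renormalization. The window is 9 SNPs by default: with ~25 kb marker
  spacing that is a ~200 kb footprint, small enough to keep single-gene
  resolution and large enough to suppress single-marker noise. It must be
  odd so the window is centered.
* **Outlier rule**: the threshold is the empirical 99th-percentile
  (type-7, linear interpolation) of all smoothed values genome-wide within
  the dataset, and a SNP is flagged iff *strictly above* it. The rule is
  rank-based, hence invariant to monotone transforms of the track; on a
  constant track nothing is flagged. The quantile is genome-wide (not
  per-chromosome) so one threshold describes one breed comparison.
* **Regions**: runs of flagged SNPs separated by at most
  `region_merge_gap_bp` (default 1 Mb) on one chromosome are merged;
  bounds are the min/max member positions, and member counts are conserved
  by construction. BED exports convert to 0-based half-open at write time.

A calibration fact users should expect at desk scale: flagging the top 1%
of smoothed values on an $m$-SNP dataset yields $\approx 0.01\,m$ flagged
SNPs *by construction*, whether or not anything is differentiated. Because
smoothing correlates neighbours over the window length, those null
exceedances arrive in short runs, so a null or single-signal scan of 5000
SNPs typically reports a handful of background regions besides any true
one. Smoothed-FST outlier calling is a screening rule, not a test with a
false-positive guarantee; region lists should be read with their peak
values and SNP counts, and the generator's `evaluate_recovery()` makes
this background rate measurable for any configuration.

## The synthetic generator

`simulate_genotypes()` realizes exactly the model the scan assumes:
uniform ancestral frequencies on (0.05, 0.5), Balding–Nichols group
frequencies at `background_c` (default 0.01, a realistic within-breed
short-term drift scale), Binomial(2, p) genotypes, uniform missingness
(default 1%), Exponential-increment positions at 25 kb mean spacing
(matching the chip density the pipeline targets), and defaults of 40
samples per group — the scale of a within-breed case/control split of
70–75 animals. Planted windows apply an opposite-sign $\pm\delta/2$ shift
(clipped to [0.01, 0.99]) or a locally elevated `c_planted`; the
frequency-shift mode is the default planting mechanism because $\delta$ is
a directly controllable effect size for power curves. A two-breed mode
(`n_breeds = 2`, `c_breed = 0.1`) adds breed-level drift for the structure
check. Every run requires an explicit seed and is fully reproducible.

What the generator does *not* emulate: background LD between markers
(SNPs are independent given frequencies), pedigree/family structure within
groups, allele-frequency-dependent genotyping error, or chip ascertainment
bias. Passing tests on synthetic data therefore validate the estimator
algebra, the calibration of the quantile rule under exchangeability, and
window/region bookkeeping — not robustness to LD-induced clustering of
null outliers, which on real chip data makes smoothed windows more
correlated than here.

## Problem sizes used in the shipped checks

The packaged tests and the reproduction script run at desk scale, chosen
so the whole suite completes in minutes on one core while keeping every
statistical check well-powered: null-calibration and recovery runs use
5000 SNPs over 5 chromosomes with 40 samples per group (50 replicates for
recovery at $\delta = 0.4$, 15-SNP windows), drift recovery uses 2000
variants at 50 per group, and the oracle comparisons are exhaustive where
the domain is finite (all HWE configurations to $n \le 50$). The bundled
demo pipeline (`inst/extdata/demo_config.yaml`) is smaller still: 1200
SNPs, 25 per group, one planted window.

## Numerical and tie-breaking choices

* Empirical quantiles are R's default type 7; the strict `>` comparison
  means exact ties with the threshold are never flagged.
* HWE p-values compare probabilities with a `1 + 1e-12` relative slack so
  floating-point noise cannot split exactly-tied configurations.
* Greedy removals (relatedness, LD) break ties by missingness then
  lexicographic id, so runs are reproducible across platforms.
* Eigenvector signs follow the largest-|loading|-positive convention.
* The text PLINK dialect stores no allele order, so its reader assigns
  `allele_a` to the lexicographically smaller observed allele and treats a
  single-observed-allele variant as monomorphic in `allele_b`; round trips
  are exact for polymorphic variants, and the binary dialect is fully
  lossless. Coordinates stay 1-based inclusive everywhere except inside
  BED files.

## Known limitations

* The outlier rule's flagged fraction is fixed by the quantile, so the
  false-region background scales with SNP count (see above); there is no
  FDR control across regions.
* The pure-drift moment estimator is designed for two groups; the
  Weir–Cockerham implementation is likewise the two-population form.
* Sex chromosomes are excluded from scans by default and the HWE test has
  no sex-aware variant.
* No haplotype statistics (iHS, XP-EHH) and no association testing —
  the scan screens for differentiation only.

## A worked desk-scale example

```{r example, eval = FALSE}
cfg <- sim_config(n_samples_per_group = 25, n_snps = 1200, n_chromosomes = 3,
                  planted_windows = data.frame(chrom = "2",
                                               start_snp_index = 150,
                                               n_snps = 12, delta = 0.4),
                  seed = 42)
sim <- simulate_genotypes(cfg)
qc <- run_qc(sim$genotypes, qc_config())
scan <- fst_scan(qc$genotypes, fst_config())
summary(scan)
evaluate_recovery(scan, sim$truth)
overlap_regions(scan, sim$genes)
```
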