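---
title: "Reconstructing Metagenomic Species Pan-genomes from gene count tables"
author: "panMSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Metagenomic Species Pan-genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panMSP)
```

## The problem

Shotgun metagenomics of complex communities (such as the human gut) is
routinely summarized as a gene count table: millions of catalog genes in
rows, samples in columns, cells holding the number of reads mapped on each
gene. Most of these genes have no genome of origin. panMSP groups them
without any reference, exploiting two facts about the genes of a single
microbial species:

* **co-occurrence** — core genes are detected in exactly the samples where
  the species is present;
* **co-abundance** — reads mapped on two genes of the same genomes are
  *directly proportional* across samples, with a proportionality coefficient
  roughly equal to their length ratio.

An accessory gene (present in only some strains) satisfies both properties
*only on the subset of samples whose strain carries it*, which is why
ordinary correlation across all samples fails for them: Pearson or Spearman
coefficients decay with gene prevalence, while the measures implemented here
do not (this is verified by the test suite on simulated data).

The result is a set of **Metagenomic Species Pan-genomes (MSPs)**: one
cluster per species, each holding its core genes, accessory genes, and
"shared" genes detected where the species is absent (cross-mapping or
horizontal transfer), organized into modules of co-occurring genes.

## The pairwise model

All statistics work on **raw counts** — normalization would destroy the
count nature of the data that the zero classification relies on. The only
exceptions are (a) bin assignment, which uses depth-normalized counts, and
(b) second-order moments, which are computed on square-root transformed
counts, the classical variance-stabilizing transform for Poisson data.

For an ordered gene pair $(g_1, g_2)$ over samples $S$:

**Proportionality coefficient.** $\alpha$ is the midpoint-median of the
ratios $g_{2,s}/g_{1,s}$ over samples where both counts are at least
$t = 6$. Restricting to jointly detected, reasonably quantified samples
discards double zeros, allows proportionality restricted to a sample subset,
and avoids low scattered counts. If no sample qualifies, the pair carries no
joint signal and every downstream measure is undefined.

**Quantification thresholds.** When $\alpha \ne 1$ one gene runs
systematically higher than the other, so each gene gets its own threshold:
$t_1 = \max(t, t/\alpha)$, $t_2 = \max(t, \alpha t)$.

**Zero taxonomy.** A zero of one gene in a sample is a *structural zero*
(confident absence) when the partner gene reaches its quantification
threshold there; otherwise it is *undetermined*. Under a Poisson model a
present gene with expected count $\lambda \ge t$ yields a zero with
probability at most $e^{-t}$, i.e. 0.2% at $t = 6$ — the price of calling
structural zeros.

**Non-robust measure $p_{nr}$.** A modified Lin concordance coefficient of
$g_2$ against $\alpha\,g_1$, over the samples $S'$ where both genes have
non-null counts:

$$p_{nr} = \frac{2\alpha\,\mathrm{cov}(g_1,g_2)}
{\alpha^2 \sigma^2_{g_1} + \sigma^2_{g_2}
 + (\alpha\,\bar g_1 - \bar g_2)^2}.$$

Unlike Pearson correlation, the location term penalizes any additive offset:
$p_{nr} = 1$ exactly when $g_2 = \alpha\,g_1$ on $S'$, i.e. direct
(origin-through) proportionality rather than mere linearity.

**Robust measure $p_r$.** Residuals $r_s = g_{2,s} - \alpha\,g_{1,s}$
(working scale; see below) are computed on samples above both quantification
thresholds, outliers are flagged by Tukey fences
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, and the concordance
formula is re-evaluated on the inliers with the same $\alpha$. Samples with
inconsistent counts — typically strain mixtures — are thereby excised. If
more than $0.3\,(|S'| - 5)$ samples are outliers the association is rejected
outright ($p_r$ undefined).

## The clustering pipeline

1. **Filter** — keep genes with counts strictly above 6 in at least 3
   samples.
2. **Split** — bin each gene by the sample of its largest depth-normalized
   count (ties to the first sample). Related genes tend to share the bin, so
   all-pairs comparison is only needed within bins.
3. **Apply** — within each bin, save pairs with $p_{nr} > 0.8$ and no
   structural zeros, sort by decreasing $p_{nr}$, and greedily grow seeds
   around the best remaining pair.
4. **Combine** — summarize each seed by a *representative* pseudo-gene
   (staged per-sample medians, see below), merge seeds whose representatives
   are proportional with no structural zeros, and drop seeds below
   `minSeedSize` (150 by default; lowered for desk-scale data).
5. **Core seeds** — in decreasing size order, each remaining seed becomes a
   species core and absorbs (discards) all remaining seeds related to it by
   $p_r > 0.8$; the assumption is that the largest of a group of related
   seeds is the species core and the rest are accessory/shared modules.
6. **Association & classification** — every retained gene (seeded or not)
   with $p_r > 0.8$ against a core representative joins that core's MSP
   (greatest $p_r$ wins when several cores match) and is classified from
   structural zeros only: `core` (none on either side), `accessory` (gene
   confidently absent in some species-positive samples), `shared_core`
   (detected where the species is absent), `shared_accessory` (both).
7. **Modules & quantification** — each non-core class is re-clustered with
   the same greedy procedure into modules of co-occurring genes (singletons
   allowed); MSP abundance per sample is the median depth-normalized count
   of the top 30 core genes.

### The representative

A seed representative is computed in three stages: per-sample median over
all seed genes; ranking of the genes by $p_{nr}$ against that vector; and a
per-sample median over the 30 best genes. The last median runs over the
genes with the highest counts and lowest dispersion, giving a stable
pseudo-gene. Representatives are kept on the raw count scale so they can be
compared exactly like genes.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `t` | 6 | detection threshold (raw counts) for ratio eligibility and the zero taxonomy |
| `pnrThreshold` | 0.8 | pair admission / seed merging cut-off |
| `prThreshold` | 0.8 | core selection and gene association cut-off |
| `maxOutlierFraction` | 0.3 | cap on the tolerated outlier proportion |
| `minSamples` | 3 | samples above `t` required by the rare-gene filter |
| `minSeedSize` | 150 | minimum merged seed size (genes) |
| `representativeTopN` | 30 | genes whose median forms the representative |
| `quantifyTopK` | 30 | core genes aggregated into MSP abundance |

`minSeedSize` is the parameter most worth adapting: 150 suits catalogs with
millions of genes; the desk-scale simulations in this package use 50 (or
lower in unit tests) since the simulated pan-genomes are smaller.

## Design choices where the design was open

Several details of the method admit more than one reading; the package fixes
them as follows and exposes the alternatives as configuration toggles.

* **Denominator of $p_{nr}$** (`pnrDenominator`). With a weight of
  $\alpha^1$ on $\sigma^2_{g_1}$, exactly proportional profiles would score
  $2\alpha/(1+\alpha) \ne 1$, violating the defining property of a
  concordance coefficient; the default therefore uses $\alpha^2$ (the
  standard Lin form under rescaling of one variable). The $\alpha^1$ variant
  remains available for fidelity experiments and the test suite verifies its
  $2c/(1+c)$ behavior.
* **Working scale** (`workingScale`). Thresholds ($t$, $t_1$, $t_2$) and
  $\alpha$ are always defined on raw counts, preserving the Poisson
  interpretation of the zero-misclassification bound; moments and residuals
  are computed on square-root counts by default, with $\alpha$ entering the
  formulas as $\sqrt{\alpha}$ (if $g_2 = \alpha g_1$ then
  $\sqrt{g_2} = \sqrt\alpha \sqrt{g_1}$). `workingScale = "raw"` disables
  the transform everywhere.
* **Outlier cap** (`outlierCapForm`). The cap is implemented as
  $|O| > 0.3\,(|S'|-5)$ (default), which approximates "more than 30%
  outliers" for large $|S'|$ and is stricter for small sample supports; the
  plain $0.3\,|S'|$ form is available.
* **Quartiles.** Tukey hinges (medians of the lower/upper halves, with the
  median shared by both halves for odd counts), matching the classical
  "Tukey's method"; `stats::fivenum` implements exactly this convention.
* **Minimum evidence.** $p_{nr}$ and $p_r$ require at least 3 samples with
  both genes present; the fences require at least 4 residuals (otherwise no
  outlier is called). Moments on fewer points are degenerate.
* **Medians.** Ties/even cardinalities use the midpoint of the two central
  values. Note that with this convention the reciprocity
  $\alpha(g_2,g_1) = 1/\alpha(g_1,g_2)$ is exact only when the eligible
  ratio set has odd cardinality (the arithmetic midpoint of reciprocals is
  not the reciprocal of the midpoint); the property tests use odd sets.
* **Merging order.** Seeds are merged in decreasing-size order (ties by
  seed id) and the absorbing representative is recomputed after each
  absorption round, so the non-redundancy of the surviving seeds is
  checkable at exit. A gene passing association against several cores goes
  to the core with the greatest $p_r$ (ties to the larger core), making MSPs
  a partition of the genes.
* **MSP quantification.** The aggregation statistic is the median of the
  top-30 core genes' depth-normalized counts, chosen for robustness and
  consistency with the representative construction.

## Numerical choices

* Tukey fences are widened by a relative tolerance of $10^{-9}$ times the
  largest residual magnitude: exactly proportional pairs produce residuals
  of order $10^{-15}$ from floating-point rounding, and with an IQR of zero
  these would otherwise be split arbitrarily into inliers and outliers.
* A zero-depth sample is retained with all normalized counts defined as 0
  (and a warning).
* The rare-gene filter is strict (`> t`), matching its description.
* Degenerate inputs (constant profiles, empty eligible sets, empty pair
  lists, zero-gene matrices) yield `NA` measures or empty results, never
  errors, except where a contract is violated (e.g. square-root transforming
  twice).

## The simulator and what it does (not) show

`simulateCounts()` draws a single virtual species: 1000 core and 6000
accessory genes by default (tests and the acceptance script use a 200 + 800
scaled pan-genome to keep runtimes in minutes; sample counts follow the
study design: 200, then 100 and 50). Gene lengths are uniform on
[100, 5000] bp, accessory prevalences uniform on [2.5%, 99.5%], per-sample
strain coverage uniform on [0.6, 20], and the observed count of a present
gene is Poisson with mean $\text{coverage} \times \text{length} / 100$ (the
expected read count at 100 bp reads; the formula is the package's choice, as
only its ingredients are prescribed). Absent genes count exactly zero.
`injectOutliers()` multiplies a fraction of each gene's present samples by
1/4, 1/3, 2, 3 or 4 (rounded back to integers); `simulateTwoStrains()` adds
a subdominant strain 5–10 times weaker with independently drawn accessory
content.

The simulator emulates the sampling noise, presence structure and outlier
processes the measures are designed for. It does **not** emulate:
cross-mapping between homologous genes of different species (shared genes
arise in real catalogs, not in a single-species simulation), non-uniform
coverage along genes, compositional coupling between species abundances,
correlated accessory content between co-occurring strains, or mapper
artefacts. Passing the simulation-based tests therefore demonstrates the
statistical machinery, not performance on real catalogs.

One consequence worth knowing: with a *single* simulated species the sample
depth is dominated by the species itself, so depth-normalized MSP abundance
is nearly flat across samples. Abundance tracks true strain coverage
(Pearson $r \ge 0.95$) once constant background genes emulate the rest of
the community, and the test suite checks it that way.

## Known limitations

* A core gene whose noisy bin assignment isolates it from all other
  seedable genes stays unseeded; it is recovered at the association stage,
  so seed completeness (not MSP completeness) depends on bin occupancy.
* Tukey fences lose power once a pair's corrupted samples approach the
  breakdown point of the hinges (about 25% one-sided); the outlier cap then
  rejects rather than repairs such associations.
* Two-strain mixtures inflate counts of genes carried by both strains; with
  frequent mixtures, low/medium-prevalence accessory genes are the first to
  fall below the association threshold.
* The greedy seed construction is order-deterministic but not globally
  optimal; a gene adjacent to two centroids joins the first (highest-pnr)
  seed examined.

## Problem sizes used by the tests

Unit tests run simulations of 20–160 genes and 10–40 samples; the
acceptance properties use the 200 + 800 gene pan-genome at 200/100/50
samples, all-pairs oracle checks up to 300 genes, and exhaustive
quartile-convention checks on all ~80 000 residual multisets of length at
most 7 over {−2, …, 10}. The full default-parameter pan-genome (7000 genes)
runs in well under an hour but is not exercised by the automated suite.
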