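---
title: "Transcriptome instability scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome instability scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinscope)
```

## The model chain

`tinscope` quantifies per-sample transcriptome instability (TIN) — a
genome-wide excess of aberrant exon skipping and inclusion — from
probe-level exon-array intensities, and tests whether it tracks the
expression of splicing-factor genes. The chain is:

1. **Quantile normalization** across samples (linear scale), so every
   array shares one value distribution. Backed by
   `limma::normalizeQuantiles` with tie averaging.
2. **Gene models.** Per transcript cluster, the log2 intensities form a
   samples-by-probes table fitted with the additive RMA model
   `value = overall + chip_i + probe_j + residual_ij` by Tukey median
   polish (rows = samples swept first). The chip effect plus overall term
   is the gene-level expression summary used downstream.
3. **FIRMA scores.** The splicing score of exon *k* in sample *i* is the
   median of its probeset's residuals. A strongly negative score means
   the exon is underexpressed relative to its gene in that sample
   (skipping); strongly positive means inclusion.
4. **Thresholds and TIN-estimates.** The pooled lower/upper 1st
   percentiles of all exon-by-sample scores in a dataset mark aberrant
   skipping/inclusion. Per-sample counts beyond the thresholds,
   log2-scaled relative to the dataset mean, give the TIN-estimate
   `T_i = log2(n_i / mean(n))`; `|T| >= 1` designates TIN-samples
   (at least double, or at most half, the average aberrance).
5. **Association and nulls.** Per-gene Pearson correlation of expression
   with `T`, two-sided Student p from `t = r sqrt((n-2)/(1-r^2))`. Set
   level summaries (percent significant at 0.05, negative:positive sign
   ratio, mean |r|) are compared with two empirical nulls: permutations of
   the TIN vector, and random gene sets of matched size drawn from the
   whole gene universe. Empirical p uses the add-one estimator
   `(b+1)/(B+1)`, which cannot return zero and at the default `B = 1000`
   has floor `1/1001`, consistent with reporting bounds as `P < 0.001`.
6. **Multivariate structure.** Covariance PCA (samples as observations,
   unscaled) and complete-linkage hierarchical clustering on Euclidean
   distances over the splicing-factor genes; a ranking score in [0.5, 1]
   quantifies how PC1/PC2 separate high- from low-TIN samples.

No multiple-testing correction is applied to the per-gene p-values
anywhere: the set-level inference rests entirely on the resampling nulls,
which compare like with like.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `lower_percentile` / `upper_percentile` | 1 / 99 | % of pooled scores | the aberrance definition; pooled over all exon-by-sample cells |
| `tin_cutoff` | 1.0 | log2 | `T = 1` is exactly twice the dataset-average aberrance |
| `alpha` | 0.05 | — | per-gene significance inside the set statistics |
| `B` | 1000 | resamples | p floor 1/1001 |
| `polish.max_iter` / `polish.tol` | 10 / 1e-4 | sweeps / log2 | common RMA practice; polish converges linearly, so residual row/col medians end below `tol` only when sweeps run to convergence |
| `tin.mode` | `"total"` | — | see below |
| pseudocount | 0.5 | counts | zero counts only arise in tiny synthetic data |

## Numerical and convention choices

* **Quantile convention** is linear interpolation between order statistics
  (R type 7) for the percentile thresholds; exceedance is strict, so cells
  exactly at a threshold are not counted and the flagged fraction never
  exceeds the nominal percentile under ties.
* **TIN-estimate definition.** `T` is the log2 of the *total*
  (skip + inclusion) count over the mean of totals, not the sum of the two
  component log-ratios: the estimate is described as the total amount of
  aberrant splicing relative to the dataset average, and only this reading
  makes "twice the average ⇒ +1.0" exact. The alternative reading is
  available as `mode = "sum_components"`.
* **"Average" is the arithmetic mean** of counts on the linear scale, so a
  sample at exactly twice the mean gets exactly +1.0.
* **Zero counts** are replaced by 0.5 before ratios, and the mean is taken
  over the adjusted counts, which preserves `mean(2^T) = 1` exactly.
* **Median polish** sweeps rows (samples) first; the median of an even
  number of values is the mean of the central pair. `stats::medpolish`
  stops on a sum-of-|residuals| criterion that can halt before the sweep
  fixed point on even-sized tables; this implementation stops when the
  largest absolute sweep median is below `tol`, and the test suite checks
  both the reconstruction identity and exact agreement with
  `stats::medpolish` on odd-sized tables where the fixed point is unique.
* **FIRMA scores below 1e-12 in magnitude are zeroed**: they are float
  dust from the polish sweeps, orders of magnitude below any meaningful
  log2 residual, and would otherwise straddle the percentile thresholds on
  noise-free input.
* **PCA component signs** are fixed by making each component's
  largest-magnitude loading positive; only group separation, not axis
  orientation, is meaningful.
* **Degenerate inputs**: zero-variance genes are flagged and excluded from
  set summaries rather than silently dropped; a dataset whose samples all
  have zero aberrant counts is refused; an empty high- or low-TIN group
  makes the separation score unavailable (reported as missing) rather than
  aborting the whole report.

## The synthetic-data generator

The generator emulates the post-CEL structure of an exon array: genes
(transcript clusters) of `exons_per_gene` probesets with `probes_per_exon`
probes, log2-additive gene and probe effects, Gaussian probe noise, and
linear-scale output `2^log2value`. A latent per-sample splicing capacity
`z ~ N(0,1)` couples the two sides of the phenomenon:

* splicing-factor genes load on `z` with `sf_loading_lambda` on top of the
  `N(0, 0.5)` idiosyncratic gene-level variation every gene carries — so
  their correlations with TIN land in a realistic, noisy range rather than
  being deterministic copies of `z`;
* the planted aberrant event count per sample is
  `N_i = round(n0 * 2^(-beta * z_i))` (optionally Poisson), and each event
  shifts all probes of one uniformly chosen exon by ±delta, all-probes so
  the probeset-median FIRMA summary can see it.

Counts are deterministic in `z` by default to make parameter recovery
sharp at small sample sizes; group effects and pairing enter as additive
log2 modifiers of the count exponent and as metadata for the subgroup and
paired-sample comparisons.

Default study conditions are 60 samples, 300 genes (40 splicing factors),
`beta = 1`, `delta = 3` log2 units, `noise_sd = 0.25`, `n0 = 40` events.
`delta` has no measured real-world counterpart; it is an order-of-magnitude
choice informed by the threshold range reported for real exon-array data
(roughly ±2 log2 units). Under these conditions the pipeline's TIN-range
comes out near 3.6, close to the average range of about 3.4 reported
across real datasets.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe GC-content and sequence biases (a constant
offset stands in for background correction; real GC correction needs probe
sequences), cross-hybridization, spatial array artifacts, correlated gene
programs beyond the single latent factor, and splicing modes other than
whole-exon shifts. One interaction the generator *did* expose: samples
with a very heavy planted event load develop heavier intensity tails, and
quantile normalization then slightly stretches their bulk values — a
sample-level variance signature that PCA can pick up from any gene set.
The study conditions keep the planted fraction near 2% of exon-by-sample
cells, where this effect is negligible for the correlation statistics;
analyses of data with much heavier aberrance should be aware of it.

## Pooled (pan-cancer) mode

`run_pan_cancer` draws `n_per_dataset` samples per dataset (per-bundle
seeds derived from one root seed), pools the intensity matrices, and
recomputes *everything* — normalization, gene models, FIRMA scores,
thresholds, TIN — across the pool, rather than concatenating per-dataset
results; the tests assert the two genuinely differ whenever dataset
baselines differ. One caveat the analysis scripts demonstrate: if datasets
differ in *both* their baseline aberrance and their gene-expression
baselines, dataset identity becomes an ecological confounder, and the
sample-level permutation null (which ignores the clustering) can declare
the pooled association significant without any within-dataset coupling.

## Test design notes

Test problem sizes are the package's own choice of desk-scale study
conditions: replicate-based calibration checks run on 20-sample,
40-gene null datasets (200 replicates for the uniformity of the empirical
p; the Kolmogorov–Smirnov check uses the continuous `mean_abs_r`
statistic, since the tie rule makes the empirical p of the discrete
percent-significant statistic conservative, for which a one-sided validity
bound is asserted instead). The analytic-vs-permutation p comparison uses
n ≤ 12 with 10,000 permutations; agreement is to within 0.05, the
distributional gap expected at such n. The TIN-group separation score is
an AUC along a data-driven direction and is optimistically biased for tiny
groups (about 0.7 at six-per-group under the null); the contrast property
(coupled splicing factors separate, uncoupled random genes do not) is
therefore tested at a cutoff of 0.4 on 30-sample fixtures, where both
groups are large enough for the bias to stay below the asserted bounds.

## Known limitations

* CEL parsing, GC background correction, and array QC metrics are out of
  scope; the pipeline starts from probe-by-sample intensity matrices.
* The FIRMA convention here (log2 residual medians, no rescaling) is
  order-equivalent to, but not numerically identical with, ratio-scale
  FIRMA outputs that are log2-transformed afterwards; percentile-based
  thresholds make the difference immaterial downstream.
* The permutation null assumes exchangeable samples; it is not valid for
  clustered pooled designs (see above).
* Single-probe probesets are retained; their scores are just that probe's
  residual.
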