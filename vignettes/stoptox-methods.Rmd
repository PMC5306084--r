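---
title: "Scoring chemically disturbed stem-cell differentiation with stoptox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chemically disturbed stem-cell differentiation with stoptox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoptox)
```

## The problem and the model

Stem-cell-based developmental toxicity assays are dynamic systems: over the
differentiation period (six days for a neuroectoderm protocol, fourteen for a
three-germ-layer protocol) several hundred to a few thousand probe sets
change expression spontaneously. We call these the **developmental genes**
(D): probe sets significantly deregulated between the undifferentiated
(day 0) control and the differentiated end-stage control. A compound applied
during differentiation deregulates its own set of probe sets relative to the
end-stage control — the **toxicant genes** (T). The question a developmental
toxicity test must answer is not *how many* genes a compound moves, but
*whether it preferentially moves the genes that drive development*.

With `N` probe sets measured on the array (54,675 on the platform the
defaults emulate) and `O` the number of probe sets in both D and T, the two
headline scores are:

* **Developmental potency** `Dp = O / D` — the fraction of all developmental
  genes altered by the compound at the tested concentration.
* **Developmental index** `Di = (O / T) / (D / N)` — the ratio by which
  developmental genes are overrepresented among the compound-deregulated
  genes. `Di = 1` is the random expectation; the normalization by `D/N`
  makes systems with different numbers of developmental genes directly
  comparable.

Overlap significance is the one-sided Fisher exact test, i.e. the upper
hypergeometric tail `P(X >= O)` for `X ~ Hypergeom(N, D, T)`: the chance of
an overlap at least this large if the compound hit T probe sets at random.

Two readings of `Dp` circulate in descriptions of this family of scores:
`O/D` (fraction of developmental genes hit) and `O/T` (fraction of hit genes
that are developmental). This package computes `Dp = O/D` — the quantity
that grows monotonically with concentration and saturates at 1 when
development is fully compromised — and reports `O/T` alongside as
`o_over_t`, since it is the other factor of `Di`.

Direction is ignored for `O` itself (a gene is "deregulated" either way),
but the four directional quadrants are always reported, because their
asymmetry carries the central biological observation: compounds mostly
*antagonize* development — suppressing developmentally up-regulated genes
and inducing developmentally down-regulated ones. The
`antagonistic_fraction` is the share of `O` in the two discordant quadrants.

## From raw matrices to regulons

The package consumes already-summarized log2 expression matrices. Quantile
normalization (`quantile_normalize`) forces every sample onto the mean
order-statistic distribution; ties receive the average of the averaged order
statistics over the tied ranks. Batch effects are removed by
`combat_correct`, the empirical-Bayes location/scale model: per-probe
standardization with respect to mean expression and treatment effect, EB
shrinkage of per-batch additive and multiplicative effects (nonparametric
prior by default; parametric normal/inverse-gamma as the faster option),
removal, and back-transformation. Biological groups are taken from the
design table so treatment effects are preserved. Degenerate structures —
a single batch, batches of one sample, batch labels confounded with the
biology — are either a no-op or a hard error; probes with zero residual
variance pass through uncorrected with a warning.

One property worth stating precisely: EB batch correction is only
*approximately* idempotent. A second pass re-estimates small, shrunken
batch effects from the finite-sample noise of the corrected data; in our
property test the second pass moves values by under 10% (RMS) of the first
pass. Exact idempotence is not achievable by this class of estimator.

Differential expression (`differential_expression`) is the classical
pooled-variance two-group comparison (a one-way ANOVA with two levels, so
F = t²; Welch's statistic is available as an option), two-sided p-values,
Benjamini–Hochberg adjustment across *all* probes of the matrix, and a
significance flag that is the conjunction of two gates: linear absolute
fold change >= 1.5 and FDR-adjusted p <= 0.05. Both thresholds are
parameters; 1.5 and 0.05 are the conventional defaults for this assay
family. Fold changes are computed as `2^(difference of log2 means)` and
reported signed (+2 and −2 are both "twofold"). A probe with zero variance
in both groups and equal means is assigned p = 1 and logged.

`call_regulons` splits the significant probes of a contrast into up/down
sets; applied to the day-0 vs end-stage contrast it yields the D-genes, and
to the end-stage vs treated contrast the T-genes of one
compound/concentration. `fold_change_tiers` counts regulated probes above
the 2/5/10-fold tiers, and `top_k_by_fdr` implements the
"50 most regulated" selection (all, if fewer than k are significant; ties
on q broken by raw p, then probe id, so the selection is deterministic).

## Consensus and diagnostic genes

Probe-level calls are lifted to genes by `collapse_to_genes`: a gene is
deregulated if at least one annotated probe set is; genes with significant
probes in both directions are *inconsistent* and count toward neither
direction downstream. `consensus_genes` counts, per gene and direction, how
many compounds of a class agree; the published per-system presets for the
minimum count are 3–5 depending on system and compound class.
`rank_diagnostic_genes` filters consensus genes by developmental membership,
antagonism to the developmental direction, and baseline expression, and
ranks by compound support then fold change. The sixth published criterion —
"function basically understood" — is not computable from data; it is
implemented as an optional curated allow-list and skipped (with a log note)
when none is supplied.

The baseline gate uses a strict `> 6` log2 cutoff at day 0 *or* at the end
stage. The value sits in the valley of the bimodal distribution of baseline
intensities on this array family, separating expressed probes from the
optical noise range; it is a parameter (`threshold_log2`) for other
platforms.

## The TF co-expression network

The network layer asks where, in the regulatory landscape, a compound acts.
Mutual information between all gene pairs is estimated with the
Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator (`knn_mi`,
max-norm, k = 9 by default), which is distribution-free and invariant to
monotone rescaling up to estimator noise. Exact ties are broken by a tiny
seeded jitter (1e-10 of each gene's scale); negative estimates are floored
at zero, and constant genes get MI 0. The MI matrix is sharpened by the
context-likelihood-of-relatedness transform (`clr_scores`): each gene's MI
row is z-scored (negatives clipped), and an edge scores
`sqrt(z_i(j)^2 + z_j(i)^2)`, so only pairs that stand out against *both*
genes' backgrounds score highly.

`build_network` restricts the score matrix to transcription factors and
keeps the top `edge_quantile` fraction of TF pairs (default 0.001 — the
top 0.1%). The quantile is computed *after* TF restriction; with distinct
scores exactly `ceiling(edge_quantile * n_pairs)` edges are kept, and pairs
tied with the threshold are all kept (a logged superset). Communities come
from greedy modularity maximization; the 18 largest are retained for
Fisher-test GO enrichment (unadjusted p < 0.05, background = network
nodes), with communities under six genes flagged. `overlay_regulation`
marks each TF up/down under a condition, removes inconsistently regulated
TFs, and reports the fraction of affected TFs per community.

On the bundled 30-TF test fixture (three planted modules, 200 samples) the
0.001 production quantile would keep a single edge out of 435 pairs, so the
module-recovery tests and examples use `edge_quantile = 0.1`; the
production default is unchanged.

## Benchmark concentration (BMC10)

The transcriptome test concentration is anchored at low cytotoxicity: the
highest concentration at which at least 90% of cells survive. Raw resazurin
fluorescence is blank-subtracted and scaled to the vehicle controls
(`normalize_viability`), technical replicates are averaged, and each
biological replicate is fitted with a four-parameter logistic on log10
concentration (`fit_dose_response`; top initialized at 100 and bounded in
[80, 120], bottom in [0, 50], multi-start Levenberg–Marquardt because a
single start can hit a singular initial Jacobian). The fitted curves are
averaged pointwise on a shared log10 grid — closer to "determined
graphically" than averaging parameters — and `bmc10` reads off the lowest
concentration where the average crosses 90%.

The read-off snaps to measured concentrations: a measured point whose
averaged viability is within 0.25 percentage points of 90% is taken as the
90% data point itself; otherwise the last measured point left of the
interpolated crossing is returned (the interpolated value is reported
alongside for transparency). The tolerance matters because a 4PL through
very few points is not unique — two bound-feasible curves can interpolate
the same four points with different crossings — so viability-space
proximity, not concentration-space coincidence, decides whether a measured
point *is* the crossing. If the averaged curve never drops below 90%, the
result is "above tested range".

## The synthetic-data generators

Every stage is testable without downloads because the package ships seeded
generators with planted truth:

* `generate_dataset` emulates a full array study: per-probe baselines
  `N(7, 2²)` log2, four biological replicates per group, planted
  developmental and toxicant effects with |log2FC| uniform on [1.5, 3.3]
  (2.8- to 10-fold, populating both ends of the fold-change tiers),
  replicate noise of 0.3 log2 units, configurable D/T/overlap counts, an
  80% antagonistic overlap by default, optional additive and multiplicative
  batch effects (assigned balanced within groups so they stay identifiable),
  and a probe-to-gene annotation with a configurable multi-mapping rate.
  The default 20,000 probes keep tests fast; `n_probes = 54675` gives a
  full-size array.
* `generate_coexpression` plants TF modules by a latent-factor model
  (within-module correlation 0.8 by default, ~0 across).
* `generate_viability` produces plate tables (five technical wells, three
  biological plates) from a known 4PL curve, including vehicle and blank
  wells.

What the generators do *not* emulate: probe-level hybridization noise,
intensity-dependent variance, correlated gene programs outside the planted
sets, or dose–response shapes other than the 4PL. Passing the recovery
tests therefore demonstrates that the statistical machinery is correct and
calibrated, not that any particular laboratory dataset will meet the same
tolerances.

One calibration fact the tests make explicit: with 100 planted toxicant
probes among 20,000 and four replicates per group, the BH gate is severe
(the effective per-probe p threshold is about 2e-4), so roughly a quarter
of planted T probes near the 1.5 log2FC floor are missed. Because overlap
and non-overlap T probes are missed at the same rate, `Di` is recovered
within 10% of its planted value while `Dp` dips proportionally — a useful
reminder that `Dp` is a *detected-fraction*, bounded by study power.

## Problem sizes and numerical choices in the test suite

The shipped tests run the full recovery study at 20,000 probes
(D = 1000, T = 100, O = 50), the null calibration at 1,000 random draws,
the MI closed-form check at n = 1,000, module recovery at 30 TFs x 200
samples, and the BMC noise study at 100 seeded repeats — sizes at which
every check completes in seconds while the sampling error of each statistic
is well inside its tolerance. Batch-correction bands are checked at 20
probes x 10 samples (additive) and 200 probes x 20 samples with five
replicates per batch-group cell (scale and treatment): below five
replicates per cell the EB scale estimate is visibly small-sample biased
(residual SD ratio ~1.17 regardless of prior), which is a property of the
estimator, not of the implementation.

## Limitations

* Indices are computed at the probe-set level by default; the gene-level
  mode depends on the quality of the supplied annotation.
* `Di` is undefined (NA) for compounds that deregulate nothing — these are
  negative tests, not zeros.
* The category-restricted indices keep the whole-array background `N`;
  restricting the background to the category would ask a different
  (conditional) question.
* The network layer validates scores, edges, communities and overlays, but
  published edge/node counts for any particular network additionally depend
  on external TF databases and annotation versions.
* No multiple-testing correction is applied across GO categories or
  communities (raw p-values are reported, as is conventional for these
  descriptive overlays); a BH column is easy to add downstream.
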