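---
title: "Pan-cancer prognosis analysis of non-coding RNA markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-cancer prognosis analysis of non-coding RNA markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panprog)
```

## The analysis in one paragraph

`panprog` asks, per cancer cohort, which miRNAs and lncRNAs separate
patients with long overall survival (OS) from patients with short OS, how
those markers distribute across cancers, which canonical signaling
pathways their target genes fall into, and — through a counterfactual
simulation — which miRNA markers could in principle move a poor-prognosis
sample toward the good-prognosis class. Samples are labelled *high-OS*
when their OS strictly exceeds the cohort median, *low-OS* otherwise.
Markers are detected by Welch's t test between the two groups (miRNA:
p < 0.05; lncRNA: p < 0.01 together with a linear-scale fold change ≥ 2
or ≤ 0.5). A Gaussian naive Bayes (NB) classifier — the PCPA model — is
trained on a class-stratified, maximally dispersed two-thirds training
split and evaluated by ROC/AUC on the remainder, and by Kaplan–Meier
curves with the log-rank test on its predicted groups.

## Median-OS labelling

The prognosis label is a median split of observed OS days: high-OS iff
`os_days > median`. Ties at the median fall to low-OS (the strict reading
of "over the median"), so the high-OS class can never exceed `floor(n/2)`
samples. For even n the median is the midpoint of the central order pair.
Cohorts where all OS values coincide degenerate to an all-low-OS labelling
with a warning.

## Differential expression filters

Expression is stored as `log2(x + 1)`. The t test is Welch's
unequal-variance form — the omics here have no reason to share variances
between prognosis groups, and Welch is the safer default where only
"two-tailed t tests" is specified. The fold change is computed on the
*linear* scale (values back-transformed by `2^x − 1`, group means
ratioed with an `1e-8` guard), and the gate is two-sided: `FC ≥ 2` *or*
`FC ≤ 0.5`, so down-regulated lncRNAs are captured symmetrically.
P-values are deliberately unadjusted — the thresholds are reproduced as
stated raw — with Benjamini–Hochberg gating available behind
`adjust = TRUE`.

For small cohorts the combined marker matrix can support overfitting; when
the expected training-set size falls below 50 samples
(`fa_threshold`), `factor_reduce()` compresses the feature space: the
number of factors is picked by the Kaiser criterion (correlation-matrix
eigenvalues above 1, capped at n − 1), a maximum-likelihood factor model
is fitted, and the union of the 10 largest-|loading| features per factor
is retained. If the ML fit does not converge the loadings fall back to
principal components (with a message); the selection rule is identical in
both routes.

## The spatial subset split

Training sets are chosen to span the expression space rather than sampled
uniformly: within each class, a random seed sample starts a greedy
farthest-point traversal — each next sample maximizes the mean distance to
everything already selected — and the first `round(2n/3)` samples (round
half up) become training data. Distances are Euclidean after per-feature
z-scoring, so no feature dominates by scale; zero-variance features drop
out (zero weight). Ties in the greedy scan break to the smallest sample
index, so the only randomness is the per-class seed draw, making the split
bit-reproducible from `rng_seed`. Stratification is per class, which
keeps the 2:1 ratio exact in both classes. Tests verify the greedy order
against an exhaustive re-implementation on all instances up to n = 8 and
the dispersion property (farthest-point training sets have larger mean
pairwise distance than random subsets of the same size, on average).

## The PCPA classifier

The default family is Gaussian naive Bayes: class priors are training
frequencies, each feature contributes an independent Gaussian
class-conditional. Posteriors are computed as log-sums of per-feature
log-densities, normalized in log space, so models with thousands of
features do not underflow. Variances are floored at
`1e-9 × max(pooled feature variance)` to keep constant features from
producing singular likelihoods; such features then carry likelihood ratio
1 and cannot influence the posterior. The classification threshold on the
high-OS posterior is 0.5. LR/SVM/NN adapters (`fit_alternative()`) expose
the same prediction contract for comparison but are not part of the
package's evaluated surface.

AUC is the pairwise concordance probability with half credit for ties
(rank/Wilcoxon form), matched in tests against an exhaustive pair count.
The survival read-out on predicted groups reports the per-group median of
*observed* OS days (the KM median is also provided), the product-limit
curves, and the two-group log-rank test with hypergeometric moments. All
three statistics are authored in-package and cross-checked against
`survival::survfit` / `survival::survdiff` to 1e-8 in the test suite.

## Marker landscape, pathway refinement, regulation

Marker sets from all cancers assemble into a binary marker × cancer
incidence matrix. A marker is *shared* when it appears in ≥ 2 cancer
types, *cancer-specific* at exactly 1; per-omic fractions summarize the
sharing asymmetry. Ranking is by cancer count with lexicographic
tie-break. A 19-type → 9-category taxonomy (urologic, gynecologic, core
GI, developmental GI, thoracic, CNS, head and neck, endocrine,
melanocytic) ships as a fixture.

Eight canonical cancer signaling pathway gene sets (PI3K, MAPK, cell
cycle, Wnt, P53, Hippo, TGFβ, Notch) are *refined* to gene-specific sets
by removing every gene present in two or more of the eight, leaving
pairwise disjoint sets. The regulation fraction of a cancer's miRNA
markers for a refined pathway is the fraction of markers with at least
one annotated target gene in the set; markers missing from the target map
stay in the denominator. Per-gene profiles keep genes regulated by
strictly more than 7% (default) of the cancer's markers; the denominator
is the per-cancer marker count, with the pan-cancer denominator available
by passing the pooled marker set. The bundled GMT
(`canonical_pathways_synthetic.gmt`) carries an illustrative synthetic
membership under the real pathway names: it exists so the code paths are
exercised end-to-end, not as a reproduction of any curated database.

## The marker-oriented simulation (MOS)

Approved anti-cancer drugs are mostly inhibitors, and miRNAs are mostly
negative regulators, so a miRNA highly expressed in good-prognosis
patients may mimic drug action. MOS makes that counterfactual concrete:
for each miRNA marker *independently*, every low-OS (test-set) sample
whose expression of that marker is below the marker's high-OS reference
level — the mean over high-OS training samples — is raised *to* the
reference, everything else untouched, and the NB model re-scores the
perturbed samples. Markers whose mean posterior shift exceeds
`epsilon = 1e-6` (over ≥ 1 perturbed sample) are flagged
*prognosis-alternative*. For an NB marker with a higher high-OS mean and
equal class variances the likelihood ratio is monotone in the expression
value, so the shift is provably positive whenever any sample is perturbed;
the suite checks this numerically. The reference is the mean rather than
some higher quantile because it is the natural point estimate of "levels
as in the high-OS group"; a median option is exposed.

Per cancer category, candidate drug-target genes are the *intersection*
across member cancers of the genes targeted by each cancer's
prognosis-alternative markers, restricted to the (unrefined) union of the
eight pathways; a union mode is available. Genes are finally annotated
against a small bundled gene → drug table containing only well-established
pairs.

## The synthetic generator

The generator produces the statistical structure the analysis assumes,
not biological realism (no real nomenclature, isoforms or copy-number
structure). Per cohort, feature baselines are `Normal(3, 1.5)` log2
units and expression is `Normal(mu_f, 2.5)`. Survival times follow a
proportional-hazards exponential model (Weibull shape exposed, default 1):
log-hazard is `log(1/1000)` per day plus `±1.0 × z` summed over planted
markers, the sign negative for protective markers (directions alternate
deterministically along the planted list). Four miRNA markers are planted
with identical identity in *every* cancer; two lncRNA markers per cancer
are planted disjointly — the idealized form of the observed sharing
asymmetry (miRNA markers mostly shared, lncRNA markers almost always
cancer-specific). Censoring defaults to 0 because the upstream clinical
contract carries OS days with an implicit event; an independent
exponential censoring channel is available. All randomness derives from
one root seed via fixed per-cohort streams, so adding a cancer never
perturbs existing ones and equal configs give bit-identical datasets.

Default sizes (3 cancers × 400 samples, 150 + 150 features) were chosen
once, ahead of testing, so that each planted marker carries a population
correlation of ≈ 0.35 with log survival time — strong enough that the
stated recovery targets (≥ 90% marker recovery, held-out AUC > 0.75,
≥ 80% MOS sensitivity at ≤ 10% false flags) are properties of the method
rather than of luck, yet weak enough that the null feature behaviour
(≈ 5% miRNA pass rate) stays visible. What passing these tests shows is
parameter recovery under the generator's assumptions; it does not certify
performance on real cohorts, where effects are smaller, expression is
heavy-tailed and dependent across features, and censoring is informative.

## Numerical choices and degenerate inputs

* Missing-value filter: features first, then samples; idempotent.
* Isoform aggregation sums on the linear scale before `log2(x + 1)`;
  duplicate-ID collapsing averages on the log scale (matching the order
  the upstream resources apply them).
* Normal-tissue removal keeps TCGA sample-type codes 01–09 and drops
  10–19; inputs without a code column skip the filter.
* `welch_t` on two zero-variance groups: p = 1 when means agree, else the
  p = 0 limit with a warning.
* Log-rank with no events: chi² = 0, p = 1. One-sided (empty) predicted
  groups: degenerate comparison with p = 1 and a warning.
* All tie-breaks (greedy scan, marker ranking) are deterministic and
  documented at the function level.

## Problem sizes used by the checks

The acceptance script and the recovery tests run 10 generator seeds at
the default 3 × 400-sample design (~460 t tests and one NB fit + MOS scan
per cohort), which completes in seconds; oracle-equivalence suites use 50
random small instances per statistic. These sizes are the package's own
validation design, balancing Monte-Carlo stability of the reported rates
against a test suite that stays fast enough to run on every change.

## Known limitations

* Only two-group (high/low OS) comparisons; no Cox regression, no
  multi-group log-rank.
* The NB feature independence assumption is knowingly wrong for co-
  regulated ncRNAs; it is the chosen model family, not a claim.
* Factor reduction applies to the combined matrix; per-omic reduction is
  not implemented.
* The drug-target and pathway fixtures are illustrative; real analyses
  should supply curated GMT/TSV inputs through the same readers.
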