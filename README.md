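# panprog

Pan-cancer prognosis analysis of non-coding RNA markers.

`panprog` is for computational biologists who want to relate miRNA and
lncRNA expression to overall survival (OS) across many cancer cohorts at
once. Per cohort it splits patients at the median OS into high-OS and
low-OS groups, detects prognosis-related differentially expressed ncRNAs
(Welch's t test, with a fold-change gate for lncRNAs), trains a Gaussian
naive Bayes classifier — the PCPA model — on a class-stratified
farthest-point ("spatial subset") training split, and evaluates it with
ROC/AUC, Kaplan–Meier curves and the log-rank test. Across cohorts it
quantifies marker sharing (miRNA markers tend to recur across cancers,
lncRNA markers tend to be cancer-specific), profiles how markers regulate
eight refined canonical signaling pathways through a miRNA→target map,
and runs the marker-oriented simulation (MOS): an in-silico screen that
raises each marker in low-OS samples to its high-OS reference level and
flags markers that increase the predicted high-OS probability —
candidates, via their target genes, for therapeutic intervention.

## The core quantities

* Label: `high-OS` iff `os_days > median(os_days)` within the cohort.
* DE filters: miRNA `P < 0.05`; lncRNA `P < 0.01` and `FC ≥ 2` or
  `FC ≤ 0.5` (linear scale, two-sided).
* Split: per class, greedy farthest-point order from a random seed
  sample; first `round(2n/3)` samples train the model.
* NB posterior: `P(high-OS | x) ∝ π_hi Π_f N(x_f; μ_f,hi, σ²_f,hi)`,
  computed in log space.
* AUC: pairwise concordance with ½ credit for ties.
* Log-rank: `χ² = (O − E)² / V` with hypergeometric moments per event
  time.
* MOS: per marker m, set `x_m ← max(x_m, ref_m)` in low-OS samples
  (`ref_m` = mean of m in high-OS training samples), re-score; flag m if
  the mean posterior shift exceeds ε = 1e-6.

## Worked example

Everything below runs on the bundled synthetic generator — no downloads.

```r
library(panprog)

cfg    <- sim_config(seed = 2026)        # 3 cancers x 400 samples
bundle <- simulate_pan_cancer(cfg)
res    <- run_pan_cancer_pipeline(bundle, split_seed = 2026)

pc <- res$per_cancer$C01
round(pc$eval$auc, 3)
#> [1] 0.973
signif(pc$survival$logrank_p, 3)
#> [1] 3.73e-30
round(pc$survival$median_os)
#> high-OS  low-OS
#>    3755     101
res$sharing
#>     omic n_total n_shared shared_fraction n_specific specific_fraction
#> 1 lncRNA       6        0             0.0          6               1.0
#> 2  miRNA      30        6             0.2         24               0.8
```

Cohort C01 yields 11 miRNA and 2 lncRNA markers; the held-out AUC of
0.973 and the log-rank p of 4e-30 say the predicted groups separate
survival sharply (predicted high-OS median 3755 days vs 101). The sharing
table shows the planted asymmetry recovered from data alone: 6 of 30
detected miRNA markers recur in ≥ 2 cancers, while every detected lncRNA
marker is cancer-specific.

```r
pc$mos$alternative_markers
#> [1] "mir_011" "mir_052" "mir_057" "mir_119" "mir_135" "mir_149"
bundle$truth$planted_markers$C01$mirna
#> [1] "mir_057" "mir_096" "mir_135" "mir_140"
```

MOS flags both planted *protective* markers (`mir_057`, `mir_135`;
`mir_096`/`mir_140` are planted hazardous, so raising them must not help)
plus a few borderline false DE hits. `res$regulation` holds the
cancer × pathway regulation fractions over the refined pathway sets, and
`category_common_genes()` intersects the flagged markers' target genes
within cancer categories, annotated against the bundled drug-target
table via `annotate_known_targets()`.

Real data enter through the same surfaces: `read_expression_tsv()`
(Xena-style TSV, either orientation, linear or log2), `filter_missing()`,
`aggregate_isoforms()`, `collapse_duplicate_ids()`,
`align_with_clinical()` (drops normal-tissue TCGA codes),
`read_gmt()` for pathways and a two-column TSV for the target map.

See `vignettes/pan-cancer-prognosis.Rmd` for the full methods account.

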