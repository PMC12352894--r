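# cytostrat

Blood mass-cytometry (CyTOF) immunophenotyping and patient stratification
in lupus nephritis (LN).

Fewer than half of LN patients reach complete renal response on standard
immunosuppression, and kidney histology alone predicts outcome poorly.
Blood immunophenotyping offers a noninvasive window on the immune axes
that drive renal injury. `cytostrat` implements, as a tested and reusable
R pipeline, the analysis that stratifies LN patients into three
immunologic groups from blood CyTOF profiles — control-like (**G0**),
IFN-high (**G1**), and cytotoxic-enriched (**G2**) — and links the groups
to renal histology and one-year treatment response. It is aimed at
computational immunologists who want to run, audit, or extend this kind
of stratification on their own cytometry cohorts.

The core quantities:

* **Cytometric IFN-I score.** For sample *i* with marker summaries
  *x<sub>im</sub>* (medians of MX1 and ISG-15 over the T- and B-panel
  cells and of Siglec-1 over myeloid cells),

  *S<sub>i</sub>* = Σ<sub>m</sub> (*x<sub>im</sub>* − μ<sub>m</sub>) / σ<sub>m</sub>,

  where μ<sub>m</sub>, σ<sub>m</sub> are control means and SDs; a sample
  is *IFN-elevated* when *S<sub>i</sub>* exceeds the control mean + 3 SD.
* **Covarying-neighborhood differential abundance.** A random-walk-smoothed
  samples × cells neighborhood-abundance matrix on the cell kNN graph,
  tested against sample phenotypes with covariate adjustment, a
  permutation global test, and a permutation-calibrated per-cell FDR mask.
* **Stratification.** K-means (K = 3, k-means++ with restarts) on
  z-scored subset proportions plus the IFN score; clusters are anchored to
  G0/G1/G2 by control fraction, mean IFN score, and a granzyme-B
  tie-break.
* **Clinical stages.** Kruskal–Wallis + Dunn, Spearman screens with BH
  control, multivariable linear/logistic models, repeated cross-validated
  elastic net, longitudinal mixed models, and the rule-based week-52
  renal-response classifier (complete / partial / none, baseline
  UPCR ≥ 1 required).

The real cohort is controlled-access; a synthetic-cohort generator with
full ground truth (four 48-marker panels, planted subsets, patient
groups, batch effects, and coupled clinical outcomes) drives all
examples and tests.

## Worked example

```r
library(cytostrat)

cfg <- run_config(seed = 42, design = cohort_design(
  n_controls = 12, n_per_group = c(8, 14, 14), cells_per_sample = 2000,
  seed = 42), restarts = 25)
run <- run_pipeline(cfg)
print(run)
#> cytostrat pipeline run
#>   samples: 48 kept of 48 (QC)
#>   subsets: 30 across 4 panels
#>   IFN-I elevation threshold: 6.754; 67% of LN samples elevated
#> anchored
#> G0 G1 G2
#> 19 14 15
summary(run)
#> Anchored vs planted groups:
#>         planted
#> anchored G0 G1 G2
#>       G0 18  0  1
#>       G1  0 14  0
#>       G2  2  0 13
#> ARI = 0.813
#> Kruskal-Wallis activity p = 0.000194, chronicity p = 0.0566
```

Reading the output: QC kept all 48 samples; two-level clustering found 30
subsets across the four panels; the IFN-I elevation threshold (control
mean + 3 SD of control scores) is 6.75 score units and 67% of LN samples
exceed it. K-means + anchoring recovered the planted G0/G1/G2 membership
with an adjusted Rand index of 0.81 on this deliberately small cohort
(the default 160-sample design recovers ARI ≈ 0.96), and the anchored
groups separate the simulated NIH activity index (Kruskal–Wallis
p = 2 × 10⁻⁴) with the planted ordering G2 > G1 > G0.

Individual stages are exported (`arcsinh_transform()`, `qc_filter()`,
`correct_batches()`, `cluster_cells()`, `ifn_score()`, `build_nam()`,
`nda_associate()`, `kmeans_stratify()`, `anchor_group_labels()`,
`classify_renal_response()`, ...) and documented; the methods vignette
(`vignettes/cytostrat-methods.Rmd`) describes the models, defaults and
design choices. `write_cohort_fcs()` / `read_events()` move cohorts
through standard FCS 3.0 files, and `inst/scripts/cytostrat` is a thin
command-line wrapper for simulation and full runs.

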