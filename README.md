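# cfrnadx

Differential diagnosis of pediatric inflammatory syndromes from plasma
cell-free RNA (cfRNA).

Kawasaki disease (KD), multisystem inflammatory syndrome in children
(MIS-C), and viral and bacterial infections overlap clinically but need
different treatment. Plasma cfRNA is shed by dead and dying cells from
blood and solid tissues, so one RNA-seq assay yields both a host-response
signature that separates these syndromes and a cell-type-of-origin mixture
that quantifies organ injury. `cfrnadx` is an R package for analysts
building or evaluating such assays: it takes a gene-by-sample count matrix
plus sample metadata and produces gene panels, trained classifiers, cell
type fractions, and per-patient diagnostic reports. A seeded synthetic
cohort generator with full ground truth makes every stage testable.

## What it implements

* **Sample QC** — fail a sample iff intron/exon ratio > 3, total counts
  < 75,000, or 5′–3′ bias > 2 (strict inequalities; reasons reported).
* **Normalization** — median-of-ratios size factors
  `s_j = median_i K_ij / g_i`; method-of-moments gene dispersions with a
  parametric trend `phi(mu) = a0 + a1/mu`; closed-form NB
  variance-stabilizing transform
  `h(q) = log2[(1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0)]`;
  strict train-to-new-sample projection that never refits.
* **Differential abundance** — per-gene NB Wald tests
  (`E K_ij = s_j exp(b0 + b1 x_j)`, fixed trend-moderated dispersion,
  vectorized IRLS), BH correction, per-gene ROC-AUC on VST values, and
  UpSet-style exclusive intersection counts of DAG sets.
* **Gene panels** — the filter cascades (adjusted p, base mean, two-sided
  gene AUC, |log2FC|, optional top-N by AUC) with shipped presets
  `misc_kd`, `multiclass_pairwise`, `covid_vs_other_viral`.
* **Classification** — stratified 60:20:20 / 70:30 partitioning;
  elastic-net logistic regression with CV-by-AUC lambda selection and
  Youden-threshold calls; a bake-off harness over six algorithm families
  selected by validation AUC; and a one-vs-one stack: six pairwise lasso
  models scoring every sample, with a 500-tree random forest
  meta-classifier turning the six scores into four class probabilities.
* **Cell type of origin** — non-negative least-squares deconvolution of
  relative abundances against a reference profile matrix, 0–1 scaling per
  cell type, and Wilcoxon/BH group contrasts (ALT, cardiac function,
  COVID severity stratifications).
* **Reports** — per-patient class probabilities with borderline flags and
  organ-injury z-scores (endothelium, heart, liver, lung, neuronal)
  against the healthy-donor distribution; lossless JSON and markdown.
* **Synthetic cohorts** — Dirichlet mixtures of cell-type profiles, NB
  counts, planted per-group and shared signatures, planted QC failures,
  and clinical covariates tied to the true fractions.

## Worked example

```r
library(cfrnadx)

ref    <- make_reference(13, 2000, seed = 5)
cfg    <- simulation_config(group_sizes = c("KD" = 40, "MIS-C" = 40,
                                            "viral" = 40, "bacterial" = 40,
                                            "healthy" = 30),
                            n_genes = 2000, seed = 7)
cohort <- simulate_cohort(cfg, ref)

pipeline <- run_pipeline(cohort, seed = 11)
print(pipeline)
#> cfRNA diagnostic pipeline: 110 train / 40 test samples; 6 pairwise panels
#>   train accuracy = 1.000; test accuracy = 1.000

print(pipeline$reports[[1]])
#> # Diagnostic report: S0001
#>
#> - QC status: pass
#> - Predicted condition: **KD**
#>
#> ## Class probabilities
#>
#> - KD: 0.97
#> - MIS-C: 0.026
#> - viral: 0.002
#> - bacterial: 0
#>
#> ## Organ injury z-scores (vs healthy donors)
#>
#> - endothelium: 0.79
#> - heart: 2.03
#> - liver: -0.027
#> - lung: -0.95
#> - neuronal: 0.96
```

(Report probabilities are printed at full precision by the package; they
are rounded here for display.) The pipeline ran QC, split the four disease
classes 70:30 stratified by group/hospital/subgroup, fit normalization and
six pairwise differential-abundance panels on the training set only,
trained the one-vs-one lasso stack with its random-forest meta-classifier,
projected the test samples through the training normalization model, and
deconvolved cell-type fractions — here sample S0001 is confidently called
KD, with a heart z-score of about 2 against healthy donors. On this
planted-signature cohort the held-out accuracy is 1.0; with planted
effects set to zero the same path returns chance-level AUC (this contrast
is asserted in the test suite).

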