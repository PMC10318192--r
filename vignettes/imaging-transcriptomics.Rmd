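---
title: "Methods: sex-stratified imaging-transcriptomics of resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified imaging-transcriptomics of resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imgtx)
```

# The analysis this package implements

Autism spectrum disorder (ASD) shows a strong male bias, and case-control
neuroimaging differences appear to differ by sex. The analysis chain
implemented here asks, separately for male and female cohorts drawn from a
multi-site resting-state fMRI consortium: (1) where does voxelwise
functional activity differ between cases and controls once scanner/site
effects are removed, (2) which gene-expression gradients (from a donor
microarray atlas) spatially track those difference maps, and (3) how well
do the implicated regions predict clinical scores and diagnosis.

The chain is: voxelwise activity metrics (ALFF, ReHo, degree centrality)
→ ComBat site harmonization protecting age and diagnosis → two-sample
t-maps with FDR and cluster-extent control → parcel-level feature maps →
probe-level expression processing into a left-hemisphere parcel × gene
matrix → PLS regression of the feature map on gene expression with
permutation and bootstrap inference → cross-validated SVR/SVC prediction.

Real consortium fMRI and donor microarray data are large external
downloads; every stage here instead runs against a synthetic cohort
generator with known ground truth, so each stage's parameter recovery is
testable end to end. Published case-control results at full scale are not
reproduced by this package; what the test suite establishes is that each
stage recovers what was injected and stays calibrated when nothing was.

# The synthetic cohort

`generate_cohort()` builds one 4D BOLD run per subject on a 12×12×12 grid
with an ellipsoidal mask (~650 voxels), 150 frames at TR = 2 s. These are
the smallest sizes at which the 0.01–0.1 Hz band contains a useful number
of DFT bins (28) and cluster statistics are meaningful. Each run is:

* baseline white noise (sd 1, arbitrary signal units);
* a low-frequency sinusoid (0.05 Hz, inside the band) whose amplitude is
  `amp_base` plus a subject-level jitter (sd `amp_sd`); in the designated
  *effect regions* the case group's amplitude is raised by
  `effect_size × amp_sd`, so `effect_size` is the injected Cohen's d on
  the band amplitude — the ALFF ground truth;
* a parcel-shared band-limited signal (weight `reho_weight`) giving local
  coherence — the ReHo ground truth;
* a global network signal loaded strongly on ~5% hub voxels and weakly on
  a third of all voxels — the degree-centrality ground truth;
* site location/scale effects applied to the BOLD signal itself (not to
  the derived metric), so harmonization is exercised end to end;
* a smooth motion random walk with injected spike frames; a spike at
  frame k raises frame displacement above 0.5 mm at frames k and k+1
  (the jump out and back).

The default configuration emulates a six-site consortium with a
male-heavier case group (4 male cases, 4 male controls, 2 female cases,
3 female controls per site), a desk-scale rendering of the screened
multi-site cohort structure returned by `abide_screened_counts()`.
Features of real data deliberately **not** modeled: hemodynamic response
shape, EPI distortion, T1 anatomy, spatial autocorrelation of
physiological noise, age-dependent effects on the metrics. Passing tests
therefore demonstrate algorithmic correctness and calibration, not
robustness to those realisms.

A single RNG stream per bundle is derived from `ground_truth()$seed`;
the probe table uses `seed + 1` and the clinical scores `seed + 2`, so
every artifact is reproducible from the seed alone.

# Functional-activity metrics

The enforced stage order is: linear detrend → ALFF (on unfiltered data)
→ ideal band-pass (0.01–0.1 Hz) → nuisance regression (6 motion
parameters, global mean, optional tissue stand-ins) → spline scrubbing of
frames with FD > 0.5 mm → ReHo / DC → z-transform → 8 mm FWHM Gaussian
smoothing. Calling a metric out of order raises a contract warning, not
an error.

* **FD** is the Power convention: sum of absolute translation deltas plus
  50 mm times the sum of absolute rotation deltas (radians), first frame
  0. The 50 mm head radius is the common default of the major
  preprocessing toolboxes; the flagging threshold is 0.5 mm.
* **ALFF** is the mean of the single-sided DFT amplitude spectrum over
  the in-band bins. Using the mean (not the sum) makes the raw value
  independent of run length. It is computed before temporal filtering so
  the in-band content is measured intact.
* **Band-pass** is an ideal DFT-domain filter: coefficients inside the
  band are kept exactly, everything else (including DC) is zeroed. Exact
  band edges, zero phase distortion, and trivially testable against the
  DFT.
* **ReHo** is Kendall's coefficient of concordance over the voxel and its
  26 in-grid neighbors: W = 12 Σ_t (R_t − R̄)² / (K²(n³ − n)), with
  midranks for ties and no tie correction in the denominator. At mask
  edges the neighborhood shrinks to the in-mask voxels with K adjusted —
  zero-padding would create rank artifacts from constant series.
* **DC** is the mean Pearson correlation with all other in-mask voxels
  whose correlation strictly exceeds 0.25; a voxel with no suprathreshold
  neighbor gets 0, zero-variance voxels have their correlations defined
  as 0 and are excluded as neighbors. A binarized variant (proportion of
  suprathreshold neighbors) is available but not the default, since the
  defining description is a mean of correlation coefficients.
* **Scrubbing** replaces flagged frames by a natural cubic spline through
  the unflagged frames; a flagged first or last frame takes the nearest
  retained frame's value rather than extrapolating the spline.
* **Smoothing** uses σ = FWHM / (2√(2 ln 2) · voxel size) and restricts
  and renormalizes the kernel inside the mask, so constants are fixed
  points and nothing bleeds across the mask edge.

# Site harmonization (ComBat)

`combat()` implements standard parametric empirical-Bayes location/scale
batch adjustment: feature-wise OLS on covariates plus batch indicators;
standardization by the pooled residual scale; EB shrinkage of per-batch
locations (normal prior) and scales (inverse-gamma prior) by the usual
iterative moment scheme (convergence when the largest parameter change
falls below 1e-6); removal of the shrunken batch effects and restoration
of the covariate fit. Age **and diagnosis** are protected covariates by
default: removing site without protecting diagnosis would bias the
downstream group contrast whenever group proportions differ by site. The
protection set is a plain argument for users who prefer age only.
Features with zero within-batch variance are left unadjusted with a
warning rather than erroring. Tests verify agreement with the published
reference implementation to ~1e-8 on shared fixtures.

One property worth stating precisely: ComBat is *not* idempotent. The
algorithm pools variance with denominator n but estimates batch variances
with denominator n_i − 1, so a second pass rescales residuals by exactly
√((n − n_batches)/n) even with no covariates (the test suite asserts this
identity to machine precision), and with covariates the per-batch scale
adjustment additionally perturbs the refitted covariate betas. This is a
property of the standard algorithm, shared by the reference
implementation, not an implementation artifact.

`site_leakage_audit()` closes the loop: a cross-validated linear SVM
trying to predict site from the harmonized features should perform near
chance; the report is flagged when accuracy exceeds chance by more than a
margin (default 10 points).

# Group statistics

Within each sex stratum, `two_sample_tmap()` computes feature-wise
pooled-variance two-sample t statistics (df = n₁ + n₂ − 2, two-sided p),
`fdr_bh()` applies Benjamini–Hochberg adjustment (delegating to
`p.adjust`), and `significant_clusters()` gates voxels at FDR q < 0.05
and then keeps connected components strictly larger than 20 voxels under
26-connectivity — the common default of the cluster-reporting tools in
this field. The gate order (FDR first, extent second) is the
documented default; both the threshold and connectivity are arguments.
Features with zero pooled variance get t = 0 with a warning.
`regional_summary()` averages any map over parcels, with a left-hemisphere
subset for the expression analyses.

# Expression processing

The probe pipeline mirrors the standard microarray-atlas workflow:

1. `filter_probes()` drops rows with invalid (missing/empty) gene ids,
   then drops probes whose fraction of samples flagged above background
   falls below 0.5 — "present in less than half of the donor samples",
   interpreted at the sample level as in intensity-based filtering.
2. `select_probe_per_gene()` keeps, for each multi-probe gene, the probe
   whose parcel-level mean expression pattern has the highest Spearman
   correlation with the gene's RNA-seq reference profile over shared
   parcels. Constant probe patterns have undefined correlation and are
   treated as −∞; ties break lexicographically by probe id; genes absent
   from the reference fall back to highest mean intensity with a warning.
3. `aggregate_to_parcels()` averages samples per (parcel, gene),
   restricted to left-hemisphere parcels (most donors sample only the
   left hemisphere in the real atlas), drops parcels with no samples, and
   z-scores each gene column across parcels.

Aggregation is a plain arithmetic mean with no donor-level normalization
beyond the final column z-scoring; donor-specific normalization curves
are out of scope. `risk_gene_coexpression()` gives the Pearson
co-expression of a gene list across parcels.

# PLS association and inference

`pls_fit()` is univariate-response NIPALS PLS: components maximize the
covariance between predictor scores and the response, with standard
deflation; explained variance per component is the incremental fraction
of var(y). Predictors and response are centered and scaled internally.

Inference:

* `permutation_test_variance()` refits under reorderings of the response
  and reports p = (1 + #{permuted ≥ observed}) / (n_perm + 1) per
  component, so p is never exactly 0 — the smallest reportable value is
  1/(n_perm + 1), and a published "p = 0" is read as truncation. The
  default null is a plain row permutation, which is exact for the
  synthetic parcellation (it has no built-in spatial autocorrelation); a
  variogram-matched surrogate null (`null = "spatial"`, Gaussian fields
  with an exponential covariance fitted to the map's empirical
  variogram, rank-remapped to the observed values) is provided for maps
  with genuine spatial structure.
* `bootstrap_gene_weights()` resamples parcels with replacement — the
  parcel is the exchangeable unit of the regression — refits, sign-aligns
  each replicate's weight vector to the original component (PLS
  components carry an arbitrary sign), and reports Z = weight / bootstrap
  SE, ranking genes by Z. `select_top_genes()` takes the top 5% of genes
  per tail (ceiling rule), both tails, since both strongly positive and
  strongly negative weights are interpretable.
* `weighted_expression_map()` projects a weight vector back to parcels
  (and voxels) for visualization and for the spatial-similarity
  permutation test (`spatial_similarity_test()`, two-sided on |r|).

A genuinely open numerical point, settled as follows: in the parcels ≪
genes regime PLS overfits — with 40 parcels and hundreds-plus of
uncorrelated gene profiles, *any* response has most of its variance
captured by component 1, and a response equal to one gene column reaches
only ~0.83 while permuted responses reach similar values. The classical
"perfect predictor" intuition (component 1 explains everything, the
permutation p sits at its floor) holds exactly when the gene profiles are
orthogonal, so the test suite constructs that geometry explicitly
(orthonormalized profiles, 40 parcels × 20 genes). When several
components pass the permutation test the pipeline reports all of them and
ranks genes on the most significant one (ties broken by larger explained
variance), rather than hard-coding a component index.

# Clinical prediction

`svr_loocv()` predicts a clinical score from regional features with a
linear ε-SVR under leave-one-out cross-validation. Age is handled by
regressing it out of the features *and* the score with coefficients
estimated on the training fold only, adding the fold's age prediction
back for the held-out subject; residualizing both sides (rather than
features only) makes an age-independent linear signal exactly recoverable
in the noiseless limit and keeps the covariate treatment symmetric.
Significance comes from label permutations of the entire LOOCV loop
(statistic: negative rMSE), default 1,000 permutations. Hyperparameters
are fixed (linear kernel, C = 1, ε = 0.1) with no nested tuning, so the
permutation test is honest; all are arguments. `svc_cv10()` classifies
diagnosis with a stratified 10-fold linear SVC, reporting mean accuracy
and mean rank-based AUC over folds, shrinking the fold count with a
warning when the smaller class is too small. Feature residualization and
model fitting always happen inside the training folds; a test
demonstrates the optimism that training-set reuse would produce on null
features.

# Orchestration, sizes and limitations

`run_pipeline()` sequences the whole analysis per sex stratum and metric,
writing every stage's artifacts (NIfTI maps, TSV tables, JSON summaries,
a provenance record with seed and config hash) before the next stage
begins; stage failures abort with the stage name. Sex strata are
harmonized separately, mirroring parallel analysis arms. The package's
interface is R functions plus this vignette; the pipeline is driven from
R (`pipeline_config()` + `run_pipeline()`) rather than a shell binary,
which is the natural interface for an R analysis package.

Problem sizes in the test suite are chosen for tight feedback: metric
oracles at 8×8×8×120 with ~35-voxel masks (20 random runs), ComBat
recovery at 2 sites × 40 subjects × 60 features (50 simulations), null
calibration at 200 generated cohorts of 16 subjects, PLS calibration at
500 replicates × 500 permutations, gene recovery at 50 replicates of a
40-parcel, 120-gene atlas, and a full two-arm pipeline run repeated twice
for byte-identical outputs. Defaults in the functions themselves stay at
field scale (10,000 permutations, 1,000+ bootstraps).

Known limitations: parametric EB only (no nonparametric ComBat, no
longitudinal or covariance-harmonizing variants); no TFCE or
permutation-based cluster-mass inference; the spatial surrogate null
assumes an isotropic exponential variogram; the generator's parcels are
random contiguous regions, not an anatomical atlas, and its hemisphere
tag is a simple midline split.
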