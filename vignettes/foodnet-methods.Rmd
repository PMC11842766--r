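---
title: "Methods: representational similarity networks for food-responsive regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity networks for food-responsive regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodnet)
```

## The analysis problem

When people view pictures of foods, several brain regions respond more to
foods than to other objects. A univariate contrast identifies *where* such
responses occur but not *what* information each region carries. This package
implements a multivariate workflow that addresses the second question on a
fully synthetic cohort with planted ground truth:

1. **Behavioural similarity.** An odd-one-out triplet task over 36 foods is
   converted into a 36 × 36 similarity matrix: for each pair, the proportion
   of triplets containing both foods in which neither was picked as odd.
   PCA of this matrix extracts the dominant property dimensions, and
   silhouette-validated k-means on the first two components discovers food
   categories.
2. **Neural RDMs.** Each region of interest (ROI) yields a condition × voxel
   beta matrix per subject; its representational dissimilarity matrix (RDM)
   is one minus the Pearson correlation between condition patterns,
   averaged across subjects into a group RDM per ROI.
3. **Network clustering.** Correlating the upper triangles of the group RDMs
   across ROI pairs gives a second-level ROI similarity matrix. ROIs with
   outlying geometry are screened out (mean multivariate distance z-scored
   across ROIs, exclusion at z ≥ 2 on the correlation metric, with Euclidean
   and PCA-reduced Mahalanobis metrics reported alongside). The remaining
   ROIs are partitioned into sub-networks, with the number of clusters
   selected by mean silhouette.
4. **RSA.** Subject-level neural RDMs are compared to behavioural model RDMs
   by Spearman correlation, z-scored against a permutation null obtained by
   relabelling the neural RDM's conditions, and tested at the network level
   by a two-stage summary-statistic procedure with Benjamini–Hochberg FDR.
5. **Searchlight.** The same RDM-model comparison is run in radius-3
   spherical neighbourhoods across a volume, producing subject Fisher-z maps
   combined by a voxelwise one-sample t-test and FDR thresholding.
6. **Amplitude-modulated GLM.** A two-condition rating task is analysed with
   a design containing a unit-amplitude onset regressor and a regressor
   whose event amplitudes are the mean-centered ratings, convolved with a
   gamma-variate hemodynamic response function; modulated betas enter a
   2 × 2 network × condition repeated-measures analysis.

## The synthetic cohort and what it does (and does not) emulate

All inputs are generated by `synth_config()` and the `gen_*` functions with
planted ground truth, so every downstream stage has a known correct answer.

**Food space.** 36 items around 5 category centroids placed on an ellipse
(half-axes 0.9 and 0.7, within-category sd 0.09) in a 2-D latent space whose
first axis plays the role of the food-processing dimension. Ground-truth
similarity is `exp(-distance)`, which keeps similarities in (0, 1] like the
proportion-valued behavioural matrix. The gentle overall scale keeps this
kernel in its quasi-linear regime; that is what makes the first two principal
components of the estimated similarity matrix carry ~80% of its variance, as
observed in the behavioural data the generator emulates, while the five
categories remain separable (silhouette of the true labels ≈ 0.77). A more
saturated kernel (larger scale) pushes variance into block-structure
harmonics and drops the two-component share to ~70%.

**Triplet choices.** All 7140 unordered triplets are enumerated (the
study-scale design samples each 5 times), and the odd item is drawn from a
Luce/softmax rule: the probability that item *x* is odd is proportional to
`exp(sim(y, z) / temperature)` for the remaining pair. Temperature 0.15
against similarity contrasts of ~0.1–0.7 gives decisive but noisy choices;
at temperature → 0 the rule becomes the argmax used by several oracle tests.

**ROI patterns.** Network-1 ROIs encode a geometry derived from latent
dimension 1; network-2 ROIs encode a geometry derived from an independent
hedonic score; one outlier ROI has an unrelated geometry with a 3× distance
scale, giving the outlier screen a true positive analogous to an
early-visual region dominated by low-level image features. Patterns are
i.i.d. normal voxel matrices mixed by the matrix square root of the target
condition-correlation kernel, plus i.i.d. noise (sd 0.6). Each subject's
geometry is additionally jittered (`subject_jitter = 1.5` times the score
sd, inter-subject geometry correlation ≈ 0.55). This between-subject
variability is essential, not cosmetic: if all subjects shared one exact
geometry, the group t-test would treat even chance-level rank overlap
between an unrelated kernel and a model RDM (|rho| of a few hundredths with
36 conditions) as a systematic effect and declare it significant at t ≈ 50.
Real cohorts differ in representational detail; with the jitter in place the
unrelated network tests at |t| ≈ 1 while the planted association tests at
t ≈ 13.

**Searchlight volume.** A 16 × 16 × 10 volume in which an axis-aligned
cuboid occupying ~30% of the volume (11 × 11 × 7) encodes the target RDM by
the same mixing construction; everything else is noise. The fraction is
deliberately large relative to the sphere radius: centers up to ~2 voxels
outside the region genuinely carry signal because their spheres straddle the
boundary, so a small planted region would cap the achievable Dice overlap of
the FDR map with the region at ~0.4 regardless of cohort size or noise. The
volumetric cohort uses 12 subjects — enough for a stable group map at this
effect size while keeping the stage's runtime desk-scale.

**Rating task.** Item ratings in both conditions derive from the hedonic
score plus a stable subject-level taste component (sd 0.25) and
condition-level noise (sd 0.1), reproducing a within-subject inter-condition
rating correlation ≈ 0.99 and a between-subject correlation ≈ 0.93.
Network-2 ROIs respond at +0.8 per rating unit in both conditions;
network-1 ROIs at +0.8 for self-control and −0.8 for pleasantness; the
outlier ROI is unmodulated.

What the generator does **not** emulate: hemodynamic nonlinearity, motion
and physiological artifacts, autocorrelated noise, spatial smoothness of
real BOLD data, subject-specific anatomy, or any non-food conditions.
Passing tests therefore demonstrate the correctness and calibration of the
pipeline's computations, not the robustness of the scientific conclusions to
real-data artifacts.

## Numerical and design choices

- **Similarity diagonal.** The similarity matrix's diagonal is fixed at 1
  (a self-pair can never be odd) and included in the PCA rows; columns are
  centered, no variance scaling.
- **Unobserved pairs** are hard errors downstream, not imputed; full
  enumeration makes them impossible in intended use.
- **Upper-triangle order** is row-major over pairs (i < j), fixed
  project-wide; all second-level correlations depend only on consistency.
- **Pattern-level vs comparison-level correlation.** RDMs use Pearson
  correlation distance on voxel patterns; RDM comparison uses Spearman.
  No cross-validated or noise-normalized distances.
- **Permutation null.** The neural RDM's conditions are relabelled jointly
  on rows and columns — the standard RSA null that preserves the RDM's
  internal structure. z uses the raw null mean and sd. Exhaustive
  enumeration of all n! relabelings is available for n ≤ 7. With 1000-10,000
  sampled permutations the z is unbiased (mean 0.010 ± 0.016 over 4000
  replicates) with sd ≈ 1. Note that the mean of z over 200 replicates has a
  Monte Carlo sd of ~0.07; checks of the form "mean within ±0.1" are
  expected to fail for ~15% of seeds even under perfect calibration.
- **Group tests.** A crossed random-effects model is replaced by the
  two-stage summary-statistic procedure (subject-level averaging, then
  one-sample and paired t-tests): deterministic, dependency-free, and
  consistent with the degrees-of-freedom pattern of interest. FDR is
  applied across each family of tests.
- **Dual clustering paths.** The ROI partition is available both as
  silhouette-validated k-means on the rows of the similarity matrix
  (default; silhouette distance 1 − s) and as maximum-modularity community
  detection on a graph with edge weights (s + 1)/2 (modularity needs
  non-negative weights; the affine map preserves order). Exact
  maximum-modularity search enumerates all set partitions for m ≤ 10 ROIs
  (Bell(10) ≈ 1.2 × 10⁵, the practical limit for enumeration in R at test
  timescales); larger problems use greedy agglomeration with single-node
  refinement passes, which matches the exhaustive optimum on all tested
  instances. The silhouette for k selection is computed on 1 − s.
- **Outlier screen.** Mahalanobis distances between ROI RDM vectors are
  computed in a PCA-reduced space of at most m − 2 components because the
  630-dimensional covariance across ~17 ROIs is singular. The exclusion
  decision keys on the correlation metric at z ≥ 2.0; the other metrics are
  reported.
- **Searchlight conventions.** Sphere membership is `dx² + dy² + dz² ≤ r²`
  on integer offsets (123 voxels at r = 3); spheres are intersected with the
  mask and bounds; centers with fewer than `min_voxels` (default 10) members
  are undefined and propagate as missing. |rho| is clipped to 1 − 1e-7
  before the Fisher transform. Cluster-extent correction via spatial
  autocorrelation simulation is out of scope; FDR thresholding is the
  implemented inference.
- **HRF.** `h(t) = (t/(pq))^p exp(p − t/q)` with p = 8.6, q = 0.547 s — the
  long-standing default gamma variate of the AFNI-style analysis this
  emulates — sampled on a 0.1 s grid, peak-normalized, truncated past the
  peak below 1e-4 of peak. Modulators are mean-centered per run so the onset
  regressor carries the mean response; a constant modulator zeroes the
  modulated column, which is dropped with a warning. Polynomial trends up to
  cubic are orthogonalized columns.
- **Determinism.** Every generator and every stochastic stage takes a seed;
  `run_pipeline()` derives stage seeds from one master seed and records a
  manifest sufficient to reproduce a run exactly.

## Problem sizes used by the packaged analyses

The numbered scripts under `analysis/` and the acceptance script run the
full 43-subject, 17-ROI, 36-item cohort for the behavioural and clustering
stages; the permutation RSA driver uses 500 permutations per cell (the full
design's 10,000 is available via `n_perm`); the searchlight stage uses the
12-subject volumetric cohort; estimator-recovery summaries use 100 simulated
runs of 206 volumes. These sizes were chosen so each stage completes in
seconds to a few minutes on one core while keeping every statistical
property of interest measurable.

## Known limitations

- The silhouette-versus-modularity choice for cluster-number selection is
  genuinely underdetermined in the emulated analysis (its Results describe
  k-means, its Methods optimal-modularity clustering); both paths are
  exposed and agree on block-structured inputs, but they are not guaranteed
  to agree on arbitrary data.
- The outlier screen's z-threshold (2.0) is a convention, not an estimate;
  with many ROIs it will eventually exclude a non-outlier by chance.
- Permutation z-scores are computed per subject × ROI × model; pooled nulls
  are not implemented.
- The two-stage group procedure ignores ROI-level heteroscedasticity within
  networks; with very unbalanced network sizes a mixed model would weight
  differently.
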