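---
title: "Longitudinal spatial-habitat radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal spatial-habitat radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(habitatr)
library(dplyr)
```

## The scientific problem

Neoadjuvant treatment (NAT) of breast cancer aims at a pathological complete
response (pCR), but tumors are spatially heterogeneous: a contrast-enhanced MR
volume mixes highly perfused, metabolically active tissue with transitional
and hypoxic/necrotic zones, and these compartments respond to therapy at
different rates. Whole-tumor ("traditional") radiomics averages over this
structure. Spatial-habitat radiomics instead partitions each tumor into a
small number of *habitats* — spatially coherent subregions with similar
enhancement characteristics — and extracts the feature panel per habitat, at
both a pre-treatment and a mid-treatment timepoint, so that the *shift in
subregional composition* during therapy can enter a response model.

`habitatr` implements that pipeline end to end: intensity preprocessing,
supervoxel over-segmentation and k-means habitat delineation with
Calinski-Harabasz cluster-count selection, an IBSI-style feature panel,
a staged feature-selection cascade, gradient-boosted response models fusing
longitudinal radiomics with clinical covariates (cT stage, ER, HER2), and a
downstream immune-association stage (TPM, moderated differential expression,
GSEA/ssGSEA, marker indices, Ro/e). Because patient images cannot be
redistributed, the package ships a synthetic phantom/cohort generator whose
planted ground truth makes every stage testable.

## The synthetic study system

`generate_phantom_pair()` builds an ellipsoidal tumor (smoothly perturbed
boundary) on a 1 mm isotropic grid and partitions it into three spatially
coherent perfusion classes grown from mutually distant seeds by
capacity-balanced competitive growth (a discrete power diagram), so the
planted classes look like the contiguous habitat maps seen in practice rather
than salt-and-pepper noise. Class 1 is the most-enhancing compartment
(means strictly decreasing, default 300/200/100 intensity units, class SD 15,
acquisition noise SD 5 — a more than 5-SD separation between adjacent
classes). The mid-treatment image is a shrunken tumor (linear factor 0.7)
recomposed to the mid-timepoint fractions.

`generate_cohort()` draws, per patient:

* clinical covariates with marginals typical of a locally advanced cohort
  (cT2 dominant, ER+ 65%, HER2+ 40%), and the derived molecular subtype;
* a pre-treatment habitat composition (Dirichlet around 0.40/0.35/0.25,
  concentration 12) and a longitudinally coupled mid-treatment composition:
  the same tumor after a treatment shift that depletes the high-enhancement
  class (class-wise multipliers 0.55/1.00/1.45), plus per-patient response
  noise (Dirichlet concentration 25). The coupling (correlation about 0.8
  between pre and mid class-1 fractions) mirrors the fact that both
  timepoints of a real tumor are informative;
* the outcome, from a logistic model whose linear predictor combines the
  clinical terms (log-odds 0.8 for cT1, 0.7 for HER2+, 0.5 for ER−, matching
  the directions reported as independent predictors of pCR) with a
  subregional imaging term: `effect * (-z(mid class-1 fraction) +
  0.25 * z(class contrast))`. The intercept is calibrated so the marginal
  response rate is 0.4, the prevalence reported for large NAT cohorts.

Two constructions place the signal *in the subregions by design*. First, the
whole-tumor mean is matched across patients: per-patient class means are
shifted so the composition-weighted mean is constant at both timepoints, so
no first-order whole-tumor average carries outcome information. Second, the
outcome uses the planted mid-treatment class-1 fraction, which only a
subregional analysis can measure directly. A whole-tumor analysis still sees
the mixture's *dispersion* change with composition — an unavoidable
information leak in any mixture — which is why the whole-tumor models in the
recovery experiments perform above chance but below the habitat models, the
qualitative ordering the method is designed to demonstrate.

The default `effect = 2.4` and the contrast weight were fixed from an
oracle calculation, not from pipeline runs: histogram standardization (part
of the preprocessing contract) deliberately equalizes whole-tumor histograms
and with them most across-patient contrast information, so the learnable
imaging signal is the composition term; at the default the composition term
alone discriminates with an asymptotic AUC of about 0.87 (clinical terms
alone about 0.56), a strong but realistic planted signal that leaves room
for estimation and fitting losses while keeping subregional recovery clearly
demonstrable.
What the phantoms do *not* emulate: pharmacokinetic enhancement dynamics,
scanner/site effects, registration error between timepoints, or non-ellipsoid
topologies. Passing recovery tests therefore shows the pipeline's statistical
machinery is sound, not that any particular clinical performance level
transfers to real data.

## Preprocessing

The preprocessing contract is bias-field correction, then isotropic
resampling, then histogram standardization.

* **Bias field**: a multiplicative gain field is estimated as the exponential
  of a coarse Gaussian low-pass (default sigma 8 mm) of the log intensities,
  normalized to unit mean inside the mask, and divided out. This removes
  slowly varying coil inhomogeneity while leaving tissue-scale contrast; a
  constant volume passes through essentially unchanged.
* **Resampling** to 1 mm isotropic voxels uses a separable cubic
  (Keys, a = −0.5) kernel for intensities and nearest neighbour for masks,
  preserving physical extent within a voxel; volumes already at target
  spacing are returned untouched, so the step is idempotent.
* **Histogram standardization** maps decile landmarks (plus the 1st and 99th
  percentiles) computed *inside the tumor mask* onto reference landmarks by a
  monotone piecewise-linear transform with linear end-segment extrapolation.
  Landmarks are tumor-based rather than whole-breast because the analysis
  region is the tumor; the reference landmark vector is frozen with the model
  so application never re-estimates it. Re-standardizing moves landmarks by
  less than 1e-6.

## Habitat delineation

Tumor voxels are over-segmented into SLIC-style supervoxels in joint
(intensity, position) space, with seeds on a regular grid inside the mask and
a spatial weight `compactness / step^2` (default compactness 0.05, i.e.
intensity-dominant boundaries, 8 iterations, target 150 supervoxels).
Spatial 26-connectivity is enforced afterwards; disconnected fragments merge
into the *adjacent supervoxel with the closest mean signal*, so interface
fragments do not contaminate a foreign compartment. Per-supervoxel summary
features — mean, SD and normalized entropy of mask-standardized intensity —
form the clustering matrix. Computing them on standardized intensity and
leaving the matrix unscaled is deliberate: re-scaling each column to unit
variance would inflate the dispersion axes (which mostly carry noise) to the
same importance as the class-mean axis and destabilize cluster-number
selection.

The habitat count is selected by k-means (k-means++ initialisation, 10
restarts, Lloyd iterations, tolerance 1e-6) over candidate K = 2..6,
maximizing the Calinski-Harabasz index `[B/(K-1)]/[W/(N-K)]`, with the mean
silhouette width reported alongside as a consistency check. Selection is
intended to be run once on a training cohort and then held fixed — the
package applies K = 3 everywhere downstream, and pre- and mid-treatment maps
of one patient always share the same K. Final clusters are mapped back to
voxels and relabelled canonically by descending mean enhancement — label 1
the perfused/metabolically active core, label 3 the marginal/necrotic zone —
with ties broken by larger volume, so any permutation of k-means output
labels yields the identical habitat map. Masks under 200 voxels fall back to
voxel-level clustering on intensity alone, since over-segmentation needs a
minimum mass to be meaningful.

On default phantoms (5-SD class separation) this machinery selects K = 3 in
well over 90% of seeded runs and recovers the planted class map with
adjusted Rand index near 1; both facts are asserted by the test suite and
recomputed by `scripts/acceptance.R`.

## The feature panel

Each region yields 1223 features: 14 shape descriptors computed once from
the region geometry, plus 93 intensity/texture features on each of 13 image
channels — the original volume, the eight sub-bands of a single-level
stationary 3D Haar wavelet transform (LLL..HHH, voxel-aligned with the
input), and Laplacian-of-Gaussian responses at four scales (default sigmas
2, 3, 4, 5 mm; the accounting 14 + 93 x 13 = 1223 pins the
channel arithmetic). The 93 split as 18 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 14 GLDM and 5 NGTDM, with IBSI-style definitions: symmetric
distance-1 GLCM averaged over the 13 unique 3D directions, run-length
matrices averaged the same way, 26-connected zones for GLSZM, dependence
alpha = 0 for GLDM. Grey levels come from fixed-bin-width discretization
(default width 25 intensity units after standardization, re-binned only if a
degenerate region would exceed 64 levels), computed from the region minimum
per channel. A patient row concatenates whole-tumor (TR) and three habitat
(SHR) panels at both timepoints: 2 x (1223 + 3669) = 9784 named values, each
name carrying `timepoint_region_channel_family_feature` provenance.

Numerical choices worth knowing: surface area uses a smoothed-gradient
estimator (integral of the gradient magnitude of the Gaussian-smoothed
indicator, sigma 0.8 mm), accurate to well under 1% on spheres where naive
voxel-face counting errs by ~50%; maximum diameters use boundary voxels with
a deterministic extreme-point reduction on large regions; regions under 8
voxels return an all-flagged (NA) vector rather than being dropped; a region
with a single grey level yields the defined degenerate values (entropy 0,
guarded divisions 0). Brute-force enumeration oracles for the co-occurrence
and run-length matrices, and analytic shape limits, back these choices in
the tests.

## The selection cascade

Four stages, in fixed order, each emitting a tidy report with every
feature's statistic and fate:

1. **Reliability**: ICC(2,1) — two-way random effects, absolute agreement,
   single measurement — against re-delineations (simulated readers via
   `perturb_mask()`, a smooth random level-set displacement of configurable
   millimetre scale). Features need ICC > 0.8 for both the intra- and
   inter-reader comparison. Zero-variance features get ICC 0 by convention.
2. **Redundancy**: variance floor (default 1e-8), then greedy Spearman
   pruning: pairs with |rho| > 0.9 are visited in deterministic name order
   and the member with the weaker centred Mann-Whitney statistic
   `|U - n1 n2/2|` is dropped.
3. **Association**: two-sided Mann-Whitney per feature, retaining p < 0.05.
   No multiplicity correction is applied at this stage — a deliberately
   liberal screen, since the LASSO downstream provides the actual sparsity
   control; the type-I behaviour is verified (about 5% of null features
   retained).
4. **Sparsity**: L1-penalized logistic regression on standardized features,
   penalty chosen by stratified ten-fold cross-validated deviance at the
   minimum (the one-SE rule is available), selected features = nonzero
   coefficients.

Counts are non-increasing along the cascade and the LASSO picks only from
univariate survivors.

## Response models and evaluation

Single-timepoint models (preTR, preSHR, midTR, midSHR) are gradient-boosted
tree classifiers (depth 3, learning rate 0.1, 200 trees, 80% row subsample,
single thread, fixed seed) on their selected feature set. The fused models
(Clin-SHR, Clin-TR) combine the pre- and mid-treatment information with the
one-hot clinical covariates; two fusion modes exist. The default is score
stacking — a logistic meta-learner on the out-of-fold cross-validated
scores of the two single-timepoint bundles plus the clinical dummies —
which is the statistically efficient choice at cohort sizes where a single
boosted learner cannot exploit small additive clinical effects; feature
concatenation into one boosted learner is available as
`fusion = "concatenate"`. Each bundle freezes its feature list,
preprocessing statistics and a decision threshold set by Youden's J on
training predictions; applying a bundle never refits.

Evaluation reports AUC via the Mann-Whitney (pairwise concordance)
formulation with DeLong 95% intervals, sensitivity/specificity/accuracy at
the frozen threshold, quantile-binned calibration with a logistic
recalibration intercept/slope, decision curves
(`NB(t) = TP/n − (FP/n)·t/(1−t)` against treat-all and treat-none), and
subgroup evaluation (no refitting; subgroups need at least 10 patients with
both outcomes, otherwise they are flagged).

In the package's recovery experiment (`scripts/acceptance.R` and the test
suite), a 240-patient synthetic cohort is generated once, the compact
simulation panel (shape + first-order, original channel) is extracted per
habitat and whole tumor after histogram standardization, and 20 stratified
train/test re-splits (120/120) fit all six models; the habitat-based fusion
beats the whole-tumor fusion by a median held-out AUC margin above 0.05,
the qualitative ordering the method is designed to demonstrate. The
problem sizes (240 patients, 32-voxel grids, the compact panel) are the
package's chosen simulation scale: large enough for stable AUC contrasts,
small enough to re-run routinely. The full 1223-feature panel is exercised
on single phantoms where counting, not discrimination, is the question.
Absolute held-out AUC levels at this scale sit around the high 0.7s for the
mid-treatment habitat model — below the asymptotic oracle of 0.87 by the
combined finite-sample and fitting losses — so the experiments assert
orderings and margins, not absolute clinical performance.

## Immune association stage

The transcriptomic stage mirrors the field's standard toolchain but is
implemented in the package: exact TPM (columns sum to 1e6); moderated
two-group t-tests with empirical-Bayes variance shrinkage (prior scale and
degrees of freedom by moment matching of log residual variances — checked
against the established moderated-t implementation in the tests) and BH
adjustment reported alongside raw p-values; preranked GSEA as a weighted
Kolmogorov-Smirnov running sum with gene-label permutation NES and p;
ssGSEA per-sample scores (rank-weight exponent 0.25, min-max cohort
normalization); MCPcounter-style marker indices (mean log2(TPM+1) over
compact shipped marker panels — the B-cell panel is CD19, CD79A, MS4A1 plus
IGHM, IGHG1, IGHG2); Spearman feature-immune correlation matrices; Ro/e
(observed over chi-square-expected cell counts); and exact/approximate
Wilcoxon group comparisons. Model-score groups are dichotomized at the
median. On synthetic data with a planted B-cell marker shift the stage
recovers the full qualitative pattern: higher B-cell indices and ssGSEA
scores in the high-score group and Ro/e above 1 for B cells in that group.

## A worked miniature

```{r mini, eval = FALSE}
coh <- generate_cohort(n_patients = 60, seed = 1)
feats <- feature_table(coh$imaging,
  n_supervoxels = 60, seed = 1,
  config = feature_panel(families = c("shape", "firstorder"), transforms = "original")
)
fam <- fit_response_models(feats, coh$cohort$outcome, coh$cohort, seed = 2)
fam$evaluations
autoplot(fam$evals$ClinSHR)
```

(The chunk is not evaluated at build time; the identical computation, at the
sizes stated above, is what `scripts/acceptance.R` runs and records.)

## Known limitations

* Phantom tumors are perturbed ellipsoids with exactly three latent classes;
  topologically complex or multifocal lesions are out of scope.
* The whole-tumor information leak through mixture dispersion bounds how far
  the habitat-vs-whole-tumor margin can be pushed in simulation.
* The GAN-based resolution enhancement used upstream in some acquisition
  protocols is intentionally not implemented; inputs are assumed to be
  conventional reconstructions.
* Habitat maps are computed independently per timepoint (same K, no voxel
  correspondence); longitudinal registration is a non-goal.
* The magnitude of subregional effects in real data is unknown; the
  generator's effect size is a free parameter of the simulation, not an
  estimate.
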