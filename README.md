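# habitatr

Longitudinal spatial-habitat radiomics for treatment-response modelling in R.

## The problem

Breast tumors under neoadjuvant treatment (NAT) are spatially heterogeneous:
a contrast-enhanced MR volume mixes a highly perfused, metabolically active
core, transitional tissue, and hypoxic/necrotic margins, and these
compartments change differently during therapy. Whole-tumor ("traditional")
radiomics averages over that structure and misses it. Spatial-habitat
radiomics (SHR) partitions each tumor into a small number of *habitats* —
spatially coherent subregions of similar enhancement — and extracts the
radiomics panel per habitat at a pre-treatment and a mid-treatment
timepoint, so the shift in subregional composition can drive a prediction
of pathological complete response (pCR).

`habitatr` is a tested implementation of that pipeline for imaging
scientists and biostatisticians:

* **Preprocessing** — multiplicative bias-field correction, cubic
  resampling to 1 mm isotropic voxels, Nyul-style histogram landmark
  standardization (`bias_field_correct()`, `resample_isotropic()`,
  `standardize_histogram()`).
* **Habitats** — SLIC-style supervoxels inside the tumor mask, k-means with
  Calinski-Harabasz selection of the habitat count
  (`CH = [B/(K-1)]/[W/(N-K)]`, silhouette reported alongside), canonical
  enhancement-ordered labels: habitat 1 = most enhancing core, habitat 3 =
  marginal zone (`supervoxel_segment()`, `select_k()`,
  `cluster_habitats()`).
* **Features** — an IBSI-style panel: 14 shape + 93 first-order/texture
  features (GLCM, GLRLM, GLSZM, GLDM, NGTDM) on 13 channels (original, 8
  stationary-wavelet sub-bands, 4 LoG scales) = **1223 per region**, 3669
  per habitat timepoint, **9784 per patient** across both timepoints
  (`feature_panel()`, `extract_patient_features()`, `feature_table()`).
* **Selection** — ICC(2,1) reliability against re-delineations, variance +
  Spearman (|rho| > 0.9) redundancy pruning, Mann-Whitney association
  (p < 0.05), LASSO with cross-validated penalty (`select_cascade()`).
* **Models** — gradient-boosted single-timepoint models and fused
  clinical + longitudinal models (Clin-SHR / Clin-TR), AUC by the
  Mann-Whitney formulation with DeLong intervals, calibration curves,
  decision-curve analysis `NB(t) = TP/n - (FP/n) t/(1-t)`, subgroup
  evaluation (`fit_response_models()`, `evaluate()`, `decision_curve()`).
* **Immune association** — TPM, moderated differential expression,
  preranked GSEA and ssGSEA, MCPcounter-style marker indices, Spearman
  feature-immune correlation, Ro/e enrichment, Wilcoxon group comparisons
  (`tpm_normalize()`, `differential_expression()`, `gsea_preranked()`,
  `ssgsea_score()`, `marker_index()`, `roe()`).
* **Synthetic data** — phantom tumor pairs with three planted perfusion
  classes, full cohorts with outcomes causally linked to subregional (not
  whole-tumor) statistics, simulated reader re-delineations, expression
  matrices and cell-type tables with planted B-cell shifts
  (`generate_phantom_pair()`, `generate_cohort()`, `perturb_mask()`,
  `generate_expression()`, `generate_celltype_table()`).

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` visualisations.

## Worked example

```r
library(habitatr)

# a synthetic 60-patient cohort with paired pre/mid phantoms
coh <- generate_cohort(n_patients = 60, seed = 1)
dplyr::count(coh$cohort, outcome)
#> # A tibble: 2 x 2
#>   outcome     n
#>   <fct>   <int>
#> 1 non-pCR    34
#> 2 pCR        26

# habitats for one patient; label 1 = most-enhancing habitat
map <- delineate_habitats(coh$imaging$P001$pre$volume,
                          coh$imaging$P001$pre$mask, k = 3, seed = 1)
habitat_composition(map)
#> # A tibble: 3 x 2
#>   habitat fraction
#>     <int>    <dbl>
#> 1       1    0.391
#> 2       2    0.449
#> 3       3    0.160
# planted fractions for this patient: 0.393 / 0.450 / 0.157

# the full printed feature accounting on one patient
ph <- generate_phantom_pair(seed = 1)
hab <- list(
  pre = list(volume = ph$pre$volume, mask = ph$pre$mask,
             habitats = delineate_habitats(ph$pre$volume, ph$pre$mask, seed = 1)),
  mid = list(volume = ph$mid$volume, mask = ph$mid$mask,
             habitats = delineate_habitats(ph$mid$volume, ph$mid$mask, seed = 1))
)
length(extract_patient_features(hab$pre, hab$mid))
#> [1] 9784

# compact-panel feature table -> selection cascade -> six models,
# evaluated on a held-out split
feats <- feature_table(coh$imaging, n_supervoxels = 60, seed = 1,
  config = feature_panel(families = c("shape", "firstorder"),
                         transforms = "original"))
fam <- fit_response_models(feats, coh$cohort$outcome, coh$cohort, seed = 2)
fam$evaluations[, c("model_id", "auc")]
#>   model_id   auc
#> 1    preTR 0.636
#> 2   preSHR 0.731
#> 3    midTR 0.348
#> 4   midSHR 0.715
#> 5  ClinSHR 0.661
#> 6   ClinTR 0.367
```

At this deliberately tiny demonstration size (60 patients, 30 held out) the
AUCs are noisy, but the habitat models already separate from their
whole-tumor counterparts; the stable margins at full simulation scale
(240 patients, 20 re-splits) are what the acceptance script reports. The
composition printed above tracks the planted fractions (0.393/0.450/0.157)
because habitat clustering recovers the planted classes with adjusted Rand
index near 1 (see the test suite).

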