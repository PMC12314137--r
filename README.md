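# shockmet

Metabolic phenotyping of circulatory shock from targeted metabolomics.

Critically ill patients admitted with septic or cardiogenic shock are
clinically heterogeneous: admission severity scores (APACHE II, SOFA) miss
much of the biological variation that drives outcome. `shockmet` implements
an unsupervised stratification of shock patients from a targeted plasma
metabolomics panel (the six-family AbsoluteIDQ p180 layout: amino acids,
biogenic amines, acylcarnitines, glycerophospholipids, sphingolipids,
sugars), and asks whether the resulting metabolic phenotypes carry
prognostic information for in-hospital mortality beyond those scores.

It is written for intensive-care and metabolomics researchers who have a
patient × metabolite concentration table (with below-LOD and missing
cells), a metabolite → family annotation, and a small clinical table.

## Methods at its core

1. **QC filtering.** A metabolite is dropped when it has > 20 % missing
   values within any patient group or detectable concentrations in < 50 %
   of all samples. Below-LOD cells are imputed with half the minimum
   measured value, missing cells with the median; the matrix is
   log-transformed and z-scored per metabolite.
2. **Clustering.** The z-matrix is embedded into two dimensions with UMAP
   (n_neighbors = 15, min_dist = 0.1, Euclidean) and clustered with DBSCAN
   (eps = 0.7, minPts = 5); eps is guided by the knee of the k-distance
   curve (k = minPts − 1), computed and reported by the package.
3. **Stability.** Cluster reproducibility is the clusterwise bootstrap
   Jaccard index J(A, B) = |A ∩ B| / |A ∪ B| over patients common to the
   original and each resampled run (1000 iterations), plus an
   outlier-exclusion sensitivity re-clustering (max |z| > 5) with an
   assignment flow table.
4. **Cluster comparisons.** Continuous variables by tie-corrected
   Kruskal–Wallis tests; categorical variables by the exact r×c Fisher
   (Freeman–Halton) test, enumerated exactly under the multivariate
   hypergeometric law.
5. **Mortality model.** Univariate screen (p < 0.1), backward elimination
   (p < 0.05) with cluster membership forced, a standardized logistic model
   of in-hospital death (cluster 2 df + APACHE II + organ failures, EPV
   reported), and Harrell optimism-corrected bootstrap validation (c-index,
   calibration slope, Emax, g-index; 1000 resamples).

A synthetic-cohort generator plants three metabolic phenotypes (13/24/23 of
60 patients) with family-specific log-normal shifts and cluster-linked
mortality (54 % / 38 % / 9 %), so every stage is testable without patient
data.

## Worked example

```r
library(shockmet)

cohort <- simulate_cohort(default_spec(rng_seed = 3))
cfg    <- run_config(rng_seed = 3, n_boot = 100)

model <- run_clustering(cohort$tables, cfg)
model
#> cluster_model: 3 clusters, 0 noise points (eps = 0.7, minPts = 5)
#> cluster
#>  1  2  3
#> 24 23 13
#>   k-distance suggested eps: 0.590

stab <- bootstrap_stability(cohort$tables, cfg, model)
stab
#> stability_report: mean Jaccard 0.973 over 100 iterations
#>   per-cluster means: 1=0.997, 2=0.978, 3=0.946

fit <- fit_outcome_model(cohort$tables, model$labels, cfg)
fit$model
#> outcome_model: 19 events, 4 df, EPV = 4.75
#>              term estimate    se ci_lower ci_upper odds_ratio p_value
#>       (Intercept)   -2.259 0.764   -3.756   -0.761       0.10 0.00311
#>          cluster1    1.581 0.885   -0.154    3.315       4.86 0.07410
#>          cluster3    2.675 1.069    0.579    4.771      14.52 0.01240
#>           apache2    0.017 0.352   -0.674    0.708       1.02 0.96200
#>  n_organ_failures    0.551 0.372   -0.179    1.280       1.73 0.13900
fit$validation
#> bootstrap internal validation
#>   c-index:    apparent 0.805 -> corrected 0.749
#>   g-index:    apparent 1.57 -> corrected 1.7
#>   calibration slope 0.658, Emax 0.1187 (100 iterations, 0 redrawn)
```

The three discovered clusters recover the planted phenotypes (ids are
renumbered by decreasing size, so the 13-patient severe phenotype appears
as cluster 3 here); the mean Jaccard near 1 says the clusters reproduce
under resampling. In the mortality model the reference level is the
cluster with the lowest observed event rate, so the positive cluster
log-odds are the excess mortality of the other two phenotypes after
adjusting for APACHE II and organ failures; the corrected c-index and
calibration slope quantify how much of the apparent discrimination
survives optimism correction at 60 patients and ~19 events.

`summarize_baseline()`, `family_profile()` and `sensitivity_recluster()`
produce the cluster characteristics table, the family-level metabolite
profile, and the outlier-sensitivity flow table.

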