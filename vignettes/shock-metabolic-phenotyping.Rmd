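---
title: "Metabolic phenotyping of shock: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic phenotyping of shock: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockmet)
```

## The problem

Shock — septic or cardiogenic — is the leading reason for ICU admission,
and its in-hospital mortality varies widely between patients with similar
admission severity scores. Targeted plasma metabolomics quantifies on the
order of 10^2 small molecules in six biochemical families (amino acids,
biogenic amines, acylcarnitines, glycerophospholipids, sphingolipids,
sugars) from a single admission sample, and unsupervised analysis of that
matrix can stratify patients into metabolic phenotypes that severity
scores do not see. `shockmet` packages that analysis: metabolite QC,
density-based clustering of a two-dimensional embedding, cluster-stability
and outlier-sensitivity checks, exact cluster comparisons, and an
internally validated mortality model.

The intended cohort scale is tens of patients and 100–200 metabolites;
everything in the package is designed, defaulted and tested at that scale
(60 patients, 130 metabolites).

## Quality control and preprocessing

A metabolite is excluded when

1. more than `qc_missing_frac` (default 0.20) of its cells are missing
   within **any** patient group, or
2. its measured fraction over all samples falls below `qc_detect_frac`
   (default 0.50), where a below-LOD cell counts as *not detected* but not
   as *missing*.

The two statuses are deliberately distinct: below-LOD is an informative
left-censored measurement, missing is absence of a measurement, and the
two rules count them differently.

Rule 1 nominally refers to patient clusters, which do not exist before
clustering. The package resolves this chicken-and-egg by defaulting the
groups to the admission-cause strata (septic / cardiogenic) for the first
pass; `qc_filter()` accepts any group vector, so a second pass with the
discovered clusters is one call away. Both choices are recorded in the QC
result.

Imputation follows the common targeted-metabolomics conventions: below-LOD
cells get half the minimum measured value of that metabolite; missing
cells get its median measured value. Concentrations are then natural-log
transformed (they are strictly positive and right-skewed) and z-scored per
metabolite with the sample SD (denominator n − 1). The outlier screen of
the sensitivity analysis uses these log-scale z-scores; on raw
concentrations a |z| > 5 rule would flag most of any cohort, because
heavy-tailed raw distributions routinely produce such scores.

Degenerate inputs fail loudly: a metabolite with no measured value cannot
be imputed, and a zero-variance column cannot be z-scored; both errors
name the metabolite.

## Embedding and clustering

The z-matrix is projected to two dimensions with UMAP. Because "default
settings" are not portable across UMAP implementations, the parameters are
pinned explicitly: `n_neighbors = 15`, `min_dist = 0.1`, Euclidean metric,
two output dimensions, one thread, and a single configured seed stored in
the model. Rows are canonically sorted by patient id before embedding, so
results cannot depend on file row order.

DBSCAN then labels the embedding. The package ships its own
implementation with the textbook semantics — a core point has at least
`min_pts` points (itself included) within `eps`; clusters are connected
components of core points plus their border points; the rest is noise
(label 0) — with one deliberate refinement: a border point reachable from
several clusters joins the cluster of its **nearest** core point (ties by
smaller index). Textbook DBSCAN assigns such points to whichever cluster
reaches them first, which depends on visit order; the nearest-core rule
makes the partition a pure function of the point set. Cluster ids are
renumbered 1..K by decreasing size (ties by smallest member id). The test
suite holds this implementation against an independently written
brute-force oracle on random instances up to n = 200.

`eps` defaults to 0.7 with `min_pts = 5`, and the k-distance curve
(k = min_pts − 1) is always computed alongside: its knee — the point of
the sorted curve furthest from the end-to-end chord — is reported as
`eps_suggested`. The configured eps always wins; the suggestion reproduces
the "read the inflection off the k-distance plot" step without silently
automating the analyst's decision. On a flat curve every point is on the
chord and the suggestion degenerates gracefully to a curve value.

## Stability and sensitivity

Cluster stability is the clusterwise bootstrap Jaccard index. Per
iteration: patients are resampled with replacement and collapsed to the
unique set — duplicated coordinates would inflate local density, which
DBSCAN is directly sensitive to, and the agreement measure is set-based
anyway; UMAP + DBSCAN are re-run on the corresponding rows of the
reference z-matrix (QC and scaling are not recomputed: the resample is a
draw from the same cohort, and the question is whether the *clustering*
reproduces); each reference cluster is scored by its maximum Jaccard
index against any bootstrap cluster over the patients common to both
sets, noise never matches, and the iteration score is the unweighted mean
over reference clusters with at least one common member. Iteration seeds
are `rng_seed + iteration`, making the 1000-iteration default exactly
reproducible. The matching convention (per-cluster maximum, then
unweighted means) is stated rather than inferred: "mean Jaccard" alone
underdetermines the computation, and this is the clusterwise-stability
convention familiar from bootstrap cluster assessment.

The sensitivity analysis excludes patients whose maximum |z| over all
metabolites exceeds `z_outlier_threshold` (default 5), re-runs the whole
pipeline on the reduced cohort with identical parameters, and
cross-tabulates original versus reduced assignments (noise is a valid
category) — the table an alluvial plot draws. With no outliers the flow
table is exactly diagonal, since the runs are identical under the same
seed.

## Cluster comparisons

Continuous variables use the tie-corrected Kruskal–Wallis H with a
chi-square reference on k − 1 df (via `stats::kruskal.test`); an
all-identical variable is reported as H = 0, p = 1 rather than an error.
Note the chi-square reference is an approximation that is anti-conservative
for very small groups; the tests document its measured error at N ≤ 8.

Categorical variables use the exact r×c Fisher (Freeman–Halton) test,
authored in the package: all tables with the observed margins are
enumerated by depth-first traversal (rows filled cell-by-cell with
feasibility pruning; the last row is forced by the column margins), each
table's multivariate-hypergeometric probability is computed in log space
from `lfactorial`, and the two-sided p is the mass of tables no more
probable than the observed one. Ties in probability are resolved with a
relative slack of 1e-7, the convention of the standard implementations;
the total enumerated mass is returned as a self-check and tested to be
1 ± 1e-10. Zero margins are an error (drop empty categories first), since
the conditional test is undefined there.

Family profiles score each patient as the mean z-score over a family's
retained metabolites — the mean, not the sum, so families of 63 and of 1
metabolite are on the same scale — and report per-cluster medians with a
Kruskal–Wallis omnibus p per family. The baseline table renders
categorical cells as `n (percent)` with percent rounded half away from
zero to integers (the convention of clinical baseline tables), continuous
cells as median (min–max), and pairwise p-values unadjusted by default
(Holm et al. available via `p_adjust_method`), since pairwise baseline
tables in this literature are conventionally reported unadjusted.

## The mortality model

Covariates pass a univariate logistic screen at `screen_alpha = 0.1`
(Wald p for single-df terms; likelihood-ratio p for factor blocks, which
is the only coherent choice for a multi-level term), then backward
elimination at `keep_alpha = 0.05` with deterministic tie-breaking.
Perfectly separating covariates are flagged and retained with a warning:
their p-values are meaningless, but silently dropping a perfect predictor
would be worse. Cluster membership, APACHE II and the number of organ
failures are forced by default — the final three-predictor, four-df
specification is a parsimony decision appropriate to ~18 events, not
something stepwise selection should be allowed to undo — and the
events-per-variable ratio (events / model df) is reported as an explicit
small-sample guard. Continuous covariates are z-scored before fitting so
coefficients are per-SD effect sizes; the cluster term's reference level
is the cluster with the lowest observed event rate, so the reported odds
ratios read as excess risk of the other phenotypes.

Internal validation is Harrell's optimism bootstrap on the **fixed** final
model: each iteration refits the same covariate set on a resample,
optimism is (performance on the resample) − (resample model on the
original data), and corrected = apparent − mean optimism, applied to the
c-index (midrank Mann–Whitney form, ties at half weight) and to the
g-index (Gini mean difference of the linear predictor, computed via order
statistics). Re-running screening inside the loop would capture selection
optimism too; validating the fixed model matches the declared scope
("validation of the final model") and is noted as understating total
optimism. The calibration slope is the mean over iterations of the slope
from refitting the original outcome on the resample model's original-data
linear predictor; Emax is the largest absolute gap between apparent risk
and the mean recalibration line over the observed predictions. Resamples
with a single outcome class or a non-converged fit are redrawn and
counted; more than 50 % failures aborts.

## The synthetic cohort

`simulate_cohort()` generates the cohort the pipeline is designed for and
is first-class, tested code — the recovery, stability and validation
properties in the test suite all run against it.

* **Structure.** 60 patients in three phenotypes of 13/24/23 (deterministic
  allocation at the default proportions), 130 metabolites split
  15/13/28/63/10/1 across the six families — the p180 panel's composition
  scaled to a post-QC panel size.
* **Concentrations.** Log-normal: per-metabolite baseline log-mean drawn
  from N(log 10, 1.5) (micromolar scale), plus a phenotype × family shift,
  plus a per-patient family latent factor (loading 0.5) that correlates
  metabolites within a family — independent metabolites would make the
  clustering problem unrealistically easy at high dimension — plus noise,
  with total within-phenotype SD 1 on the log scale.
* **Shift pattern.** Phenotype A: biogenic amines, sugars and sphingolipids
  high; phenotype B: glycerophospholipids and sphingolipids high;
  phenotype C: uniformly low. The default magnitude is 3 SD: the source
  analyses report clean, fully stable three-cluster solutions, and no
  quantitative effect sizes, so the default encodes a strongly separated
  cohort; the magnitude is a single knob (`default_family_shift(m)`) and
  the tests exercise the grid from 0 to 4 SD.
* **Censoring.** Each metabolite is censored below the 2 % quantile of its
  marginal draw (below-LOD), and 1 % of cells are missing completely at
  random — enough to exercise both QC rules without dominating the data.
* **Clinical covariates and outcome.** APACHE II is a rounded normal with
  phenotype means 29/25/22 (SD 6, floored at 5), SOFA 13/13/11 (SD 3,
  floored at 6, the study-style inclusion floor), organ failures
  1 + Binomial(4, p) with p = 0.6/0.5/0.35, admission cause septic with
  probability 0.54/0.71/0.65. Hospital death follows a logit with
  intercept −2.372, phenotype offsets (1.811, 1.503, 0), 0.06 per APACHE
  II point above 25 and 0.35 per organ failure above 2; these four numbers
  were solved by numeric integration over the covariate distributions so
  the phenotype-wise marginal mortality is 54 % / 38 % / 9 %. The
  integration lives in `implied_mortality()` and serves as the oracle for
  the generator's Monte-Carlo tests. Mortality depends on phenotype *and*
  covariates, so the multivariable model has a genuine adjustment problem.
* **What it does not emulate.** Batch effects, plate drift and the
  LC–MS/MS error structure; correlations between families; comorbidity
  structure. Passing recovery tests on this generator therefore show that
  the pipeline does what it claims on data with the assumed structure —
  not that real shock cohorts have that structure.

## Numerical and testing choices

Tolerances: z-score means/SDs to 1e-9 of their targets; Fisher enumeration
mass to 1e-10 of 1; probability ties at 1e-7 relative; Jaccard aggregation
identities to 1e-12. Problem sizes in the default test run are chosen for
a laptop-scale suite: DBSCAN oracle equivalence up to n = 200, bootstrap
stability at 25–100 iterations, the optimism-direction experiment at 200
seeds × 50 resamples, large-sample limits at n = 10^5, parameter recovery
at n = 5000. The acceptance script runs the full 1000-iteration stability
and validation bootstraps.

## Limitations

* UMAP coordinates are implementation- and seed-dependent; the package
  pins parameters and seed, but numeric coordinates will not transfer
  across UMAP builds, and neither will the exact geometry of any
  particular published embedding. Stability is therefore assessed by
  resampling, not by coordinate comparison.
* The Freeman–Halton enumeration is exponential in principle; it is exact
  and fast for cohort-scale tables (N of a few hundred, small r × c) but
  not intended for large tables.
* The g-index is defined here as the Gini mean difference of the linear
  predictor. Published uses of "g-index" do not always define it in-text;
  this package states its definition and applies it consistently to the
  apparent/corrected pair.
* Backward elimination after a univariate screen is kept because it is
  the field's standard small-sample workflow, with its known instabilities
  mitigated by forcing the final specification; it is not a recommendation
  of stepwise selection in general.
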