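#' Default synthetic-cohort specification
#'
#' Defines the study conditions the pipeline is designed for: 60 shock
#' patients in three metabolic phenotypes of 13, 24 and 23, a targeted panel
#' of 130 metabolites across the six p180 families, family-specific
#' log-scale concentration shifts, below-LOD censoring, and cluster-linked
#' in-hospital mortality.
#'
#' The planted phenotypes follow the qualitative pattern reported for shock
#' metabotypes: phenotype A (severe, highest mortality) has elevated
#' biogenic amines, sugars and sphingolipids; phenotype B elevated
#' glycerophospholipids and sphingolipids; phenotype C is uniformly low.
#' The default shift magnitude is 3 within-cluster SD on the log scale —
#' strong, cleanly separable phenotypes. The mortality logit (intercept
#' -2.372; phenotype offsets 1.811, 1.503, 0; 0.06 per APACHE II point above
#' 25; 0.35 per organ failure above 2) was solved by numeric integration
#' over the covariate distributions so that phenotype-wise hospital
#' mortality is 54%, 38% and 9%.
#'
#' @param n_patients Cohort size.
#' @param cluster_proportions Phenotype proportions (must sum to 1).
#' @param n_metabolites_per_family Named integer vector over
#'   [METABOLITE_FAMILIES]; the default scales the p180 panel composition
#'   down to 130 metabolites.
#' @param family_shift 3 x 6 numeric matrix (phenotype x family) of
#'   log-scale shifts in units of `within_cluster_sd`.
#' @param within_cluster_sd Total within-phenotype SD of log concentration.
#' @param family_loading Loading of the shared per-family latent factor that
#'   correlates metabolites within a family (must be < `within_cluster_sd`).
#' @param lod_quantile Fraction of each metabolite's marginal distribution
#'   censored as below-LOD.
#' @param missing_rate Fraction of cells missing completely at random.
#' @param mortality_logit List with `intercept`, `cluster_offsets` (length
#'   3), `apache2` and `n_organ_failures` coefficients (raw scale, centered
#'   at APACHE II 25 and 2 failures).
#' @param apache2_means,apache2_sd Per-phenotype APACHE II distribution
#'   (rounded normal, floored at 5).
#' @param sofa_means,sofa_sd Per-phenotype SOFA distribution (rounded
#'   normal, floored at 6 per the study inclusion criterion).
#' @param organ_failure_prob Per-phenotype success probability of the
#'   `1 + Binomial(4, p)` organ-failure count.
#' @param septic_prob Per-phenotype probability of septic (vs cardiogenic)
#'   admission.
#' @param rng_seed Integer seed.
#'
#' @return An object of class `synthetic_cohort_spec`.
#' @export
default_spec <- function(n_patients = 60,
                         cluster_proportions = c(13, 24, 23) / 60,
                         n_metabolites_per_family = c(
                           amino_acids = 15, biogenic_amines = 13,
                           acylcarnitines = 28, glycerophospholipids = 63,
                           sphingolipids = 10, sugars = 1),
                         family_shift = default_family_shift(),
                         within_cluster_sd = 1,
                         family_loading = 0.5,
                         lod_quantile = 0.02,
                         missing_rate = 0.01,
                         mortality_logit = list(
                           intercept = -2.372,
                           cluster_offsets = c(1.811, 1.503, 0),
                           apache2 = 0.06,
                           n_organ_failures = 0.35),
                         apache2_means = c(29, 25, 22), apache2_sd = 6,
                         sofa_means = c(13, 13, 11), sofa_sd = 3,
                         organ_failure_prob = c(0.6, 0.5, 0.35),
                         septic_prob = c(0.54, 0.71, 0.65),
                         rng_seed = 1L) {
  stopifnot(
    "cluster_proportions must sum to 1" =
      abs(sum(cluster_proportions) - 1) < 1e-8,
    "cluster_proportions must be positive" = all(cluster_proportions > 0),
    "need one proportion per phenotype" = length(cluster_proportions) == 3,
    "metabolite counts must be positive" =
      all(n_metabolites_per_family >= 1),
    "lod_quantile must be in [0, 1)" =
      lod_quantile >= 0 && lod_quantile < 1,
    "missing_rate must be in [0, 1)" =
      missing_rate >= 0 && missing_rate < 1,
    "family_loading must be below within_cluster_sd" =
      family_loading < within_cluster_sd
  )
  bad_fam <- setdiff(names(n_metabolites_per_family), METABOLITE_FAMILIES)
  if (length(bad_fam)) {
    stop("unknown families in n_metabolites_per_family: ",
         paste(bad_fam, collapse = ", "))
  }
  if (!is.matrix(family_shift) || nrow(family_shift) != 3 ||
      !all(colnames(family_shift) %in% METABOLITE_FAMILIES)) {
    stop("family_shift must be a 3 x family matrix with columns from: ",
         paste(METABOLITE_FAMILIES, collapse = ", "))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cluster_proportions = cluster_proportions,
    n_metabolites_per_family = n_metabolites_per_family,
    family_shift = family_shift,
    within_cluster_sd = within_cluster_sd,
    family_loading = family_loading,
    lod_quantile = lod_quantile,
    missing_rate = missing_rate,
    mortality_logit = mortality_logit,
    apache2_means = apache2_means, apache2_sd = apache2_sd,
    sofa_means = sofa_means, sofa_sd = sofa_sd,
    organ_failure_prob = organ_failure_prob,
    septic_prob = septic_prob,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_cohort_spec")
}

#' Default planted family-shift pattern
#'
#' @param magnitude Shift size in within-cluster SD units (default 3).
#' @return A 3 x 6 matrix, phenotypes A/B/C by family.
#' @export
default_family_shift <- function(magnitude = 3) {
  s <- matrix(0, 3, length(METABOLITE_FAMILIES),
              dimnames = list(c("A", "B", "C"), METABOLITE_FAMILIES))
  s["A", c("biogenic_amines", "sugars", "sphingolipids")] <- magnitude
  s["B", c("glycerophospholipids", "sphingolipids")] <- magnitude
  s
}

#' Simulate a synthetic shock cohort
#'
#' Draws a cohort under `spec`: phenotype labels from a multinomial,
#' log-normal metabolite concentrations with per-family latent factors and
#' phenotype x family mean shifts, per-metabolite below-LOD censoring at the
#' `lod_quantile` of the marginal draw, MCAR missingness, phenotype-dependent
#' clinical covariates, and in-hospital death from the specified logit
#' (APACHE II centered at 25, organ failures centered at 2). ICU death is a
#' thinned subset of hospital death. Fully reproducible given
#' `spec$rng_seed`.
#'
#' @param spec A `synthetic_cohort_spec`, e.g. from [default_spec()].
#' @return An object of class `synthetic_cohort`: a list with `tables` (a
#'   [cohort_tables()] object) and `true_labels` (named integer vector of
#'   planted phenotype ids 1..3).
#' @examples
#' cohort <- simulate_cohort(default_spec(rng_seed = 42))
#' table(cohort$true_labels)
#' @export
simulate_cohort <- function(spec = default_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_patients
  k <- length(spec$cluster_proportions)
  # deterministic rounded allocation keeps phenotype sizes at their targets
  sizes <- round_to_total(spec$cluster_proportions * n, n)
  labels <- rep(seq_len(k), sizes)
  pid <- sprintf("P%03d", seq_len(n))
  names(labels) <- pid

  counts <- spec$n_metabolites_per_family
  fam_of <- rep(names(counts), counts)
  met <- unlist(lapply(names(counts), function(f) {
    sprintf("%s_%02d", abbreviate_family(f), seq_len(counts[[f]]))
  }))
  m <- length(met)

  mu <- stats::rnorm(m, log(10), 1.5)           # per-metabolite baseline
  fams <- unique(fam_of)
  latent <- matrix(stats::rnorm(n * length(fams)), n, length(fams),
                   dimnames = list(pid, fams))
  eps_sd <- sqrt(spec$within_cluster_sd^2 - spec$family_loading^2)
  shift <- matrix(0, k, length(fams), dimnames = list(NULL, fams))
  keep <- intersect(colnames(spec$family_shift), fams)
  shift[, keep] <- spec$family_shift[, keep] * spec$within_cluster_sd

  logc <- matrix(0, n, m, dimnames = list(pid, met))
  for (j in seq_len(m)) {
    f <- fam_of[j]
    logc[, j] <- mu[j] + shift[labels, f] +
      spec$family_loading * latent[, f] + stats::rnorm(n, 0, eps_sd)
  }
  conc <- exp(logc)

  status <- matrix("measured", n, m, dimnames = list(pid, met))
  if (spec$lod_quantile > 0) {
    for (j in seq_len(m)) {
      lod <- stats::quantile(conc[, j], spec$lod_quantile, names = FALSE)
      status[conc[, j] < lod, j] <- "below_LOD"
    }
  }
  if (spec$missing_rate > 0) {
    mcar <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    status[mcar] <- "missing"
  }
  conc[status != "measured"] <- NA_real_

  apache2 <- pmax(5L, as.integer(round(
    stats::rnorm(n, spec$apache2_means[labels], spec$apache2_sd))))
  sofa <- pmax(6L, as.integer(round(
    stats::rnorm(n, spec$sofa_means[labels], spec$sofa_sd))))
  nof <- 1L + stats::rbinom(n, 4, spec$organ_failure_prob[labels])
  cause <- ifelse(stats::runif(n) < spec$septic_prob[labels],
                  "septic", "cardiogenic")
  lp <- mortality_linear_predictor(spec, labels, apache2, nof)
  hospital_death <- stats::runif(n) < stats::plogis(lp)
  icu_death <- hospital_death & stats::runif(n) < 15 / 18

  clinical <- data.frame(
    patient_id = pid, admission_cause = cause,
    apache2 = apache2, sofa = sofa, n_organ_failures = nof,
    icu_death = icu_death, hospital_death = hospital_death,
    stringsAsFactors = FALSE)

  tables <- cohort_tables(conc, status,
                          stats::setNames(fam_of, met), clinical)
  structure(list(tables = tables,
                 true_labels = labels[rownames(tables$concentrations)],
                 spec = spec),
            class = "synthetic_cohort")
}

#' Linear predictor of the planted mortality model
#'
#' Exposed so tests can compare empirical mortality with the logit-implied
#' probabilities.
#'
#' @param spec A `synthetic_cohort_spec`.
#' @param labels Integer phenotype ids.
#' @param apache2,n_organ_failures Covariate vectors on the raw scale.
#' @return Numeric linear predictor (log-odds of hospital death).
#' @export
mortality_linear_predictor <- function(spec, labels, apache2,
                                       n_organ_failures) {
  ml <- spec$mortality_logit
  ml$intercept + ml$cluster_offsets[labels] +
    ml$apache2 * (apache2 - 25) +
    ml$n_organ_failures * (n_organ_failures - 2)
}

#' Logit-implied marginal mortality per phenotype
#'
#' Numerically integrates the mortality logit over the phenotype's covariate
#' distribution (rounded-normal APACHE II floored at 5, `1 + Binomial(4, p)`
#' organ failures). Serves as the analytic reference for Monte-Carlo checks
#' of [simulate_cohort()].
#'
#' @param spec A `synthetic_cohort_spec`.
#' @param cluster Phenotype id (1..3).
#' @return Marginal probability of hospital death.
#' @export
implied_mortality <- function(spec, cluster) {
  a <- 5:80
  pa <- stats::pnorm(a + 0.5, spec$apache2_means[cluster], spec$apache2_sd) -
    stats::pnorm(a - 0.5, spec$apache2_means[cluster], spec$apache2_sd)
  pa[1] <- stats::pnorm(5.5, spec$apache2_means[cluster], spec$apache2_sd)
  pa <- pa / sum(pa)
  f <- 1:5
  pf <- stats::dbinom(0:4, 4, spec$organ_failure_prob[cluster])
  p <- outer(a, f, function(x, y) {
    stats::plogis(mortality_linear_predictor(spec, cluster, x, y))
  })
  sum(p * outer(pa, pf))
}

round_to_total <- function(x, total) {
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(rem)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

abbreviate_family <- function(f) {
  c(amino_acids = "AA", biogenic_amines = "BA", acylcarnitines = "AC",
    glycerophospholipids = "GP", sphingolipids = "SL", sugars = "SU")[[f]]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic shock cohort\n")
  cat("  planted phenotypes:",
      paste(names(table(x$true_labels)), table(x$true_labels),
            sep = "=", collapse = ", "), "\n")
  print(x$tables)
  invisible(x)
}
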