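#' Run configuration for the phenotyping pipeline
#'
#' Bundles every tunable parameter of the analysis. Defaults reproduce the
#' reference analysis settings: DBSCAN at `eps = 0.7`, `min_pts = 5` on a
#' two-dimensional UMAP embedding (15 neighbours, min_dist 0.1, Euclidean),
#' 1000 bootstrap iterations for stability and model validation, outlier
#' threshold |z| > 5, metabolite retention at <= 20% missing within any
#' patient group and detection in >= 50% of samples, and a p < 0.1 univariate
#' screen with p < 0.05 backward elimination.
#'
#' @param eps DBSCAN neighbourhood radius in embedding space (> 0).
#' @param min_pts DBSCAN core-point threshold, counting the point itself
#'   (integer >= 2).
#' @param n_boot Number of bootstrap iterations (>= 1).
#' @param z_outlier_threshold Max |z| above which a patient is flagged as a
#'   metabolomic outlier in the sensitivity analysis.
#' @param qc_missing_frac Exclude a metabolite when its missing fraction
#'   exceeds this within any patient group (0 < x < 1).
#' @param qc_detect_frac Exclude a metabolite when measured (above-LOD,
#'   non-missing) in less than this fraction of all samples (0 < x <= 1).
#' @param screen_alpha Univariate screening threshold for mortality
#'   covariates.
#' @param keep_alpha Backward-elimination retention threshold.
#' @param n_neighbors,min_dist UMAP parameters, pinned explicitly because
#'   "default settings" differ across UMAP implementations.
#' @param rng_seed Integer seed controlling every stochastic step.
#'
#' @return An object of class `run_config` (a validated list).
#' @examples
#' cfg <- run_config(rng_seed = 7)
#' cfg$eps
#' @export
run_config <- function(eps = 0.7, min_pts = 5, n_boot = 1000,
                       z_outlier_threshold = 5,
                       qc_missing_frac = 0.20, qc_detect_frac = 0.50,
                       screen_alpha = 0.10, keep_alpha = 0.05,
                       n_neighbors = 15, min_dist = 0.1,
                       rng_seed = 1L) {
  stopifnot(
    "eps must be > 0" = is.numeric(eps) && eps > 0,
    "min_pts must be an integer >= 2" = min_pts >= 2,
    "n_boot must be >= 1" = n_boot >= 1,
    "qc_missing_frac must be in (0, 1)" =
      qc_missing_frac > 0 && qc_missing_frac < 1,
    "qc_detect_frac must be in (0, 1]" =
      qc_detect_frac > 0 && qc_detect_frac <= 1,
    "screen_alpha must be in (0, 1]" = screen_alpha > 0 && screen_alpha <= 1,
    "keep_alpha must be in (0, 1]" = keep_alpha > 0 && keep_alpha <= 1,
    "n_neighbors must be >= 2" = n_neighbors >= 2,
    "min_dist must be >= 0" = min_dist >= 0,
    "rng_seed must be a finite integer" = is.finite(rng_seed)
  )
  structure(list(
    eps = as.numeric(eps), min_pts = as.integer(min_pts),
    n_boot = as.integer(n_boot),
    z_outlier_threshold = as.numeric(z_outlier_threshold),
    qc_missing_frac = as.numeric(qc_missing_frac),
    qc_detect_frac = as.numeric(qc_detect_frac),
    screen_alpha = as.numeric(screen_alpha),
    keep_alpha = as.numeric(keep_alpha),
    n_neighbors = as.integer(n_neighbors), min_dist = as.numeric(min_dist),
    rng_seed = as.integer(rng_seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults. Unknown keys are an error, so typos do not silently fall back
#' to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("shockmet run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
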