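#' Jaccard index of two patient sets
#'
#' `|A ∩ B| / |A ∪ B|`; undefined (error) when both sets are empty.
#'
#' @param set_a,set_b Vectors of patient ids.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) stop("Jaccard index of two empty sets is undefined")
  length(intersect(set_a, set_b)) / u
}

#' Clusterwise Jaccard agreement between two partitions
#'
#' The clusterboot convention: restrict both partitions to the patients they
#' share, then score each reference cluster by its maximum Jaccard index
#' against any comparison cluster (noise is never a match candidate), and
#' average unweighted over reference clusters that have at least one member
#' among the common patients.
#'
#' @param labels_ref Named integer labels of the reference partition.
#' @param labels_cmp Named integer labels of the comparison partition
#'   (possibly over a subset or superset of patients).
#' @return List with `per_cluster` (named vector, `NA` for reference
#'   clusters with no common member) and `mean` (over non-`NA` clusters).
#' @export
clusterwise_jaccard <- function(labels_ref, labels_cmp) {
  common <- intersect(names(labels_ref), names(labels_cmp))
  if (!length(common)) stop("partitions share no patients")
  ref <- labels_ref[common]
  cmp <- labels_cmp[common]
  ref_ids <- sort(setdiff(unique(labels_ref), NOISE))
  if (!length(ref_ids)) stop("reference partition has no clusters")
  cmp_ids <- setdiff(unique(cmp), NOISE)
  per <- vapply(ref_ids, function(k) {
    a <- common[ref == k]
    if (!length(a)) return(NA_real_)
    if (!length(cmp_ids)) return(0)
    max(vapply(cmp_ids, function(k2) {
      jaccard_index(a, common[cmp == k2])
    }, numeric(1)))
  }, numeric(1))
  names(per) <- ref_ids
  list(per_cluster = per, mean = mean(per, na.rm = TRUE))
}

#' Bootstrap stability of the clustering
#'
#' Repeats the embedding + DBSCAN pipeline on bootstrap resamples of the
#' cohort and scores each iteration's partition against the reference
#' clustering with the clusterwise Jaccard index. Per iteration: patients
#' are sampled with replacement and collapsed to unique patients (duplicated
#' points would inflate local density and distort DBSCAN); UMAP + DBSCAN are
#' re-run with the reference eps/minPts on the corresponding rows of the
#' reference z-matrix; agreement is computed over patients common to the
#' bootstrap and original sets. Iteration seeds are `cfg$rng_seed +
#' iteration`, so the run is exactly reproducible.
#'
#' @param tables A [cohort_tables()] object.
#' @param cfg A [run_config()]; `cfg$n_boot` controls the iteration count.
#' @param reference A [run_clustering()] model for the same cohort (computed
#'   if omitted).
#' @return An object of class `stability_report`: `per_iteration_jaccard`,
#'   `per_cluster_mean_jaccard`, `mean_jaccard`, `n_boot`, `seeds`.
#' @export
bootstrap_stability <- function(tables, cfg = run_config(),
                                reference = NULL) {
  if (is.null(reference)) reference <- run_clustering(tables, cfg)
  if (n_clusters(reference$labels) == 0) {
    stop("reference clustering has no clusters; stability is undefined")
  }
  z <- reference$qc$z_matrix
  pid <- rownames(z)
  n <- length(pid)
  seeds <- cfg$rng_seed + seq_len(cfg$n_boot)
  ref_ids <- sort(setdiff(unique(reference$labels), NOISE))
  per_cluster <- matrix(NA_real_, cfg$n_boot, length(ref_ids),
                        dimnames = list(NULL, ref_ids))
  per_iter <- numeric(cfg$n_boot)
  for (b in seq_len(cfg$n_boot)) {
    set.seed(seeds[b])
    draw <- sort(unique(sample(pid, n, replace = TRUE)))
    nn <- min(cfg$n_neighbors, length(draw) - 1L)
    emb <- embed_umap(z[draw, , drop = FALSE], n_neighbors = nn,
                      min_dist = cfg$min_dist, rng_seed = seeds[b])
    lab <- dbscan_cluster(emb, eps = cfg$eps, min_pts = cfg$min_pts)
    cj <- clusterwise_jaccard(reference$labels, lab)
    per_cluster[b, names(cj$per_cluster)] <- cj$per_cluster
    per_iter[b] <- cj$mean
  }
  structure(list(
    per_iteration_jaccard = per_iter,
    per_cluster_mean_jaccard = colMeans(per_cluster, na.rm = TRUE),
    mean_jaccard = mean(per_iter),
    n_boot = cfg$n_boot, seeds = seeds
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: mean Jaccard %.3f over %d iterations\n",
              x$mean_jaccard, x$n_boot))
  cat("  per-cluster means:",
      paste(names(x$per_cluster_mean_jaccard),
            sprintf("%.3f", x$per_cluster_mean_jaccard),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Flag patients with extreme metabolomic profiles
#'
#' A patient is an outlier when the maximum |z| over all metabolites exceeds
#' `threshold` (computed on the log-transformed, standardized matrix).
#' Returns the offending metabolite and value for each flagged patient,
#' sorted by decreasing extremity.
#'
#' @param z_matrix Standardized patient x metabolite matrix.
#' @param threshold Outlier cut-off on |z| (the conventional screen is 5).
#' @return Data frame with `patient_id`, `worst_metabolite`, `max_abs_z`.
#' @export
find_outliers <- function(z_matrix, threshold = 5) {
  stopifnot(is.matrix(z_matrix))
  absz <- abs(z_matrix)
  max_z <- apply(absz, 1, max)
  worst <- colnames(z_matrix)[apply(absz, 1, which.max)]
  hit <- which(max_z > threshold)
  out <- data.frame(patient_id = rownames(z_matrix)[hit],
                    worst_metabolite = worst[hit],
                    max_abs_z = unname(max_z[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$max_abs_z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Outlier-exclusion sensitivity re-clustering
#'
#' Identifies extreme patients (max |z| > `cfg$z_outlier_threshold`),
#' excludes them, re-runs the full pipeline on the reduced cohort with the
#' same parameters, and cross-tabulates original versus reduced cluster
#' assignments over the retained patients (the table behind an alluvial
#' plot). Noise (0) is a valid row/column.
#'
#' @param tables A [cohort_tables()] object.
#' @param cfg A [run_config()].
#' @param reference Optional precomputed reference [run_clustering()] model.
#' @return An object of class `sensitivity_report`: `outliers` (data frame),
#'   `labels_original`, `labels_reduced`, `flow_table`.
#' @export
sensitivity_recluster <- function(tables, cfg = run_config(),
                                  reference = NULL) {
  if (is.null(reference)) reference <- run_clustering(tables, cfg)
  outliers <- find_outliers(reference$qc$z_matrix,
                            cfg$z_outlier_threshold)
  keep <- setdiff(rownames(tables$concentrations), outliers$patient_id)
  if (length(keep) < cfg$min_pts + 1) {
    stop("only ", length(keep), " patients remain after outlier ",
         "exclusion; need at least min_pts + 1 = ", cfg$min_pts + 1)
  }
  reduced_tables <- subset_cohort(tables, keep)
  reduced <- run_clustering(reduced_tables, cfg)
  lab_orig <- reference$labels[keep]
  lab_red <- reduced$labels[keep]
  flow <- table(original = lab_orig, reduced = lab_red)
  structure(list(outliers = outliers,
                 labels_original = reference$labels,
                 labels_reduced = reduced$labels,
                 flow_table = flow,
                 reduced_model = reduced),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report: %d outlier(s) excluded\n",
              nrow(x$outliers)))
  if (nrow(x$outliers)) print(x$outliers)
  cat("assignment flow (original x reduced):\n")
  print(x$flow_table)
  invisible(x)
}

#' Subset a cohort to a set of patients
#'
#' @param tables A [cohort_tables()] object.
#' @param patient_ids Patients to keep.
#' @return A `cohort_tables` object over the subset.
#' @export
subset_cohort <- function(tables, patient_ids) {
  stopifnot(inherits(tables, "cohort_tables"))
  missing <- setdiff(patient_ids, rownames(tables$concentrations))
  if (length(missing)) {
    stop("unknown patients: ", paste(missing, collapse = ", "))
  }
  cohort_tables(
    tables$concentrations[patient_ids, , drop = FALSE],
    tables$status[patient_ids, , drop = FALSE],
    tables$annotations,
    tables$clinical[tables$clinical$patient_id %in% patient_ids, ,
                    drop = FALSE])
}
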