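#' Two-dimensional UMAP embedding
#'
#' Embeds the standardized metabolite matrix into two dimensions with UMAP
#' (via uwot), using explicitly pinned parameters — 15 neighbours, min_dist
#' 0.1, Euclidean metric — because "default settings" differ between UMAP
#' implementations. Rows are canonicalized by sorting on rowname before
#' embedding, so the result does not depend on input row order; the
#' embedding is deterministic given `rng_seed` (single-threaded).
#'
#' @param z_matrix Numeric matrix (patients x metabolites) with patient ids
#'   as rownames.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param rng_seed Integer seed.
#' @return n x 2 coordinate matrix, rownames = sorted patient ids.
#' @export
embed_umap <- function(z_matrix, n_neighbors = 15, min_dist = 0.1,
                       rng_seed = 1L) {
  stopifnot(is.matrix(z_matrix), !is.null(rownames(z_matrix)))
  n <- nrow(z_matrix)
  if (n <= n_neighbors) {
    stop("UMAP needs more patients (", n, ") than n_neighbors (",
         n_neighbors, "); use n_neighbors <= ", n - 1)
  }
  z_matrix <- z_matrix[order(rownames(z_matrix)), , drop = FALSE]
  set.seed(rng_seed)
  emb <- uwot::umap(z_matrix, n_components = 2, n_neighbors = n_neighbors,
                    min_dist = min_dist, metric = "euclidean",
                    n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  dimnames(emb) <- list(rownames(z_matrix), c("UMAP1", "UMAP2"))
  emb
}

#' k-distance curve and suggested eps
#'
#' For each point, the Euclidean distance to its k-th nearest neighbour
#' (excluding itself), sorted ascending — the curve practitioners inspect to
#' pick the DBSCAN eps. A knee is suggested automatically as the point of
#' the sorted curve furthest from the chord joining its endpoints
#' (kneedle-style); the suggestion is advisory and the configured eps always
#' takes precedence.
#'
#' @param embedding Numeric coordinate matrix.
#' @param k Neighbour rank (the usual choice is `min_pts - 1`).
#' @return List with `k_distances` (sorted ascending) and `eps_suggested`.
#' @export
k_distance <- function(embedding, k) {
  stopifnot(is.matrix(embedding))
  n <- nrow(embedding)
  if (k <= 0) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of points")
  d <- as.matrix(stats::dist(embedding))
  # distance to k-th neighbour excluding self
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
  kd <- sort(kd)
  list(k_distances = kd, eps_suggested = knee_point(kd))
}

# max perpendicular distance from the sorted curve to its end-to-end chord
knee_point <- function(y) {
  n <- length(y)
  if (n < 3) return(y[n])
  x <- seq_len(n)
  dx <- n - 1
  dy <- y[n] - y[1]
  norm <- sqrt(dx^2 + dy^2)
  dist <- abs(dy * (x - 1) - dx * (y - y[1])) / norm
  y[which.max(dist)]
}

#' DBSCAN density clustering
#'
#' Standard DBSCAN semantics: a point is a core point iff at least `min_pts`
#' points (itself included) lie within `eps`; clusters are the connected
#' components of core points under the eps-neighbourhood relation, plus
#' their border points; everything else is labelled [NOISE] (0). Border
#' points within eps of core points from several clusters are assigned to
#' the cluster of their nearest core point (ties by smaller point index), a
#' deterministic rule that removes the visit-order dependence of textbook
#' DBSCAN. Cluster ids are renumbered 1..K by decreasing size, ties broken
#' by the smallest contained point name.
#'
#' @param embedding Numeric coordinate matrix (rownames = patient ids).
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Core threshold including the point itself (>= 2).
#' @return Named integer vector of cluster labels (0 = noise).
#' @export
dbscan_cluster <- function(embedding, eps, min_pts) {
  stopifnot(is.matrix(embedding), eps > 0, min_pts >= 2)
  n <- nrow(embedding)
  ids <- rownames(embedding)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- as.matrix(stats::dist(embedding))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(nb, length, integer(1)) >= min_pts

  labels <- rep(0L, n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (q in nb[[p]]) {
        if (is_core[q] && labels[q] == 0L) {
          labels[q] <- comp
          queue <- c(queue, q)
        }
      }
    }
  }
  for (i in which(!is_core)) {
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (length(cores)) {
      labels[i] <- labels[cores[which.min(d[i, cores])]]
    }
  }
  stats::setNames(relabel_by_size(labels, ids), ids)
}

# renumber 1..K by decreasing size; ties by smallest member name; 0 = noise
relabel_by_size <- function(labels, ids) {
  ks <- setdiff(unique(labels), 0L)
  if (!length(ks)) return(labels)
  size <- vapply(ks, function(k) sum(labels == k), integer(1))
  first <- vapply(ks, function(k) min(ids[labels == k]), character(1))
  ord <- ks[order(-size, first)]
  out <- labels
  for (j in seq_along(ord)) out[labels == ord[j]] <- j
  out
}

#' Run the full clustering stage
#'
#' Composes QC filtering, imputation/log transform, z-scoring, UMAP
#' embedding and DBSCAN into one provenance-carrying model: the k-distance
#' curve (k = min_pts - 1) and its suggested eps are recorded, but the
#' configured `cfg$eps` is the one applied, reproducing the practice of
#' reading eps off the k-distance plot and fixing it.
#'
#' @param tables A [cohort_tables()] object.
#' @param cfg A [run_config()].
#' @param qc Optional precomputed [qc_filter()] result (avoids re-running
#'   QC when the caller already has it).
#' @return An object of class `cluster_model`: embedding, labels (named, 0 =
#'   noise), eps/min_pts used, `k_distance_curve`, `eps_suggested`, the QC
#'   result and the seed.
#' @examples
#' cohort <- simulate_cohort(default_spec(rng_seed = 3))
#' model <- run_clustering(cohort$tables, run_config(rng_seed = 3))
#' table(model$labels)
#' @export
run_clustering <- function(tables, cfg = run_config(), qc = NULL) {
  stopifnot(inherits(tables, "cohort_tables"))
  if (is.null(qc)) qc <- qc_filter(tables, cfg = cfg)
  if (!length(qc$retained)) stop("no metabolites survived QC")
  emb <- embed_umap(qc$z_matrix, n_neighbors = cfg$n_neighbors,
                    min_dist = cfg$min_dist, rng_seed = cfg$rng_seed)
  kd <- k_distance(emb, k = cfg$min_pts - 1L)
  labels <- dbscan_cluster(emb, eps = cfg$eps, min_pts = cfg$min_pts)
  structure(list(embedding = emb, labels = labels,
                 eps = cfg$eps, min_pts = cfg$min_pts,
                 k_distance_curve = kd$k_distances,
                 eps_suggested = kd$eps_suggested,
                 qc = qc, cfg = cfg, rng_seed = cfg$rng_seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  k <- n_clusters(x$labels)
  cat(sprintf("cluster_model: %d clusters, %d noise points (eps = %g, ",
              k, sum(x$labels == NOISE), x$eps),
      sprintf("minPts = %d)\n", x$min_pts), sep = "")
  print(table(cluster = x$labels))
  cat(sprintf("  k-distance suggested eps: %.3f\n", x$eps_suggested))
  invisible(x)
}

#' Number of clusters in a label vector
#' @param labels Integer labels with 0 = noise.
#' @return Integer count of proper clusters.
#' @export
n_clusters <- function(labels) length(setdiff(unique(labels), NOISE))
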