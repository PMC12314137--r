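#' Metabolite retention filter
#'
#' Applies the two panel-QC rules: a metabolite is excluded when (1) its
#' fraction of missing cells exceeds `cfg$qc_missing_frac` within any patient
#' group, or (2) it is measured (above LOD, not missing) in fewer than
#' `cfg$qc_detect_frac` of all samples. Below-LOD and missing are distinct
#' statuses: rule (1) counts only missing cells, rule (2) counts below-LOD
#' cells as not detected. When both rules fire both reasons are recorded.
#'
#' The grouped missingness rule nominally refers to patient clusters, which
#' do not exist before clustering; by default the admission-cause strata
#' stand in as groups for the first pass (pass `groups` explicitly to re-run
#' the filter with discovered clusters).
#'
#' @param tables A [cohort_tables()] object.
#' @param groups Optional per-patient group labels (named by patient id or
#'   in table order). `NULL` treats the cohort as one group;
#'   `"admission_cause"` (the default) uses the admission-cause strata.
#' @param cfg A [run_config()].
#' @return An object of class `qc_result` with elements `retained`
#'   (character), `excluded` (data.frame `metabolite`, `reason`), `matrix`
#'   (imputed log-concentration matrix over retained metabolites) and
#'   `z_matrix` (per-metabolite z-scores of `matrix`).
#' @export
qc_filter <- function(tables, groups = "admission_cause",
                      cfg = run_config()) {
  stopifnot(inherits(tables, "cohort_tables"))
  status <- tables$status
  if (ncol(status) == 0) stop("no metabolites to filter")
  pid <- rownames(status)
  if (identical(groups, "admission_cause")) {
    groups <- stats::setNames(tables$clinical$admission_cause,
                              tables$clinical$patient_id)
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(pid)), pid)
  }
  if (!is.null(names(groups))) {
    if (!all(pid %in% names(groups))) {
      stop("groups must cover every patient; missing: ",
           paste(setdiff(pid, names(groups)), collapse = ", "))
    }
    groups <- groups[pid]
  } else if (length(groups) != length(pid)) {
    stop("unnamed groups must have one label per patient")
  }
  if (anyNA(groups)) stop("groups must not contain NA")

  mets <- colnames(status)
  miss_by_group <- rowsum((status == "missing") * 1L, groups)
  group_n <- as.vector(table(groups)[rownames(miss_by_group)])
  miss_frac <- sweep(miss_by_group, 1, group_n, "/")
  rule_missing <- apply(miss_frac > cfg$qc_missing_frac, 2, any)
  detect_frac <- colMeans(status == "measured")
  rule_detect <- detect_frac < cfg$qc_detect_frac

  excluded <- rbind(
    data.frame(metabolite = mets[rule_missing],
               reason = rep("missing_gt_20pct", sum(rule_missing)),
               stringsAsFactors = FALSE),
    data.frame(metabolite = mets[rule_detect],
               reason = rep("detect_lt_50pct", sum(rule_detect)),
               stringsAsFactors = FALSE))
  excluded <- excluded[order(excluded$metabolite, excluded$reason), ,
                       drop = FALSE]
  rownames(excluded) <- NULL
  retained <- sort(setdiff(mets, excluded$metabolite))

  mat <- z <- NULL
  if (length(retained)) {
    mat <- impute_and_transform(tables, retained)
    z <- zscore_matrix(mat)
  }
  structure(list(retained = retained, excluded = excluded,
                 matrix = mat, z_matrix = z,
                 groups = groups,
                 thresholds = c(missing = cfg$qc_missing_frac,
                                detect = cfg$qc_detect_frac)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result: %d retained, %d excluded metabolites\n",
              length(x$retained), length(unique(x$excluded$metabolite))))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Impute censored cells and log-transform
#'
#' Below-LOD cells are set to half the minimum measured value of that
#' metabolite (the standard half-minimum LOD convention for targeted
#' panels); missing cells to the median measured value; the matrix is then
#' natural-log transformed. Deterministic.
#'
#' @param tables A [cohort_tables()] object.
#' @param retained Character vector of metabolites to keep (default: all).
#' @return Numeric patient x metabolite matrix of log concentrations.
#' @export
impute_and_transform <- function(tables,
                                 retained = colnames(tables$concentrations)) {
  stopifnot(inherits(tables, "cohort_tables"), length(retained) > 0)
  missing_cols <- setdiff(retained, colnames(tables$concentrations))
  if (length(missing_cols)) {
    stop("unknown metabolites: ", paste(missing_cols, collapse = ", "))
  }
  conc <- tables$concentrations[, retained, drop = FALSE]
  status <- tables$status[, retained, drop = FALSE]
  for (j in seq_along(retained)) {
    meas <- status[, j] == "measured"
    if (!any(meas)) {
      stop("metabolite ", retained[j],
           " has no measured values; cannot impute")
    }
    vals <- conc[meas, j]
    if (any(status[, j] == "below_LOD")) {
      conc[status[, j] == "below_LOD", j] <- min(vals) / 2
    }
    if (any(status[, j] == "missing")) {
      conc[status[, j] == "missing", j] <- stats::median(vals)
    }
  }
  if (any(conc <= 0)) {
    stop("non-positive concentrations after imputation; cannot log-transform")
  }
  log(conc)
}

#' Per-metabolite z-scores
#'
#' Standardizes each column to mean 0 and sample SD 1 (denominator n - 1).
#'
#' @param mat Numeric matrix (patients x metabolites).
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat), nrow(mat) >= 2)
  sds <- apply(mat, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance metabolite(s): ",
         paste(colnames(mat)[zero], collapse = ", "))
  }
  scale(mat, center = TRUE, scale = sds)[, , drop = FALSE]
}
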