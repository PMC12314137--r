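#' Kruskal-Wallis rank test across clusters
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). The
#' degenerate all-identical case returns H = 0, p = 1 rather than an error,
#' matching how constant baseline variables are reported.
#'
#' @param groups List of numeric vectors, one per cluster (each non-empty).
#' @return A `group_comparison` object: `test = "kruskal_wallis"`,
#'   `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))$statistic  # H = 2.4
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("every group must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) {
    return(structure(list(test = "kruskal_wallis", statistic = 0,
                          df = length(groups) - 1, p_value = 1),
                     class = "group_comparison"))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Patient-level metabolite-family scores
#'
#' One score per patient and family: the mean of the patient's z-scores over
#' the family's retained metabolites. The mean (rather than the sum) keeps
#' scores comparable across families of very different sizes. Families with
#' no retained metabolite are dropped with a warning.
#'
#' @param z_matrix Standardized patient x metabolite matrix.
#' @param annotations Named character vector metabolite -> family covering
#'   every column of `z_matrix`.
#' @return Patient x family numeric matrix.
#' @export
family_scores <- function(z_matrix, annotations) {
  stopifnot(is.matrix(z_matrix))
  mets <- colnames(z_matrix)
  unann <- setdiff(mets, names(annotations))
  if (length(unann)) {
    stop("metabolites without family annotation: ",
         paste(unann, collapse = ", "))
  }
  fam <- annotations[mets]
  present <- intersect(METABOLITE_FAMILIES, unique(fam))
  absent <- setdiff(intersect(METABOLITE_FAMILIES, unique(annotations)),
                    present)
  if (length(absent)) {
    warning("families with no retained metabolite dropped: ",
            paste(absent, collapse = ", "))
  }
  out <- vapply(present, function(f) {
    rowMeans(z_matrix[, fam == f, drop = FALSE])
  }, numeric(nrow(z_matrix)))
  matrix(out, nrow = nrow(z_matrix),
         dimnames = list(rownames(z_matrix), present))
}

#' Family-level profile across clusters
#'
#' Median family score per (cluster, family) plus a Kruskal-Wallis omnibus
#' p-value per family — the table behind family-level heatmaps of metabolic
#' phenotypes. Noise patients (label 0) are excluded from the comparison.
#'
#' @param z_matrix Standardized patient x metabolite matrix.
#' @param annotations Metabolite -> family map.
#' @param labels Named integer cluster labels (0 = noise).
#' @return An object of class `family_profile`: `medians` (cluster x family
#'   matrix) and `p_values` (named per family).
#' @export
family_profile <- function(z_matrix, annotations, labels) {
  scores <- family_scores(z_matrix, annotations)
  labels <- labels[rownames(scores)]
  in_cluster <- labels != NOISE
  scores <- scores[in_cluster, , drop = FALSE]
  cl <- labels[in_cluster]
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("need at least two clusters for a profile")
  med <- t(vapply(ks, function(k) {
    apply(scores[cl == k, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(scores))))
  dimnames(med) <- list(paste0("cluster_", ks), colnames(scores))
  pvals <- vapply(colnames(scores), function(f) {
    kruskal_wallis(split(scores[, f], cl))$p_value
  }, numeric(1))
  structure(list(medians = med, p_values = pvals),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat("family_profile: median family z-score by cluster\n")
  print(round(x$medians, 3))
  cat("omnibus Kruskal-Wallis p:\n")
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Baseline characteristics table by cluster
#'
#' Builds the familiar "Table 1": per cluster and overall, categorical
#' variables as `n (pct)` with percent rounded half-up to integer, and
#' continuous variables as `median (min-max)`; an omnibus p-value per
#' variable using the exact r x c Fisher test for categoricals and the
#' Kruskal-Wallis test for continuous variables. Noise patients are
#' excluded.
#'
#' @param tables A [cohort_tables()] object.
#' @param labels Named integer cluster labels.
#' @param variables Clinical columns to summarize (default: every column
#'   except `patient_id`). Logical and character/factor columns are treated
#'   as categorical.
#' @param pairwise If `TRUE`, also compute unadjusted pairwise p-values per
#'   cluster pair (Holm adjustment via `p_adjust_method`).
#' @param p_adjust_method Multiplicity adjustment for the pairwise table
#'   (default `"none"`).
#' @return An object of class `baseline_table`: `table` (data frame of
#'   rendered cells with p-values) and optionally `pairwise`.
#' @export
summarize_baseline <- function(tables, labels,
                               variables = NULL, pairwise = FALSE,
                               p_adjust_method = "none") {
  stopifnot(inherits(tables, "cohort_tables"))
  clin <- tables$clinical
  labels <- labels[clin$patient_id]
  keep <- labels != NOISE
  clin <- clin[keep, , drop = FALSE]
  cl <- labels[keep]
  ks <- sort(unique(cl))
  if (is.null(variables)) variables <- setdiff(names(clin), "patient_id")
  groups_list <- c(stats::setNames(lapply(ks, function(k) cl == k),
                                   paste0("cluster_", ks)),
                   list(total = rep(TRUE, length(cl))))

  rows <- lapply(variables, function(v) {
    x <- clin[[v]]
    categorical <- is.logical(x) || is.character(x) || is.factor(x)
    cells <- vapply(groups_list, function(sel) {
      render_cell(x[sel], categorical)
    }, character(1))
    p <- baseline_p(x, cl, categorical)
    data.frame(variable = v, t(cells), p_value = p,
               test = if (categorical) "fisher_exact" else "kruskal_wallis",
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  res <- list(table = out, clusters = ks)
  if (pairwise) {
    pw <- list()
    for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j) {
      nm <- paste0(ks[i], "_vs_", ks[j])
      sel <- cl %in% ks[c(i, j)]
      pw[[nm]] <- vapply(variables, function(v) {
        x <- clin[[v]][sel]
        baseline_p(x, cl[sel],
                   is.logical(clin[[v]]) || is.character(clin[[v]]) ||
                     is.factor(clin[[v]]))
      }, numeric(1))
    }
    pw <- as.data.frame(pw, check.names = FALSE)
    if (p_adjust_method != "none") {
      pw[] <- t(apply(pw, 1, stats::p.adjust, method = p_adjust_method))
    }
    pw <- cbind(variable = variables, pw)
    rownames(pw) <- NULL
    res$pairwise <- pw
  }
  structure(res, class = "baseline_table")
}

baseline_p <- function(x, cl, categorical) {
  if (categorical) {
    tab <- table(factor(x), factor(cl))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
    fisher_exact_rxc(unclass(tab))$p_value
  } else {
    kruskal_wallis(split(as.numeric(x), cl))$p_value
  }
}

render_cell <- function(x, categorical) {
  if (categorical) {
    if (is.logical(x)) {
      n <- sum(x)
      sprintf("%d (%d)", n, round_half_up(100 * n / length(x)))
    } else {
      # multi-level: report the modal level's count
      tab <- sort(table(x), decreasing = TRUE)
      sprintf("%s: %d (%d)", names(tab)[1], tab[1],
              round_half_up(100 * tab[1] / length(x)))
    }
  } else {
    sprintf("%s (%s-%s)", format(stats::median(x)),
            format(min(x)), format(max(x)))
  }
}

#' Round half away from zero to integer (the "7 (54)" table convention)
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_up <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' @export
print.baseline_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
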