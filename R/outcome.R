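#' Univariate screening of mortality covariates
#'
#' Fits one single-covariate logistic regression per candidate and keeps
#' those associated with the outcome at `p < alpha`. Single-df terms use the
#' Wald p-value; factors with more than two levels use the likelihood-ratio
#' p-value of the whole block. Covariates that separate the outcome
#' perfectly are flagged with a warning and retained (their Wald p is
#' meaningless, but dropping a perfect predictor at the screen would be
#' worse).
#'
#' @param clinical Data frame of candidate covariates (no outcome column).
#' @param outcome Logical or 0/1 vector with both classes present.
#' @param alpha Screening threshold (conventionally 0.1).
#' @return Data frame with `covariate`, `p_value`, `separation`, `screened_in`.
#' @export
univariate_screen <- function(clinical, outcome, alpha = 0.1) {
  outcome <- check_outcome(outcome, nrow(clinical))
  res <- lapply(names(clinical), function(v) {
    x <- clinical[[v]]
    df <- data.frame(y = outcome, x = x)
    fit <- suppressWarnings(
      stats::glm(y ~ x, family = stats::binomial(), data = df))
    sep <- detect_separation(fit)
    p <- term_p_value(fit, "x")
    data.frame(covariate = v, p_value = p, separation = sep,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$separation)) {
    warning("perfect or quasi-perfect separation for: ",
            paste(res$covariate[res$separation], collapse = ", "),
            "; retained, but p-values are unreliable")
  }
  res$screened_in <- res$p_value < alpha | res$separation
  res
}

check_outcome <- function(outcome, n) {
  outcome <- as.integer(as.logical(outcome))
  stopifnot(length(outcome) == n, !anyNA(outcome))
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both events and non-events")
  }
  outcome
}

detect_separation <- function(fit) {
  mu <- stats::fitted(fit)
  eps <- 1e-8
  all(mu[fit$y == 1] > 1 - eps) && all(mu[fit$y == 0] < eps) ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
}

# Wald p for single-df terms, LR p for multi-level factor blocks
term_p_value <- function(fit, term) {
  labels <- attr(stats::terms(fit), "term.labels")
  asgn <- attr(stats::model.matrix(fit), "assign")
  cols <- which(asgn == match(term, labels))
  if (length(cols) == 1) {
    stats::coef(summary(fit))[cols, "Pr(>|z|)"]
  } else {
    mf <- stats::model.frame(fit)
    rest <- setdiff(labels, term)
    form <- if (length(rest)) stats::reformulate(rest, "y") else y ~ 1
    reduced <- stats::glm(form, family = stats::binomial(), data = mf)
    stats::anova(reduced, fit, test = "LRT")[2, "Pr(>Chi)"]
  }
}

#' Backward elimination of mortality covariates
#'
#' Starting from the screened covariate set, repeatedly refits the logistic
#' model and drops the non-forced term with the largest p-value, until every
#' non-forced term has `p < keep_alpha`. Single-df terms are judged by their
#' Wald p; multi-level factors are dropped or kept as a block using the
#' likelihood-ratio p. Ties are broken toward the larger p then
#' lexicographic name, so the procedure is deterministic.
#'
#' @param covariates Character vector of columns of `clinical` to start
#'   from.
#' @param clinical Data frame holding the covariates.
#' @param outcome Binary outcome vector.
#' @param keep_alpha Retention threshold (conventionally 0.05).
#' @param forced Covariates never eliminated regardless of p.
#' @return Character vector: the final covariate list.
#' @export
backward_eliminate <- function(covariates, clinical, outcome,
                               keep_alpha = 0.05, forced = character()) {
  stopifnot(length(covariates) >= 1)
  outcome <- check_outcome(outcome, nrow(clinical))
  current <- covariates
  repeat {
    candidates <- setdiff(current, forced)
    if (!length(candidates)) break
    fit <- fit_logistic(current, clinical, outcome)
    ps <- vapply(candidates, function(v) term_p_value(fit, v), numeric(1))
    ord <- order(-ps, candidates)
    worst <- candidates[ord[1]]
    if (ps[ord[1]] < keep_alpha) break
    current <- setdiff(current, worst)
    if (!length(current)) break
  }
  current
}

fit_logistic <- function(covariates, clinical, outcome) {
  df <- clinical[, covariates, drop = FALSE]
  df$y <- outcome
  stats::glm(stats::reformulate(covariates, "y"),
             family = stats::binomial(), data = df)
}

#' Fit the final mortality model
#'
#' Maximum-likelihood logistic regression of in-hospital death on the final
#' covariate set with continuous covariates standardized (z-scored) first,
#' so coefficients are comparable effect sizes. Cluster membership enters as
#' a categorical term with the configured reference level (the low-risk
#' cluster by convention). Reports per-term log-odds with Wald 95%
#' confidence intervals and the events-per-variable ratio, computed as
#' exact division of events by non-intercept model degrees of freedom.
#'
#' @param covariates Character vector of columns of `clinical`.
#' @param clinical Data frame; factor/character columns are treated as
#'   categorical, numeric columns are z-scored.
#' @param outcome Binary outcome vector.
#' @param cluster_var Name of the cluster-membership column, if present.
#' @param reference_cluster Reference level for `cluster_var` (default
#'   `"3"`, the low-mortality phenotype).
#' @return An object of class `outcome_model`: `fit` (the glm), a
#'   `coefficients` data frame (estimate, 95% CI, p), `n_events`,
#'   `model_df`, `epv`, and the standardization constants.
#' @export
fit_final_model <- function(covariates, clinical, outcome,
                            cluster_var = "cluster",
                            reference_cluster = "3") {
  outcome <- check_outcome(outcome, nrow(clinical))
  if (sum(outcome) == 0) stop("no events; cannot fit a mortality model")
  df <- clinical[, covariates, drop = FALSE]
  scaling <- list()
  for (v in covariates) {
    if (is.numeric(df[[v]])) {
      mu <- mean(df[[v]])
      s <- stats::sd(df[[v]])
      if (s == 0) stop("constant covariate: ", v)
      df[[v]] <- (df[[v]] - mu) / s
      scaling[[v]] <- c(mean = mu, sd = s)
    } else {
      df[[v]] <- factor(df[[v]])
      if (v == cluster_var && reference_cluster %in% levels(df[[v]])) {
        df[[v]] <- stats::relevel(df[[v]], ref = reference_cluster)
      }
    }
  }
  fit <- fit_logistic(covariates, df, outcome)
  if (!fit$converged) stop("logistic fit did not converge")
  sm <- stats::coef(summary(fit))
  ci <- suppressMessages(stats::confint.default(fit))
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      odds_ratio = exp(sm[, "Estimate"]),
                      p_value = sm[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  n_events <- sum(outcome)
  model_df <- length(stats::coef(fit)) - 1L
  structure(list(fit = fit, coefficients = coefs,
                 covariates = covariates, data = df, outcome = outcome,
                 n_events = n_events, model_df = model_df,
                 epv = n_events / model_df, scaling = scaling),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("outcome_model: %d events, %d df, EPV = %s\n",
              x$n_events, x$model_df, format(x$epv)))
  print(transform(x$coefficients,
                  estimate = round(estimate, 3),
                  se = round(se, 3), ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3),
                  odds_ratio = round(odds_ratio, 2),
                  p_value = signif(p_value, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Concordance index (c-statistic)
#'
#' Probability that a randomly chosen event patient has a higher predicted
#' risk than a randomly chosen non-event patient; tied predictions count
#' one half.
#'
#' @param predicted Numeric risk scores (any strictly increasing transform
#'   of risk gives the same value).
#' @param outcome Binary outcome with both classes present.
#' @return Numeric in `[0, 1]`.
#' @export
concordance_index <- function(predicted, outcome) {
  outcome <- check_outcome(outcome, length(predicted))
  n1 <- as.numeric(sum(outcome))
  n0 <- length(outcome) - n1
  # Mann-Whitney U via midranks; midranks give ties weight 1/2 exactly
  r <- rank(predicted, ties.method = "average")
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope and maximum calibration error
#'
#' Refits the outcome on the model's linear predictor by logistic maximum
#' likelihood: the slope of that refit is the calibration slope (1 on the
#' training data; < 1 signals overfitting when evaluated out of sample).
#' Emax is the largest absolute difference, over the observed predictions,
#' between apparent risk `plogis(lp)` and recalibrated risk
#' `plogis(a + b * lp)`.
#'
#' @param linear_predictor Numeric linear predictor (log-odds scale).
#' @param outcome Binary outcome.
#' @return List with `intercept`, `calibration_slope`, `emax`.
#' @export
calibration_metrics <- function(linear_predictor, outcome) {
  outcome <- check_outcome(outcome, length(linear_predictor))
  if (stats::sd(linear_predictor) == 0) {
    stop("constant linear predictor; calibration slope is undefined")
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ linear_predictor, family = stats::binomial()))
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  emax <- max(abs(stats::plogis(linear_predictor) -
                    stats::plogis(a + b * linear_predictor)))
  list(intercept = a, calibration_slope = b, emax = emax)
}

#' Gini mean difference of a linear predictor (g-index)
#'
#' Mean absolute difference over all unordered pairs of linear-predictor
#' values — a spread measure of discrimination on the log-odds scale that
#' shrinks when effects are attenuated.
#'
#' @param linear_predictor Numeric vector of length >= 2.
#' @return Non-negative numeric.
#' @export
gini_mean_difference <- function(linear_predictor) {
  n <- length(linear_predictor)
  stopifnot(n >= 2)
  x <- sort(linear_predictor)
  # sum_{i<j} (x_j - x_i) via order statistics, then / choose(n, 2)
  w <- (2 * seq_len(n) - n - 1)
  sum(w * x) / choose(n, 2)
}

#' Optimism-corrected bootstrap validation
#'
#' Harrell's optimism bootstrap for the fixed final model (the covariate set
#' is not re-selected inside the loop). Each iteration resamples patients
#' with replacement, refits the same covariate set on the resample, and
#' measures the optimism of the c-index and g-index as (performance on the
#' resample) minus (performance of the resample model on the original
#' data); corrected = apparent - mean optimism. The calibration slope is
#' the mean, over iterations, of the slope obtained by refitting the
#' original outcome on the resample model's original-data linear predictor;
#' Emax is evaluated from that mean recalibration line over the observed
#' predictions. Resamples with a single outcome class or a non-converged
#' fit are redrawn (counts reported).
#'
#' @param model An [fit_final_model()] object.
#' @param n_boot Number of bootstrap iterations.
#' @param rng_seed Integer seed; iteration seeds are `rng_seed + b`.
#' @param max_redraw_frac Abort if more than this fraction of draws fail.
#' @return An object of class `validation_metrics`: `c_apparent`,
#'   `c_corrected`, `calibration_slope`, `emax`, `g_apparent`,
#'   `g_corrected`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_validate <- function(model, n_boot = 1000, rng_seed = 1L,
                               max_redraw_frac = 0.5) {
  stopifnot(inherits(model, "outcome_model"))
  df <- model$data
  y <- model$outcome
  n <- nrow(df)
  lp_app <- unname(stats::predict(model$fit, type = "link"))
  c_app <- concordance_index(lp_app, y)
  g_app <- gini_mean_difference(lp_app)

  opt_c <- opt_g <- slope <- intercept <- numeric(n_boot)
  n_redrawn <- 0L
  max_fail <- ceiling(max_redraw_frac * n_boot)
  draw_seed <- rng_seed
  for (b in seq_len(n_boot)) {
    repeat {
      draw_seed <- draw_seed + 1L
      set.seed(draw_seed)
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (length(unique(yb)) < 2) {
        n_redrawn <- n_redrawn + 1L
      } else {
        fit_b <- tryCatch(
          suppressWarnings(fit_logistic(model$covariates,
                                        df[idx, , drop = FALSE], yb)),
          error = function(e) NULL)
        if (is.null(fit_b) || !fit_b$converged) {
          n_redrawn <- n_redrawn + 1L
        } else break
      }
      if (n_redrawn > max_fail) {
        stop("more than ", max_redraw_frac * 100,
             "% of bootstrap resamples were degenerate")
      }
    }
    lp_bb <- unname(stats::predict(fit_b, type = "link"))
    lp_bo <- unname(stats::predict(fit_b, newdata = df, type = "link"))
    opt_c[b] <- concordance_index(lp_bb, yb) - concordance_index(lp_bo, y)
    opt_g[b] <- gini_mean_difference(lp_bb) - gini_mean_difference(lp_bo)
    cal <- calibration_metrics(lp_bo, y)
    slope[b] <- cal$calibration_slope
    intercept[b] <- cal$intercept
  }
  a_bar <- mean(intercept)
  b_bar <- mean(slope)
  emax <- max(abs(stats::plogis(lp_app) -
                    stats::plogis(a_bar + b_bar * lp_app)))
  structure(list(
    c_apparent = c_app, c_corrected = c_app - mean(opt_c),
    calibration_slope = b_bar, emax = emax,
    g_apparent = g_app, g_corrected = g_app - mean(opt_g),
    n_boot = n_boot, n_redrawn = n_redrawn
  ), class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat("bootstrap internal validation\n")
  cat(sprintf("  c-index:    apparent %.3f -> corrected %.3f\n",
              x$c_apparent, x$c_corrected))
  cat(sprintf("  g-index:    apparent %.3g -> corrected %.3g\n",
              x$g_apparent, x$g_corrected))
  cat(sprintf("  calibration slope %.3f, Emax %.4f (%d iterations, %d redrawn)\n",
              x$calibration_slope, x$emax, x$n_boot, x$n_redrawn))
  invisible(x)
}

#' Fit and validate the mortality model for a clustered cohort
#'
#' Convenience wrapper tying the outcome stage together: builds the
#' covariate table (cluster membership plus the clinical covariates), runs
#' the univariate screen, backward elimination with cluster membership
#' forced, fits the standardized final model, and bootstrap-validates it.
#'
#' @param tables A [cohort_tables()] object.
#' @param labels Named cluster labels (noise patients are dropped).
#' @param cfg A [run_config()]; `screen_alpha`, `keep_alpha`, `n_boot`,
#'   `rng_seed` are used.
#' @param candidates Clinical columns to screen (default: `apache2`,
#'   `sofa`, `n_organ_failures`, `admission_cause`).
#' @param forced Covariates kept regardless of the screen and elimination.
#'   The default is the published final specification — cluster membership
#'   (2 df), APACHE II and number of organ failures — which was fixed on
#'   parsimony grounds rather than left entirely to stepwise selection.
#' @param outcome_var Outcome column (default `hospital_death`).
#' @return An object of class `outcome_model_report`: `screen`,
#'   `final_covariates`, `model` and `validation`. The reference level of
#'   the cluster term is the cluster with the lowest observed event rate.
#' @export
fit_outcome_model <- function(tables, labels, cfg = run_config(),
                              candidates = c("apache2", "sofa",
                                             "n_organ_failures",
                                             "admission_cause"),
                              forced = c("cluster", "apache2",
                                         "n_organ_failures"),
                              outcome_var = "hospital_death") {
  stopifnot(inherits(tables, "cohort_tables"))
  clin <- tables$clinical
  labels <- labels[clin$patient_id]
  keep <- labels != NOISE
  clin <- clin[keep, , drop = FALSE]
  clin$cluster <- factor(labels[keep])
  y <- clin[[outcome_var]]
  candidates <- intersect(candidates, names(clin))
  forced <- intersect(forced, c("cluster", names(clin)))
  screen <- univariate_screen(clin[, union("cluster", candidates),
                                   drop = FALSE], y, cfg$screen_alpha)
  pool <- union(forced, screen$covariate[screen$screened_in])
  final <- backward_eliminate(pool, clin, y,
                              keep_alpha = cfg$keep_alpha,
                              forced = forced)
  event_rate <- tapply(as.integer(as.logical(y)), clin$cluster, mean)
  ref <- names(event_rate)[which.min(event_rate)]
  model <- fit_final_model(final, clin, y, cluster_var = "cluster",
                           reference_cluster = ref)
  validation <- bootstrap_validate(model, n_boot = cfg$n_boot,
                                   rng_seed = cfg$rng_seed)
  structure(list(screen = screen, final_covariates = final,
                 model = model, validation = validation),
            class = "outcome_model_report")
}

#' @export
print.outcome_model_report <- function(x, ...) {
  cat("mortality model:", paste(x$final_covariates, collapse = " + "), "\n")
  print(x$model)
  print(x$validation)
  invisible(x)
}
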