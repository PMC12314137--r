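test_that("univariate screen keeps associated covariates and flags separation", {
  set.seed(40)
  n <- 200
  x_signal <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + 1.5 * x_signal)
  clin <- data.frame(signal = x_signal, noise = rnorm(n))
  sc <- univariate_screen(clin, y, alpha = 0.1)
  expect_true(sc$screened_in[sc$covariate == "signal"])
  # vacuous threshold retains everything
  sc_all <- univariate_screen(clin, y, alpha = 1)
  expect_true(all(sc_all$screened_in))
  # covariate equal to the outcome separates perfectly
  expect_warning(
    sep <- univariate_screen(data.frame(copy = as.numeric(y)), y, 0.1),
    "separation")
  expect_true(sep$separation)
  expect_true(sep$screened_in)
})

test_that("null covariates pass the screen at about the alpha rate", {
  set.seed(41)
  n_rep <- 400
  alpha <- 0.1
  kept <- vapply(seq_len(n_rep), function(i) {
    y <- rep(c(TRUE, FALSE), each = 40)
    univariate_screen(data.frame(x = rnorm(80)), y, alpha)$screened_in
  }, logical(1))
  rate <- mean(kept)
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(rate - alpha), 3 * se)
})

test_that("backward elimination drops noise first and respects forcing", {
  set.seed(42)
  n <- 300
  clin <- data.frame(strong = rnorm(n), junk = rnorm(n))
  y <- runif(n) < plogis(-0.3 + 1.2 * clin$strong)
  final <- backward_eliminate(c("strong", "junk"), clin, y, 0.05)
  expect_identical(final, "strong")
  # all terms significant: fixed point
  clin2 <- data.frame(a = rnorm(n), b = rnorm(n))
  y2 <- runif(n) < plogis(1.5 * clin2$a - 1.5 * clin2$b)
  expect_setequal(backward_eliminate(c("a", "b"), clin2, y2, 0.05),
                  c("a", "b"))
  # forcing everything keeps everything
  expect_setequal(
    backward_eliminate(c("strong", "junk"), clin, y, 0.05,
                       forced = c("strong", "junk")),
    c("strong", "junk"))
})

test_that("events-per-variable is exact division", {
  set.seed(43)
  n <- 60
  clin <- data.frame(cluster = factor(rep(1:3, c(13, 24, 23))),
                     apache2 = rnorm(n, 25, 6),
                     n_organ_failures = rpois(n, 2))
  y <- rep(FALSE, n)
  y[sample(n, 18)] <- TRUE
  m <- fit_final_model(c("cluster", "apache2", "n_organ_failures"),
                       clin, y)
  expect_identical(m$model_df, 4L)
  expect_identical(m$n_events, 18L)
  expect_identical(m$epv, 4.5)
  expect_error(fit_final_model("apache2", clin, rep(FALSE, n)), "events")
})

test_that("standardized coefficients recover the generating model", {
  # large-sample parameter recovery on a known logit
  set.seed(44)
  n <- 5000
  clin <- data.frame(cluster = factor(sample(1:3, n, replace = TRUE)),
                     apache2 = rnorm(n, 25, 6),
                     n_organ_failures = rpois(n, 2))
  beta <- c("2" = 1.1, "3" = -1.4)
  lp <- -0.8 + ifelse(clin$cluster == "2", beta[["2"]], 0) +
    ifelse(clin$cluster == "3", beta[["3"]], 0) +
    0.06 * (clin$apache2 - 25) + 0.35 * (clin$n_organ_failures - 2)
  y <- runif(n) < plogis(lp)
  m <- fit_final_model(c("cluster", "apache2", "n_organ_failures"),
                       clin, y, reference_cluster = "1")
  cf <- m$coefficients
  get <- function(term) cf[cf$term == term, ]
  # continuous terms are standardized: truth on the per-SD scale
  truth <- c(cluster2 = 1.1, cluster3 = -1.4,
             apache2 = 0.06 * stats::sd(clin$apache2),
             n_organ_failures = 0.35 * stats::sd(clin$n_organ_failures))
  for (term in names(truth)) {
    row <- get(term)
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$se)
  }
})

test_that("concordance index counts pairs with half-credit ties", {
  expect_equal(concordance_index(c(0.2, 0.6, 0.4, 0.8), c(0, 0, 1, 1)),
               0.75)
  expect_equal(concordance_index(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(concordance_index(rep(0.3, 10),
                                 c(rep(0, 5), rep(1, 5))), 0.5)
  expect_error(concordance_index(1:4, c(1, 1, 1, 1)), "both")
  # invariance under strictly increasing transforms
  set.seed(45)
  p <- rnorm(50)
  y <- runif(50) < plogis(p)
  if (length(unique(y)) == 2) {
    expect_equal(concordance_index(exp(p), y), concordance_index(p, y))
  }
})

test_that("concordance agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(46)
  for (i in 1:10) {
    p <- round(rnorm(40), 1)  # rounding forces ties
    y <- runif(40) < plogis(p)
    if (length(unique(y)) < 2) next
    ref <- survival::concordance(y ~ p)$concordance
    expect_equal(concordance_index(p, y), ref, tolerance = 1e-12)
  }
})

test_that("calibration metrics satisfy the self-calibration identity", {
  set.seed(47)
  n <- 500
  x <- rnorm(n)
  y <- runif(n) < plogis(-0.4 + x)
  fit <- glm(y ~ x, family = binomial())
  lp <- predict(fit, type = "link")
  cal <- calibration_metrics(lp, y)
  expect_equal(cal$calibration_slope, 1, tolerance = 1e-6)
  expect_equal(cal$emax, 0, tolerance = 1e-6)
  # halving the predictor doubles the slope
  cal_half <- calibration_metrics(lp / 2, y)
  expect_equal(cal_half$calibration_slope, 2, tolerance = 1e-6)
  expect_error(calibration_metrics(rep(1, n), y), "constant")
})

test_that("anti-predictive predictors get a negative calibration slope", {
  set.seed(48)
  n <- 10000
  x <- rnorm(n)
  y <- runif(n) < plogis(2 * x)
  cal <- calibration_metrics(-2 * x, y)
  expect_lt(cal$calibration_slope, 0)
})

test_that("gini mean difference matches pairwise enumeration", {
  expect_equal(gini_mean_difference(c(3, 3, 3)), 0)
  expect_equal(gini_mean_difference(c(0, 1)), 1)
  expect_equal(gini_mean_difference(c(0, 1, 2)), 4 / 3)
  set.seed(49)
  x <- rnorm(25)
  pairs <- combn(x, 2)
  expect_equal(gini_mean_difference(x),
               mean(abs(pairs[1, ] - pairs[2, ])), tolerance = 1e-12)
  # linear scaling
  expect_equal(gini_mean_difference(-3.5 * x),
               3.5 * gini_mean_difference(x), tolerance = 1e-12)
})

test_that("bootstrap validation reports apparent metrics consistently", {
  set.seed(50)
  co <- simulate_cohort(default_spec(rng_seed = 50))
  clin <- co$tables$clinical
  clin$cluster <- factor(co$true_labels)
  m <- fit_final_model(c("cluster", "apache2", "n_organ_failures"),
                       clin, clin$hospital_death)
  v <- bootstrap_validate(m, n_boot = 40, rng_seed = 50)
  lp <- predict(m$fit, type = "link")
  expect_equal(v$c_apparent, concordance_index(lp, clin$hospital_death))
  expect_equal(v$g_apparent, gini_mean_difference(lp))
  expect_true(v$emax >= 0)
  expect_identical(v$n_boot, 40)
  # deterministic under the seed
  v2 <- bootstrap_validate(m, n_boot = 40, rng_seed = 50)
  expect_identical(v, v2)
})

test_that("confidence intervals cover the truth at the nominal rate", {
  set.seed(51)
  n_rep <- 120
  n <- 500
  beta <- 0.8
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(n)
    y <- runif(n) < plogis(-0.5 + beta * x)
    if (length(unique(y)) < 2) next
    m <- fit_final_model("x", data.frame(x = x), y)
    row <- m$coefficients[m$coefficients$term == "x", ]
    truth <- beta * stats::sd(x)
    covered[r] <- row$ci_lower <= truth && truth <= row$ci_upper
  }
  rate <- mean(covered)
  se <- sqrt(0.95 * 0.05 / n_rep)
  expect_gt(rate, 0.95 - 3 * se)
})
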