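test_that("detectability rule excludes metabolites measured in < 50%", {
  # metabolite below LOD in 6/10 patients -> measured 40% < 50%
  edits <- lapply(1:6, function(i) list(row = i, col = 1,
                                        status = "below_LOD"))
  tab <- tiny_cohort(10, 3, edits)
  qc <- qc_filter(tab, groups = NULL, run_config())
  expect_true("AA_01" %in% qc$excluded$metabolite)
  expect_equal(qc$excluded$reason[qc$excluded$metabolite == "AA_01"],
               "detect_lt_50pct")
  expect_setequal(qc$retained, c("AA_02", "AA_03"))
})

test_that("clean metabolites are always retained", {
  tab <- tiny_cohort(10, 4)
  qc <- qc_filter(tab, groups = NULL, run_config())
  expect_setequal(qc$retained, colnames(tab$concentrations))
  expect_equal(nrow(qc$excluded), 0)
})

test_that("missingness rule applies within each patient group", {
  # 2/5 missing (40% > 20%) in one group, clean in the other
  edits <- list(list(row = 1, col = 2, status = "missing"),
                list(row = 2, col = 2, status = "missing"))
  tab <- tiny_cohort(10, 3, edits)
  groups <- stats::setNames(rep(c("g1", "g2"), each = 5),
                            rownames(tab$concentrations))
  qc <- qc_filter(tab, groups = groups, run_config())
  expect_equal(qc$excluded$metabolite, "AA_02")
  expect_equal(qc$excluded$reason, "missing_gt_20pct")
  # pooled, 2/10 = 20% is not > 20%: the same cells pass without groups
  qc_pooled <- qc_filter(tab, groups = NULL, run_config())
  expect_false("AA_02" %in% qc_pooled$excluded$metabolite)
})

test_that("both exclusion reasons are recorded when both rules fire", {
  edits <- c(lapply(1:3, function(i) list(row = i, col = 1,
                                          status = "missing")),
             lapply(4:9, function(i) list(row = i, col = 1,
                                          status = "below_LOD")))
  tab <- tiny_cohort(10, 2, edits)
  qc <- qc_filter(tab, groups = NULL, run_config())
  reasons <- qc$excluded$reason[qc$excluded$metabolite == "AA_01"]
  expect_setequal(reasons, c("missing_gt_20pct", "detect_lt_50pct"))
})

test_that("exclusion is monotone in both thresholds", {
  co <- simulate_cohort(default_spec(n_patients = 30, lod_quantile = 0.1,
                                     missing_rate = 0.1, rng_seed = 8))
  n_excl <- function(miss, det) {
    length(unique(qc_filter(co$tables, groups = NULL,
                            run_config(qc_missing_frac = miss,
                                       qc_detect_frac = det)
                            )$excluded$metabolite))
  }
  for (det in c(0.3, 0.5, 0.8)) {
    expect_true(n_excl(0.10, det) >= n_excl(0.30, det))
  }
  for (miss in c(0.1, 0.2)) {
    expect_true(n_excl(miss, 0.3) <= n_excl(miss, 0.6))
  }
})

test_that("imputation follows half-minimum and median rules", {
  tab <- tiny_cohort(3, 2, list(list(row = 3, col = 1,
                                     status = "below_LOD")))
  tab$concentrations[, 1] <- c(2, 4, NA)
  m <- impute_and_transform(tab, c("AA_01", "AA_02"))
  expect_equal(unname(exp(m[, "AA_01"])), c(2, 4, 1))  # half of min(2, 4)
  # untouched column is exactly log of the original values
  expect_equal(m[, "AA_02"], log(tab$concentrations[, "AA_02"]))

  tab2 <- tiny_cohort(3, 1, list(list(row = 2, col = 1,
                                      status = "missing")))
  tab2$concentrations[, 1] <- c(1, NA, 3)
  m2 <- impute_and_transform(tab2, "AA_01")
  expect_equal(unname(exp(m2[2, 1])), 2)  # median of {1, 3}
})

test_that("a metabolite with no measured values cannot be imputed", {
  edits <- lapply(1:3, function(i) list(row = i, col = 1,
                                        status = "below_LOD"))
  tab <- tiny_cohort(3, 2, edits)
  expect_error(impute_and_transform(tab, c("AA_01", "AA_02")), "AA_01")
})

test_that("z-scoring standardizes columns with sample SD and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  rownames(m) <- paste0("P", 1:3)
  z <- zscore_matrix(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, stats::sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(zscore_matrix(z), z, tolerance = 1e-12)
  m[, "b"] <- 7
  expect_error(zscore_matrix(m), "b")
})

test_that("qc_filter is invariant to row and column order", {
  edits <- list(list(row = 2, col = 2, status = "below_LOD"),
                list(row = 5, col = 3, status = "missing"))
  tab <- tiny_cohort(6, 4, edits)
  shuffled <- cohort_tables(tab$concentrations[6:1, c(3, 1, 4, 2)],
                            tab$status[6:1, c(3, 1, 4, 2)],
                            tab$annotations, tab$clinical)
  a <- qc_filter(tab, groups = NULL, run_config())
  b <- qc_filter(shuffled, groups = NULL, run_config())
  expect_identical(a$retained, b$retained)
  expect_identical(a$excluded, b$excluded)
  expect_equal(a$z_matrix, b$z_matrix)
})
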