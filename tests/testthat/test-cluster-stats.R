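test_that("Kruskal-Wallis H matches hand computation and degenerates", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 2.4)
  expect_equal(res$df, 1)
  degenerate <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5)))
  expect_equal(degenerate$statistic, 0)
  expect_equal(degenerate$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric())), "non-empty")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(30)
  for (i in 1:20) {
    g <- list(rnorm(6), rnorm(5, 1), rnorm(4))
    base <- kruskal_wallis(g)
    for (f in list(exp, function(x) x^3, function(x) 1 / (1 + exp(-x)))) {
      tr <- kruskal_wallis(lapply(g, f))
      expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
    }
  }
})

test_that("Freeman-Halton enumeration is complete and exact", {
  # 2x2 diagonal table: 3 feasible tables, observed is one of the 2 extremes
  res <- fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$prob_total, 1, tolerance = 1e-10)
  # enumeration mass sums to 1 for assorted shapes
  set.seed(31)
  for (i in 1:25) {
    r <- sample(2:3, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 3) + 1, r, cc)
    out <- fisher_exact_rxc(tab)
    expect_equal(out$prob_total, 1, tolerance = 1e-10)
    expect_gte(out$p_value, 0)
    expect_lte(out$p_value, 1)
  }
})

test_that("r x c exact test reduces to the 2x2 hypergeometric form", {
  set.seed(32)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p_value, fisher_2x2_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("exact test is invariant under row and column permutation", {
  set.seed(33)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 5) + 1, 2, 3)
    p <- fisher_exact_rxc(tab)$p_value
    expect_equal(fisher_exact_rxc(tab[2:1, ])$p_value, p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_rxc(tab[, c(3, 1, 2)])$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("exact test rejects degenerate margins", {
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  expect_error(fisher_exact_rxc(matrix(1:3, 1)), "2 x 2")
})

test_that("family scores average z-scores within families", {
  z <- matrix(c(1, -1, 0.5, 2, 0, -2), 2, 3,
              dimnames = list(c("P1", "P2"),
                              c("BA_01", "BA_02", "SU_01")))
  ann <- c(BA_01 = "biogenic_amines", BA_02 = "biogenic_amines",
           SU_01 = "sugars")
  fs <- family_scores(z, ann)
  expect_equal(fs["P1", "biogenic_amines"], mean(c(1, 0.5)))
  # singleton family: the score is that metabolite's z-score
  expect_equal(fs[, "sugars"], z[, "SU_01"])
  expect_equal(family_scores(z * 0, ann),
               matrix(0, 2, 2, dimnames = dimnames(fs)))
  expect_warning(
    family_scores(z[, 1:2, drop = FALSE],
                  c(ann[1:2], GP_01 = "glycerophospholipids")),
    "glycerophospholipids")
})

test_that("planted family shifts surface in the cluster profile", {
  skip_if_not_installed("mclust")
  # phenotype A is planted with the highest biogenic-amine levels; its
  # cluster median family score should be the largest
  hits <- 0L
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    co <- simulate_cohort(default_spec(rng_seed = 300 + s))
    qc <- qc_filter(co$tables, cfg = run_config())
    prof <- family_profile(qc$z_matrix, co$tables$annotations,
                           co$true_labels)
    med <- prof$medians[, "biogenic_amines"]
    if (which.max(med) == 1) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("baseline table renders counts as n (percent) with exact tests", {
  co <- simulate_cohort(default_spec(rng_seed = 6))
  labels <- co$true_labels
  bl <- summarize_baseline(co$tables, labels, pairwise = TRUE)
  row <- bl$table[bl$table$variable == "hospital_death", ]
  deaths <- tapply(co$tables$clinical$hospital_death, labels, sum)
  sizes <- tabulate(labels, 3)
  for (k in 1:3) {
    expect_equal(row[[paste0("cluster_", k)]],
                 sprintf("%d (%d)", deaths[k],
                         round_half_up(100 * deaths[k] / sizes[k])))
  }
  expect_true(all(bl$table$p_value >= 0 & bl$table$p_value <= 1))
  expect_equal(nrow(bl$pairwise), nrow(bl$table))
  # the printed-table convention itself: 7/13 -> "7 (54)", 2/23 -> "2 (9)"
  expect_equal(round_half_up(100 * 7 / 13), 54L)
  expect_equal(round_half_up(100 * 2 / 23), 9L)
  # constant variable is rendered with p = 1, not an error
  tab2 <- co$tables
  tab2$clinical$always_true <- TRUE
  bl2 <- summarize_baseline(tab2, labels, variables = "always_true")
  expect_equal(bl2$table$p_value, 1)
})
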