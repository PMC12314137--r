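# Small in-code fixtures and independent oracles shared across tests.

# minimal hand-built cohort: n patients, m metabolites, optional cell edits
tiny_cohort <- function(n = 4, m = 3, edits = list()) {
  pid <- sprintf("P%02d", seq_len(n))
  met <- sprintf("AA_%02d", seq_len(m))
  conc <- matrix(seq_len(n * m) + 0.5, n, m, dimnames = list(pid, met))
  status <- matrix("measured", n, m, dimnames = list(pid, met))
  for (e in edits) {
    status[e$row, e$col] <- e$status
    if (e$status != "measured") conc[e$row, e$col] <- NA
  }
  clinical <- data.frame(
    patient_id = pid,
    admission_cause = rep(c("septic", "cardiogenic"), length.out = n),
    apache2 = 20 + seq_len(n), sofa = 8 + seq_len(n) %% 4,
    n_organ_failures = 1 + seq_len(n) %% 3,
    icu_death = rep(c(FALSE, TRUE), length.out = n),
    hospital_death = rep(c(FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE)
  cohort_tables(conc, status, stats::setNames(rep("amino_acids", m), met),
                clinical)
}

# a cached default (strong-shift) synthetic cohort + clustering, reused by
# several expensive tests
strong_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(default_spec(rng_seed = 11))
      cfg <- run_config(rng_seed = 11, n_boot = 25)
      cache <<- list(cohort = co, cfg = cfg,
                     model = run_clustering(co$tables, cfg))
    }
    cache
  }
})

# Independent brute-force DBSCAN oracle: textbook region-query expansion
# over an explicit O(n^2) scan, followed by the package's declared
# nearest-core border rule. Written without reference to the implementation.
dbscan_oracle <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dmat[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  }
  region <- function(i) which(dmat[i, ] <= eps)
  core <- vapply(seq_len(n), function(i) length(region(i)) >= min_pts,
                 logical(1))
  lab <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || !core[i]) next
    cl <- cl + 1L
    seeds <- i
    while (length(seeds)) {
      s <- seeds[1]; seeds <- seeds[-1]
      if (core[s] && lab[s] == 0L) {
        lab[s] <- cl
        seeds <- union(seeds, setdiff(region(s)[core[region(s)]],
                                      which(lab != 0L)))
      }
    }
  }
  for (i in seq_len(n)) {
    if (core[i] || lab[i] != 0L) next
    cand <- intersect(region(i), which(core))
    if (length(cand)) lab[i] <- lab[cand[order(dmat[i, cand])[1]]]
  }
  lab
}

# partitions agree up to label renaming (noise label 0 fixed)
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  keep <- a != 0L
  length(unique(paste(a[keep], b[keep]))) ==
    length(unique(a[keep])) &&
    length(unique(a[keep])) == length(unique(b[keep]))
}

# independent tie-corrected Kruskal-Wallis H from the textbook formula
kw_H_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  grp <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact permutation distribution of H (all distinct group assignments)
kw_exact_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  idx <- seq_along(x)
  h_obs <- kw_H_oracle(groups)
  hs <- c()
  assign3 <- function(a) {
    rest <- setdiff(idx, a)
    if (length(sizes) == 2) {
      kw_H_oracle(list(x[a], x[rest]))
    } else {
      vapply(utils::combn(rest, sizes[2], simplify = FALSE),
             function(b) kw_H_oracle(list(x[a], x[b], x[setdiff(rest, b)])),
             numeric(1))
    }
  }
  hs <- unlist(lapply(utils::combn(idx, sizes[1], simplify = FALSE),
                      assign3))
  mean(hs >= h_obs - 1e-9)
}

# closed-form two-sided 2x2 Fisher p by direct hypergeometric enumeration
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
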