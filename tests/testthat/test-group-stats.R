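test_that("zero-variance input gives p = 1 with a degenerate-data warning", {
  expect_warning(
    res <- permutation_test(rep(2, 10), rep(2, 12), n_perm = 100, seed = 1),
    "Degenerate")
  expect_equal(res$p_perm, 1)
  expect_equal(res$t_stat, 0)
})

test_that("permutation p-values are valid under the null and powered at d=1", {
  # quick check; the full-scale calibration runs in the acceptance suite
  pvals <- vapply(1:120, function(s) {
    withr::with_seed(s, {
      a <- rnorm(30); b <- rnorm(30)
    })
    permutation_test(a, b, n_perm = 300, seed = 1000 + s)$p_perm
  }, numeric(1))
  expect_lt(mean(pvals <= 0.05), 0.12)
  expect_gt(mean(pvals <= 0.05), 0.005)

  small_p <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      a <- rnorm(50, 1); b <- rnorm(50, 0)
    })
    permutation_test(a, b, n_perm = 500, seed = 2000 + s)$p_perm
  }, numeric(1))
  expect_gte(mean(small_p < 0.01), 0.95)
})

test_that("permutation tests are reproducible and the t is order-invariant", {
  withr::with_seed(3, { a <- rnorm(20, 0.5); b <- rnorm(25) })
  r1 <- permutation_test(a, b, n_perm = 500, seed = 42)
  r2 <- permutation_test(a, b, n_perm = 500, seed = 42)
  expect_identical(r1, r2)
  perm <- withr::with_seed(4, sample(length(a)))
  r3 <- permutation_test(a[perm], b, n_perm = 500, seed = 42)
  expect_equal(r3$t_stat, r1$t_stat, tolerance = 1e-12)
  expect_equal(r3$direction, r1$direction)
})

test_that("the t statistic matches the pooled-variance textbook value", {
  withr::with_seed(9, { a <- rnorm(15, 1, 2); b <- rnorm(20) })
  r <- permutation_test(a, b, n_perm = 100, seed = 1)
  expect_equal(r$t_stat, unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("compare_global flags the planted metrics with the right direction", {
  coh <- simulate_cohort(simulation_config(seed = 21, n_patients = 10,
                                           n_controls = 10))
  auc <- global_auc_table(
    cohort_global_curves(coh, sparsity_grid(0.10, 0.34, 0.06),
                         n_rand = 3, seed = 5))
  res <- compare_global(auc, n_perm = 500, seed = 6)
  expect_setequal(res$metric,
                  c("cp", "lp", "e_loc", "e_glob", "gamma", "lambda",
                    "sigma"))
  cp <- res[res$metric == "cp", ]
  expect_true(cp$significant)
  expect_equal(cp$direction, "patient<control")
})

test_that("the two-of-three nodal rule reports consistent nodes only", {
  # synthetic AUC table: node 1 shifted in degree+efficiency (same sign),
  # node 2 shifted in degree(+) and betweenness(-), node 3 null
  n_per <- 20
  rows <- list()
  withr::with_seed(11, {
    for (g in c("patient", "control")) {
      for (s in seq_len(n_per)) {
        id <- paste0(g, s)
        for (node in 1:3) {
          for (meas in c("degree", "betweenness", "efficiency")) {
            shift <- 0
            if (g == "patient" && node == 1 &&
                meas %in% c("degree", "efficiency")) shift <- -2
            if (g == "patient" && node == 2) {
              if (meas == "degree") shift <- -2
              if (meas == "betweenness") shift <- 2
            }
            rows[[length(rows) + 1]] <- tibble::tibble(
              subject_id = id, group = g, node = node, measure = meas,
              auc = rnorm(1) + shift)
          }
        }
      }
    }
  })
  tbl <- dplyr::bind_rows(rows)
  out <- compare_nodal(tbl, n_perm = 500, seed = 3)
  expect_true(1 %in% out$node)
  expect_false(2 %in% out$node)    # direction conflict
  expect_false(3 %in% out$node)    # not significant
  expect_equal(out$direction[out$node == 1], -1)
  expect_match(out$measures[out$node == 1], "degree")
  expect_match(out$measures[out$node == 1], "efficiency")
})

test_that("partial correlation handles identities, nuisance and recovery", {
  withr::with_seed(5, {
    z <- rnorm(500)
    x <- rnorm(500)
  })
  # y = x exactly: r = 1 whatever the covariates
  r1 <- partial_correlation(x, x, cbind(z))
  expect_equal(r1$r, 1, tolerance = 1e-12)
  # y equals a covariate: partial r ~ 0
  r2 <- partial_correlation(x, z, cbind(z))
  expect_lt(abs(r2$r), 0.1)
  # true partial correlation 0.5 recovered on average (n = 100)
  rhat <- vapply(1:200, function(s) {
    withr::with_seed(300 + s, {
      z <- rnorm(100)
      e <- MASS::mvrnorm(100, c(0, 0),
                         matrix(c(1, 0.5, 0.5, 1), 2))
      x <- e[, 1] + 2 * z
      y <- e[, 2] - z
    })
    partial_correlation(x, y, cbind(z))$r
  }, numeric(1))
  expect_gt(mean(rhat), 0.45)
  expect_lt(mean(rhat), 0.55)
})

test_that("no covariates reduces exactly to the Pearson correlation test", {
  withr::with_seed(8, { x <- rnorm(40); y <- 0.4 * x + rnorm(40) })
  r <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(r$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
})

test_that("rank-deficient covariates raise a collinearity error", {
  withr::with_seed(2, { x <- rnorm(30); y <- rnorm(30); z <- rnorm(30) })
  expect_error(partial_correlation(x, y, cbind(a = z, b = 2 * z)),
               class = "wm_collinearity_error")
})

test_that("covariate adjustment leaves a clean planted effect intact", {
  withr::with_seed(6, {
    covs <- cbind(rnorm(40))
    a <- rnorm(20, 1) + 0.3 * covs[1:20]
    b <- rnorm(20) + 0.3 * covs[21:40]
  })
  rad <- permutation_test(a, b, n_perm = 500, seed = 2, covariates = covs)
  expect_lt(rad$p_perm, 0.05)
  expect_equal(rad$direction, 1)
})
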