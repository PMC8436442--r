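test_that("progression rate and class follow the clinical formula", {
  expect_equal(progression_rate(42, 10), 0.6)
  expect_equal(progression_rate(48, 7.3), 0)
  expect_equal(as.character(progression_class(0.71)), "fast")
  expect_equal(as.character(progression_class(0.68)), "slow")   # strict >
  expect_equal(as.character(progression_class(0.6)), "slow")
  expect_error(progression_rate(42, 0), class = "wm_domain_error")
  expect_error(progression_rate(49, 10), class = "wm_domain_error")
})

test_that("edge vectorisation is the exact row-major upper triangle", {
  m <- rand_sym_matrix(90, 0.5, TRUE, 3)
  v <- vectorize_edges(m)
  expect_length(v, 4005)
  expect_equal(devectorize_edges(v, 90), m)
  expect_equal(v[1], m[1, 2])                  # first edge is (1, 2)
  expect_equal(v[2], m[1, 3])
  expect_equal(v[90], m[2, 3])                 # row 2 starts after 89 edges
  idx <- edge_index_table(90)
  expect_equal(nrow(idx), 4005)
  expect_equal(unlist(idx[1, c("i", "j")], use.names = FALSE), c(1L, 2L))
})

test_that("PCA keeps the smallest component set reaching the target", {
  # rank-1 data
  withr::with_seed(1, {
    u <- rnorm(20); v <- rnorm(50)
  })
  p1 <- pca_reduce(outer(u, v), 0.8)
  expect_equal(p1$k, 1L)
  expect_equal(sum(p1$explained[1]), 1, tolerance = 1e-9)
  # isotropic noise in 10 dims: about 8 components reach 80%
  ks <- vapply(1:50, function(s) {
    x <- withr::with_seed(s, matrix(rnorm(2000), 200, 10))
    pca_reduce(x, 0.8)$k
  }, integer(1))
  expect_gte(mean(ks), 7)
  expect_lte(mean(ks), 9)
  # a looser target never needs more components
  x <- withr::with_seed(9, matrix(rnorm(600), 30, 20))
  expect_lte(pca_reduce(x, 0.6)$k, pca_reduce(x, 0.8)$k)
  expect_error(pca_reduce(x, 1.2), class = "wm_config_error")
  # loadings are orthonormal and reproduce the training scores
  p <- pca_reduce(x, 0.8)
  expect_equal(crossprod(p$loadings), diag(p$k), tolerance = 1e-9)
  expect_equal(pca_transform(p, x), p$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a perfectly separable label is classified perfectly", {
  withr::with_seed(4, {
    x <- matrix(rnorm(60 * 40, sd = 0.05), 60, 40)
    x[, 7] <- rep(c(0, 5), each = 30) + rnorm(60, sd = 0.05)
  })
  y <- factor(rep(c("slow", "fast"), each = 30), levels = c("slow", "fast"))
  cv <- nested_cv_svm(x, y, outer_k = 5, inner_k = 3, seed = 2)
  expect_equal(cv$mean_balanced_accuracy, 1.0)
})

test_that("random labels give chance-level accuracy", {
  withr::with_seed(5, x <- matrix(rnorm(73 * 200), 73, 200))
  accs <- vapply(1:10, function(s) {
    y <- withr::with_seed(s, factor(sample(rep(c("slow", "fast"),
                                               c(36, 37))),
                                    levels = c("slow", "fast")))
    nested_cv_svm(x, y, seed = 100 + s)$mean_balanced_accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.3 & accs <= 0.7))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("balanced accuracy is invariant to class relabelling", {
  lv <- c("slow", "fast")
  truth <- factor(rep(c("slow", "fast"), c(30, 10)), levels = lv)
  pred <- factor(c(rep("slow", 24), rep("fast", 6),
                   rep("fast", 7), rep("slow", 3)), levels = lv)
  swap <- function(f) factor(ifelse(f == "slow", "fast", "slow"),
                             levels = lv)
  ba <- wmconnect:::balanced_accuracy
  expect_equal(ba(truth, pred), (24 / 30 + 7 / 10) / 2)
  expect_equal(ba(swap(truth), swap(pred)), ba(truth, pred))
})

test_that("test-fold labels never influence the fitted model", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40 * 30), 40, 30)
    x[1:20, 1:5] <- x[1:20, 1:5] + 1.5
  })
  y <- factor(rep(c("slow", "fast"), each = 20), levels = c("slow", "fast"))
  folds <- rep(1:5, 8)
  y_bad <- y
  corrupt <- folds == 2
  y_bad[corrupt] <- factor(ifelse(y[corrupt] == "slow", "fast", "slow"),
                           levels = c("slow", "fast"))
  cv1 <- nested_cv_svm(x, y, outer_k = 5, inner_k = 3, seed = 4,
                       folds = folds)
  cv2 <- nested_cv_svm(x, y_bad, outer_k = 5, inner_k = 3, seed = 4,
                       folds = folds)
  p1 <- cv1$predictions[cv1$predictions$fold == 2, ]
  p2 <- cv2$predictions[cv2$predictions$fold == 2, ]
  expect_identical(as.character(p1$pred), as.character(p2$pred))
  expect_identical(cv1$chosen_C[2], cv2$chosen_C[2])
})

test_that("nested CV is deterministic under a fixed seed", {
  withr::with_seed(8, x <- matrix(rnorm(50 * 60), 50, 60))
  y <- factor(rep(c("slow", "fast"), 25), levels = c("slow", "fast"))
  cv1 <- nested_cv_svm(x, y, outer_k = 5, seed = 11)
  cv2 <- nested_cv_svm(x, y, outer_k = 5, seed = 11)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_identical(cv1$chosen_C, cv2$chosen_C)
})

test_that("stratification failures are reported", {
  x <- matrix(rnorm(12 * 5), 12, 5)
  y <- factor(rep(c("slow", "fast"), c(9, 3)), levels = c("slow", "fast"))
  expect_error(nested_cv_svm(x, y, outer_k = 5, seed = 1),
               class = "wm_stratification_error")
  expect_error(nested_cv_svm(x, factor(rep("slow", 12),
                                       levels = c("slow", "fast")),
                             seed = 1),
               class = "wm_stratification_error")
})

test_that("connection importance implements the |w| x |loading| sum", {
  atlas <- node_atlas(c("A", "B", "C"))
  # 3 edges: (A,B), (A,C), (B,C); 2 components
  loadings <- matrix(c(0.5, 0, 0.2,
                       0.1, 0, -0.9), ncol = 2)
  w <- c(2, 1)
  out <- connection_importance(w, loadings, atlas, top_n_pcs = 2,
                               top_n_edges = 3)
  # edge 1: 2*0.5 + 1*0.1 = 1.1 ; edge 2: 0 ; edge 3: 2*0.2 + 1*0.9 = 1.3
  expect_equal(out$importance[out$region_i == "A" & out$region_j == "B"],
               1.1)
  expect_equal(out$importance[out$region_i == "A" & out$region_j == "C"],
               0)
  expect_equal(out$rank[out$region_i == "B" & out$region_j == "C"], 1L)
  expect_warning(
    connection_importance(w, loadings, atlas, top_n_pcs = 5),
    "components")
})

test_that("permutation p-values respect the add-one lower bound", {
  withr::with_seed(12, {
    x <- matrix(rnorm(30 * 20), 30, 20)
    x[1:15, 1] <- x[1:15, 1] + 4
  })
  y <- factor(rep(c("slow", "fast"), each = 15), levels = c("slow", "fast"))
  ps <- permutation_significance(x, y, n_perm = 19, seed = 5, outer_k = 3,
                                 inner_k = 2, C_grid = c(0.1, 1))
  expect_gte(ps$p_perm, 1 / 20)
  expect_equal(ps$p_perm, 1 / 20)   # separable signal beats every shuffle
})
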