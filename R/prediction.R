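#' Baseline progression rate and fast/slow class
#'
#' The baseline progression rate is `(48 - ALSFRS-R) / duration`, in
#' functional-scale points lost per month since symptom onset.  Patients
#' are classed `fast` when the rate strictly exceeds the cut-off
#' (default 0.68 per month) and `slow` otherwise.
#'
#' @param alsfrs_r ALSFRS-R total score(s), 0-48.
#' @param duration_months Months since symptom onset, > 0.
#' @return `progression_rate()`: numeric rate(s), units per month.
#' @examples
#' progression_rate(42, 10)           # 0.6
#' progression_class(0.71)            # fast
#' @export
progression_rate <- function(alsfrs_r, duration_months) {
  if (any(alsfrs_r < 0 | alsfrs_r > 48, na.rm = TRUE)) {
    abort("alsfrs_r must lie in [0, 48].", class = "wm_domain_error")
  }
  if (any(duration_months <= 0, na.rm = TRUE)) {
    abort("duration_months must be > 0.", class = "wm_domain_error")
  }
  (48 - alsfrs_r) / duration_months
}

#' @rdname progression_rate
#' @param rate Progression rate(s).
#' @param cutoff Rate cut-off, per month (default 0.68).
#' @return `progression_class()`: factor with levels `slow`, `fast`.
#' @export
progression_class <- function(rate, cutoff = 0.68) {
  factor(ifelse(rate > cutoff, "fast", "slow"), levels = c("slow", "fast"))
}

#' PCA reduction fitted on training data only
#'
#' Centred principal component analysis keeping the smallest number of
#' components whose cumulative explained variance reaches
#' `variance_target`.  New subjects are projected with the training mean
#' and loadings only, so no test information leaks into the transform.
#'
#' @param train_x Training matrix, subjects x features.
#' @param variance_target Cumulative explained-variance target in (0, 1\]
#'   (default 0.8).
#' @return List of class `wm_pca`: `center`, `loadings` (features x k),
#'   `scores` (training scores), `k`, `explained` (per-component variance
#'   fractions).
#' @export
pca_reduce <- function(train_x, variance_target = 0.8) {
  if (!(variance_target > 0 && variance_target <= 1)) {
    abort("variance_target must lie in (0, 1].", class = "wm_config_error")
  }
  stopifnot(nrow(train_x) >= 2)
  ctr <- colMeans(train_x)
  Xc <- sweep(train_x, 2, ctr)
  # eigendecompose the n x n Gram matrix (features >> subjects), then
  # back-project only the k retained loading vectors
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  pos <- ev > max(ev) * 1e-12
  expl <- ev[pos] / sum(ev[pos])
  k <- which(cumsum(expl) >= variance_target - 1e-12)[1]
  d <- sqrt(ev[seq_len(k)])
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  loadings <- crossprod(Xc, sweep(u, 2, d, "/"))
  structure(list(center = ctr,
                 loadings = loadings,
                 scores = sweep(u, 2, d, "*"),
                 k = k, explained = expl),
            class = "wm_pca")
}

#' @rdname pca_reduce
#' @param pca A fitted `wm_pca`.
#' @param new_x New subjects x features matrix.
#' @return `pca_transform()`: scores of the new subjects.
#' @export
pca_transform <- function(pca, new_x) {
  sweep(new_x, 2, pca$center) %*% pca$loadings
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(levels(truth), function(lv) {
    sel <- truth == lv
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == lv)
  }, numeric(1)), na.rm = TRUE)
}

stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    abort(sprintf(
      "Cannot build %d stratified folds: smallest class has %d member(s).",
      k, min(table(labels))), class = "wm_stratification_error")
  }
  folds <- integer(length(labels))
  with_seed(check_seed(seed), {
    for (lv in levels(labels)) {
      sel <- which(labels == lv)
      folds[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
  })
  folds
}

fit_svm <- function(scores, labels, C) {
  e1071::svm(x = scores, y = labels, kernel = "linear", cost = C,
             scale = FALSE)
}

svm_primal_weights <- function(model) {
  as.numeric(t(model$coefs) %*% model$SV)
}

#' Nested cross-validated linear SVM
#'
#' Outer folds estimate generalisation; inner folds, run on the outer
#' training portion only, tune the SVM cost C by balanced accuracy.  The
#' PCA reduction is refitted inside every training split (outer and
#' inner), so neither the transform nor the model ever sees test labels
#' or test data.  Fully deterministic under `seed`.
#'
#' @param x Subjects x features matrix.
#' @param labels Factor with levels `slow`, `fast` (see
#'   [progression_class()]).
#' @param outer_k,inner_k Fold counts (defaults 10 and 5, stratified).
#' @param C_grid Cost grid (default `10^(-3:3)`); ties go to the smaller
#'   C.
#' @param variance_target PCA explained-variance target.
#' @param seed Integer seed.
#' @param folds Optional externally supplied outer fold assignment
#'   (integer vector in `1:outer_k`), overriding the stratified draw.
#' @param pca_global If `TRUE`, fit one PCA on the whole sample before
#'   cross-validation instead of refitting inside each training split.
#'   This leaks unlabelled test data into the transform and is provided
#'   only for comparison with analyses that reduce dimension once
#'   up front; the leakage-safe per-fold PCA is the default.
#' @return List: `fold_accuracies`, `mean_balanced_accuracy`, `chosen_C`,
#'   `n_components` (per fold), `predictions` (tibble with `index`,
#'   `fold`, `truth`, `pred`).
#' @export
nested_cv_svm <- function(x, labels, outer_k = 10, inner_k = 5,
                          C_grid = 10^(-3:3), variance_target = 0.8,
                          seed = 1L, folds = NULL, pca_global = FALSE) {
  if (pca_global) {
    x <- pca_reduce(x, variance_target)$scores
    variance_target <- 1
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    abort("Both classes must be present.", class = "wm_stratification_error")
  }
  seed <- check_seed(seed)
  if (is.null(folds)) folds <- stratified_folds(labels, outer_k, seed)
  outer_ids <- sort(unique(folds))
  fold_acc <- numeric(length(outer_ids))
  chosen_C <- numeric(length(outer_ids))
  n_comp <- integer(length(outer_ids))
  preds <- vector("list", length(outer_ids))

  for (fi in seq_along(outer_ids)) {
    f <- outer_ids[fi]
    tr <- folds != f
    x_tr <- x[tr, , drop = FALSE]; y_tr <- labels[tr]
    if (nlevels(droplevels(y_tr)) != 2 ||
        nlevels(droplevels(labels[!tr])) != 2) {
      abort("A fold contains one class only; reduce the fold count.",
            class = "wm_stratification_error")
    }
    inner <- stratified_folds(y_tr, inner_k, seed + 1000L * fi)
    # one PCA per inner split, shared across the C grid
    inner_splits <- lapply(sort(unique(inner)), function(g) {
      itr <- inner != g
      pca <- pca_reduce(x_tr[itr, , drop = FALSE], variance_target)
      list(train_scores = pca$scores, y_train = y_tr[itr],
           test_scores = pca_transform(pca, x_tr[!itr, , drop = FALSE]),
           y_test = y_tr[!itr])
    })
    inner_acc <- vapply(C_grid, function(C) {
      mean(vapply(inner_splits, function(sp) {
        m <- fit_svm(sp$train_scores, sp$y_train, C)
        balanced_accuracy(sp$y_test, predict(m, sp$test_scores))
      }, numeric(1)))
    }, numeric(1))
    best <- C_grid[which.max(inner_acc)]   # which.max -> smallest C on ties
    pca <- pca_reduce(x_tr, variance_target)
    m <- fit_svm(pca$scores, y_tr, best)
    pr <- predict(m, pca_transform(pca, x[!tr, , drop = FALSE]))
    fold_acc[fi] <- balanced_accuracy(labels[!tr], pr)
    chosen_C[fi] <- best
    n_comp[fi] <- pca$k
    preds[[fi]] <- tibble(index = which(!tr), fold = f,
                          truth = labels[!tr], pred = pr)
  }
  list(fold_accuracies = fold_acc,
       mean_balanced_accuracy = mean(fold_acc),
       chosen_C = chosen_C,
       n_components = n_comp,
       predictions = dplyr::bind_rows(preds))
}

#' Permutation significance of the classifier
#'
#' Re-runs the *entire* nested-CV pipeline (fold construction, PCA, inner
#' C tuning) on label-shuffled data `n_perm` times and compares the
#' observed mean balanced accuracy with the null accuracies:
#' `p = (1 + #\{acc* >= acc\}) / (n_perm + 1)`.
#'
#' @inheritParams nested_cv_svm
#' @param n_perm Number of label shuffles (default 5000; scale down for
#'   exploratory runs).
#' @param acc_obs Optional precomputed observed accuracy (skips one run).
#' @return List: `p_perm`, `acc_obs`, `perm_accuracies`.
#' @export
permutation_significance <- function(x, labels, n_perm = 5000, seed = 1L,
                                     outer_k = 10, inner_k = 5,
                                     C_grid = 10^(-3:3),
                                     variance_target = 0.8,
                                     acc_obs = NULL) {
  seed <- check_seed(seed)
  if (is.null(acc_obs)) {
    acc_obs <- nested_cv_svm(x, labels, outer_k, inner_k, C_grid,
                             variance_target, seed)$mean_balanced_accuracy
  }
  labels <- droplevels(as.factor(labels))
  perm_acc <- vapply(seq_len(n_perm), function(p) {
    y <- with_seed(seed + p, sample(labels))
    nested_cv_svm(x, y, outer_k, inner_k, C_grid, variance_target,
                  seed + p)$mean_balanced_accuracy
  }, numeric(1))
  list(p_perm = (1 + sum(perm_acc >= acc_obs)) / (n_perm + 1),
       acc_obs = acc_obs,
       perm_accuracies = perm_acc)
}

#' Back-map SVM weights onto individual connections
#'
#' Selects the `top_n_pcs` principal components with the largest absolute
#' SVM weight and scores every connection by the sum over those components
#' of `|w_pc| * |loading_pc,edge|`; the `top_n_edges` highest-scoring
#' connections are returned with their region names.
#'
#' @param svm_weights Per-component SVM weight vector.
#' @param loadings Features x components loading matrix.
#' @param atlas A [node_atlas()] naming the nodes.
#' @param top_n_pcs Components to keep (default 10; clamped with a warning
#'   when fewer are available).
#' @param top_n_edges Connections to return (default 50).
#' @param signed If `TRUE`, score each connection by the absolute *signed*
#'   sum over the selected components instead of the sum of absolute
#'   products (default `FALSE`).
#' @return Tibble: `rank`, `edge`, `i`, `j`, `region_i`, `region_j`,
#'   `importance`, sorted by descending importance.
#' @export
connection_importance <- function(svm_weights, loadings, atlas,
                                  top_n_pcs = 10, top_n_edges = 50,
                                  signed = FALSE) {
  k <- length(svm_weights)
  stopifnot(ncol(loadings) == k)
  if (top_n_pcs > k) {
    warn(sprintf("Only %d components available; using all of them.", k))
    top_n_pcs <- k
  }
  sel <- order(-abs(svm_weights))[seq_len(top_n_pcs)]
  imp <- if (signed) {
    abs(loadings[, sel, drop = FALSE] %*% svm_weights[sel])
  } else {
    abs(loadings[, sel, drop = FALSE]) %*% abs(svm_weights[sel])
  }
  idx <- edge_index_table(length(atlas))
  out <- idx |>
    dplyr::mutate(importance = as.numeric(imp),
                  region_i = unclass(atlas)[.data$i],
                  region_j = unclass(atlas)[.data$j]) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$i, .data$j) |>
    head(top_n_edges) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  out
}

#' Classify patients by baseline progression rate from their connectomes
#'
#' End-to-end single-subject classifier: patients' unthresholded edge
#' vectors are reduced by PCA (80% variance), fed to a linear SVM inside a
#' nested cross-validation, optionally tested against a label-shuffle
#' null, and the final all-patient model's weights are mapped back onto
#' connections.
#'
#' @param cohort A `wm_cohort`; only patients are used.
#' @param cutoff Progression-rate cut-off (default 0.68/month).
#' @param n_perm Label shuffles for the significance test (0 skips it).
#' @param top_pcs,top_edges Back-mapping sizes (defaults 10 and 50).
#' @inheritParams nested_cv_svm
#' @return Object of class `wm_progression`: list with the nested-CV
#'   results, `p_perm` (if requested), `rates`, `labels`, `final_C`,
#'   `importance` (top-connection tibble).
#' @export
predict_progression <- function(cohort, cutoff = 0.68, outer_k = 10,
                                inner_k = 5, C_grid = 10^(-3:3),
                                variance_target = 0.8, n_perm = 0,
                                seed = 1L, top_pcs = 10, top_edges = 50) {
  seed <- check_seed(seed)
  pats <- subset_cohort(cohort,
                        cohort$metadata$subject_id[
                          cohort$metadata$group == "patient"])
  rates <- progression_rate(pats$metadata$alsfrs_r,
                            pats$metadata$duration_months)
  labels <- progression_class(rates, cutoff)
  X <- cohort_edge_matrix(pats)

  cv <- nested_cv_svm(X, labels, outer_k, inner_k, C_grid,
                      variance_target, seed)

  p_perm <- NA_real_
  perm_acc <- NULL
  if (n_perm > 0) {
    ps <- permutation_significance(X, labels, n_perm = n_perm,
                                   seed = seed + 1L, outer_k = outer_k,
                                   inner_k = inner_k, C_grid = C_grid,
                                   variance_target = variance_target,
                                   acc_obs = cv$mean_balanced_accuracy)
    p_perm <- ps$p_perm
    perm_acc <- ps$perm_accuracies
  }

  cs <- table(cv$chosen_C)
  final_C <- as.numeric(names(cs)[which.max(cs)])
  pca <- pca_reduce(X, variance_target)
  final <- fit_svm(pca$scores, labels, final_C)
  importance <- connection_importance(svm_primal_weights(final),
                                      pca$loadings, cohort$atlas,
                                      top_n_pcs = top_pcs,
                                      top_n_edges = top_edges)

  structure(list(
    fold_accuracies = cv$fold_accuracies,
    mean_balanced_accuracy = cv$mean_balanced_accuracy,
    chosen_C = cv$chosen_C,
    n_components = cv$n_components,
    predictions = dplyr::mutate(
      cv$predictions, subject_id = pats$metadata$subject_id[.data$index]),
    p_perm = p_perm,
    perm_accuracies = perm_acc,
    rates = rates,
    labels = labels,
    cutoff = cutoff,
    final_C = final_C,
    importance = importance
  ), class = "wm_progression")
}

#' @export
print.wm_progression <- function(x, ...) {
  cat("<wm_progression> linear SVM on PCA-reduced connectomes\n",
      sprintf("  %d patients (%d fast / %d slow at cutoff %.2f/month)\n",
              length(x$labels), sum(x$labels == "fast"),
              sum(x$labels == "slow"), x$cutoff),
      sprintf("  mean balanced accuracy: %.3f", x$mean_balanced_accuracy),
      if (!is.na(x$p_perm)) sprintf(" (permutation p = %.4g)", x$p_perm)
      else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn predict_progression Tidy the top-connection importance
#'   table.
#' @param x A `wm_progression`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wm_progression <- function(x, ...) x$importance

#' @describeIn predict_progression One-row model summary.
#' @exportS3Method generics::glance
glance.wm_progression <- function(x, ...) {
  tibble(
    mean_balanced_accuracy = x$mean_balanced_accuracy,
    p_perm = x$p_perm,
    n_patients = length(x$labels),
    n_fast = sum(x$labels == "fast"),
    n_slow = sum(x$labels == "slow"),
    final_C = x$final_C,
    median_components = stats::median(x$n_components)
  )
}
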