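# Vectorised permutation machinery shared by the global, nodal and NBS
# comparisons.  X: subjects x variables; is_a: logical group indicator.
# The statistic is the pooled-variance two-sample t (contrast A - B).
# Covariates, if given, are regressed out of every column first and group
# labels are then permuted on the residuals (Freedman-Lane style).
# `stat_fn`, if given, is applied to each permutation's t vector and its
# results collected (used for max-component NBS statistics).
perm_t_apply <- function(X, is_a, n_perm, seed, covariates = NULL,
                         stat_fn = NULL, block = 2000L) {
  X <- as.matrix(X)
  if (!is.null(covariates)) X <- residualize(X, covariates)
  t_obs <- two_sample_t_cols(X, is_a)
  n <- length(is_a)
  na <- sum(is_a); nb <- n - na
  tot <- colSums(X); tot2 <- colSums(X^2)
  exceed <- numeric(ncol(X))
  perm_stats <- NULL
  done <- 0L
  with_seed(check_seed(seed), {
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      P <- matrix(0, b, n)
      for (r in seq_len(b)) P[r, sample.int(n, na)] <- 1
      SA <- P %*% X            # b x p group-A sums
      QA <- P %*% (X^2)
      MA <- SA / na
      MB <- sweep(-SA, 2, tot, "+") / nb
      SSA <- QA - na * MA^2
      SSB <- sweep(-QA, 2, tot2, "+") - nb * MB^2
      SP2 <- (SSA + SSB) / (n - 2)
      TT <- (MA - MB) / sqrt(pmax(SP2, 0) * (1 / na + 1 / nb))
      TT[!is.finite(TT)] <- 0
      exceed <- exceed + colSums(abs(TT) >=
                                   matrix(abs(t_obs), b, ncol(X), byrow = TRUE))
      if (!is.null(stat_fn)) {
        ps <- apply(TT, 1L, stat_fn)
        perm_stats <- rbind(perm_stats,
                            if (is.matrix(ps)) t(ps) else matrix(ps, ncol = 1))
      }
      done <- done + b
    }
  })
  list(t_obs = unname(t_obs),
       p = unname((1 + exceed) / (n_perm + 1)),
       perm_stats = perm_stats)
}

#' Two-sample permutation test
#'
#' Nonparametric group comparison: the statistic is the pooled-variance
#' two-sample t on the observed labels, and its null distribution is built
#' by relabelling group membership.  The two-tailed p-value uses the
#' add-one estimator `p = (1 + #{|t*| >= |t|}) / (n_perm + 1)`, which never
#' returns zero.  With covariates, both groups' values are residualised on
#' the covariates before permutation (Freedman-Lane).
#'
#' @param values_a,values_b Numeric vectors (group A is reported with
#'   positive sign when its mean is larger).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param covariates Optional numeric matrix/data frame with
#'   `length(values_a) + length(values_b)` rows (A rows first).
#' @param metric_name Optional label carried into the result.
#' @return One-row tibble: `metric`, `t_stat`, `p_perm`, `n_perm`,
#'   `direction` (sign of mean(A) - mean(B)).
#' @export
permutation_test <- function(values_a, values_b, n_perm = 10000, seed = 1L,
                             covariates = NULL, metric_name = "value") {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1, n_perm >= 100)
  x <- c(values_a, values_b)
  is_a <- rep(c(TRUE, FALSE), c(length(values_a), length(values_b)))
  if (var(x) == 0) {
    warn("Degenerate data: zero variance in both groups; p = 1.")
    return(tibble(metric = metric_name, t_stat = 0, p_perm = 1,
                  n_perm = as.integer(n_perm), direction = 0))
  }
  res <- perm_t_apply(matrix(x, ncol = 1), is_a, n_perm, seed,
                      covariates = covariates)
  tibble(metric = metric_name, t_stat = res$t_obs[1], p_perm = res$p[1],
         n_perm = as.integer(n_perm), direction = sign(res$t_obs[1]))
}

#' Group comparison of global metric AUCs
#'
#' One permutation test per global metric, patient minus control contrast,
#' with no multiplicity correction across the seven metrics (raw p-values
#' are reported).
#'
#' @param auc_tbl Output of [global_auc_table()].
#' @param n_perm,seed,covariates As in [permutation_test()]; `covariates`
#'   is a data frame with `subject_id` plus numeric columns (e.g. head
#'   motion), matched to the AUC table by subject.
#' @param alpha Significance level used for the `significant` flag.
#' @return Tibble: `metric`, `t_stat`, `p_perm`, `n_perm`, `direction`
#'   (`"patient<control"` / `"patient>control"`), `significant`.
#' @export
compare_global <- function(auc_tbl, n_perm = 10000, seed = 1L,
                           covariates = NULL, alpha = 0.05) {
  wide <- tidyr::pivot_wider(auc_tbl, id_cols = c("subject_id", "group"),
                             names_from = "metric", values_from = "auc")
  metrics <- intersect(global_metric_names, names(wide))
  X <- as.matrix(wide[metrics])
  is_a <- wide$group == "patient"
  Z <- align_covariates(covariates, wide$subject_id)
  res <- perm_t_apply(X, is_a, n_perm, seed, covariates = Z)
  tibble(
    metric = metrics,
    t_stat = res$t_obs,
    p_perm = res$p,
    n_perm = as.integer(n_perm),
    direction = ifelse(res$t_obs < 0, "patient<control", "patient>control"),
    significant = res$p <= alpha
  )
}

align_covariates <- function(covariates, subject_ids) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if ("subject_id" %in% names(covariates)) {
    rows <- match(subject_ids, covariates$subject_id)
    if (any(is.na(rows))) {
      abort("Covariates missing for some subjects.",
            class = "wm_validation_error")
    }
    covariates <- covariates[rows, setdiff(names(covariates), "subject_id"),
                             drop = FALSE]
  }
  as.matrix(covariates)
}

#' Nodal group comparison with the two-of-three reporting rule
#'
#' Runs a permutation test per node and per centrality measure (degree,
#' betweenness, efficiency) on the nodal AUCs.  A node is reported only
#' when at least two of the three measures are significant at `alpha`
#' *with the same direction of change* - the conventional rule balancing
#' power against type-I risk for nodal statistics.
#'
#' @param nodal_auc_tbl Output of [nodal_auc_table()].
#' @param n_perm,seed,covariates,alpha As in [compare_global()].
#' @param p_adjust Multiplicity correction across nodes within each
#'   measure (`"none"`, the default, or any [stats::p.adjust()] method,
#'   e.g. `"fdr"`).
#' @return Tibble of findings: `node`, `direction`, `n_significant`,
#'   `measures` (comma-separated), sorted by node index.  The full
#'   node-by-measure test table is attached as attribute `"tests"`.
#' @export
compare_nodal <- function(nodal_auc_tbl, n_perm = 10000, seed = 1L,
                          covariates = NULL, alpha = 0.05,
                          p_adjust = "none") {
  wide <- nodal_auc_tbl |>
    dplyr::mutate(key = paste(.data$measure, .data$node, sep = ".")) |>
    tidyr::pivot_wider(id_cols = c("subject_id", "group"),
                       names_from = "key", values_from = "auc")
  keys <- setdiff(names(wide), c("subject_id", "group"))
  X <- as.matrix(wide[keys])
  is_a <- wide$group == "patient"
  Z <- align_covariates(covariates, wide$subject_id)
  res <- perm_t_apply(X, is_a, n_perm, seed, covariates = Z)
  parts <- strsplit(keys, ".", fixed = TRUE)
  tests <- tibble(
    measure = vapply(parts, `[[`, "", 1L),
    node = as.integer(vapply(parts, `[[`, "", 2L)),
    t_stat = res$t_obs,
    p_perm = res$p
  ) |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_perm, method = p_adjust)) |>
    dplyr::ungroup()
  findings <- tests |>
    dplyr::filter(.data$p_adj <= alpha) |>
    dplyr::group_by(.data$node, direction = sign(.data$t_stat)) |>
    dplyr::summarise(n_significant = dplyr::n(),
                     measures = paste(sort(.data$measure), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_significant >= 2) |>
    dplyr::arrange(.data$node)
  attr(findings, "tests") <- tests
  findings
}

#' Partial Pearson correlation
#'
#' Correlation between the residuals of `x` and `y` after linear
#' regression on the covariates (intercept included); the p-value is
#' two-tailed from the t distribution with `n - k - 2` degrees of freedom,
#' `k` the number of covariates.  With no covariates this reduces exactly
#' to the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors without missing values.
#' @param covariates Optional numeric matrix/data frame, full column rank.
#' @param x_name,y_name Labels for the output row.
#' @return One-row tibble: `x`, `y`, `covariates`, `r`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                x_name = "x", y_name = "y") {
  if (anyNA(x) || anyNA(y) || (!is.null(covariates) && anyNA(covariates))) {
    abort("Missing values are not allowed in partial_correlation().",
          class = "wm_validation_error")
  }
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) {
    abort("Sample size must exceed number of covariates + 2.",
          class = "wm_validation_error")
  }
  R <- residualize(cbind(x, y), covariates)
  r <- cor(R[, 1], R[, 2])
  df <- n - k - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(t), df)
  tibble(x = x_name, y = y_name,
         covariates = if (k) paste(colnames(as.data.frame(covariates)),
                                   collapse = ",") else "",
         r = r, p = p, n = as.integer(n))
}

#' Partial correlations between metric AUCs and clinical scores
#'
#' For the patient group, correlates each requested metric AUC with each
#' clinical score, controlling for age, sex and illness duration by
#' default.
#'
#' @param auc_tbl Long AUC table ([global_auc_table()] or a nodal table
#'   with a `metric` column).
#' @param metadata Cohort metadata (patients are selected by `group`).
#' @param metrics Metric names to correlate (default: all present).
#' @param scores Clinical score columns (default ALSFRS-R total, the three
#'   subscores, anxiety and depression).
#' @param covariates Metadata columns to control for.
#' @return Tibble with one [partial_correlation()] row per metric x score.
#' @export
clinical_correlations <- function(auc_tbl, metadata,
                                  metrics = NULL,
                                  scores = c("alsfrs_r", "bulbar", "motor",
                                             "respiratory", "anxiety",
                                             "depression"),
                                  covariates = c("age", "sex",
                                                 "duration_months")) {
  pats <- metadata[metadata$group == "patient", , drop = FALSE]
  wide <- tidyr::pivot_wider(auc_tbl, id_cols = "subject_id",
                             names_from = "metric", values_from = "auc")
  dat <- dplyr::inner_join(pats, wide, by = "subject_id")
  metrics <- metrics %||% setdiff(names(wide), "subject_id")
  Z <- as.matrix(dat[covariates])
  purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(scores, function(sc) {
      partial_correlation(dat[[m]], dat[[sc]], Z,
                          x_name = m, y_name = sc)
    })
  })
}
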