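#' Run the full connectome analysis pipeline
#'
#' Chains every stage on one cohort: sparsity-grid metric curves and AUCs,
#' global and nodal group comparisons, the network-based statistic,
#' partial correlations with clinical scores, and the progression-rate
#' classifier.  All stochastic stages derive their seeds from `seed`, so
#' an identical call reproduces identical numbers.  When `out_dir` is
#' given, every stage result is written (TSV for tables, JSON for
#' structured results) together with a manifest echoing the configuration,
#' its hash and the package version.
#'
#' @param cohort A `wm_cohort`; if `NULL`, one is simulated from
#'   `sim_config`.
#' @param sim_config A [simulation_config()] used when `cohort` is `NULL`.
#' @param grid The analysis [sparsity_grid()].
#' @param weighted Use FA-weighted (default) or binary thresholded
#'   networks.
#' @param n_rand Random references per network for gamma/lambda/sigma.
#' @param n_perm Permutations for the group comparisons and the NBS.
#' @param nbs_t_threshold Primary NBS edge threshold.
#' @param covariate_cols Optional metadata columns used as covariates in
#'   the group comparisons (validated before any computation).
#' @param prediction Run the progression classifier stage?
#' @param n_perm_prediction Label shuffles for the classifier null
#'   (0 skips the significance test).
#' @param prediction_args Named list of extra arguments passed to
#'   [predict_progression()] (e.g. `outer_k` for small cohorts).
#' @param seed Master seed (mandatory).
#' @param out_dir Optional output directory.
#' @return A list of class `wm_bundle` with elements `cohort`, `curves`,
#'   `global_auc`, `global_comparison`, `nodal_findings`, `nbs`,
#'   `correlations`, `prediction`, `manifest`.
#' @export
run_full_analysis <- function(cohort = NULL,
                              sim_config = simulation_config(),
                              grid = sparsity_grid(),
                              weighted = TRUE,
                              n_rand = 10,
                              n_perm = 1000,
                              nbs_t_threshold = 2.62,
                              covariate_cols = NULL,
                              prediction = TRUE,
                              n_perm_prediction = 0,
                              prediction_args = list(),
                              seed = 1L,
                              out_dir = NULL) {
  seed <- check_seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "wm_pipeline_error", parent = e)
    })
  }

  cohort <- cohort %||% stage("simulate", simulate_cohort(sim_config))
  if (!is.null(covariate_cols)) {
    missing <- setdiff(covariate_cols, names(cohort$metadata))
    if (length(missing)) {
      abort(paste0("Covariate column(s) absent from metadata: ",
                   paste(missing, collapse = ", ")),
            class = "wm_config_error")
    }
  }
  covs <- if (is.null(covariate_cols)) NULL else
    cohort$metadata[c("subject_id", covariate_cols)]

  curves <- stage("metrics",
                  cohort_global_curves(cohort, grid, weighted = weighted,
                                       n_rand = n_rand, seed = seed + 1L))
  global_auc <- stage("metrics", global_auc_table(curves))
  nodal_curves <- stage("metrics",
                        cohort_nodal_curves(cohort, grid,
                                            weighted = weighted))
  nodal_auc <- stage("metrics", nodal_auc_table(nodal_curves))

  global_cmp <- stage("compare",
                      compare_global(global_auc, n_perm = n_perm,
                                     seed = seed + 2L, covariates = covs))
  nodal_find <- stage("compare",
                      compare_nodal(nodal_auc, n_perm = n_perm,
                                    seed = seed + 3L, covariates = covs))

  nbs <- stage("nbs",
               nbs_test(cohort, nbs_config(t_threshold = nbs_t_threshold,
                                           n_perm = n_perm,
                                           seed = seed + 4L)))

  correlations <- stage("correlate",
                        clinical_correlations(global_auc, cohort$metadata))

  pred <- if (prediction) {
    stage("predict",
          do.call(predict_progression,
                  c(list(cohort, n_perm = n_perm_prediction,
                         seed = seed + 5L), prediction_args)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wmconnect")),
    seed = seed,
    grid = as.numeric(grid),
    weighted = weighted,
    n_rand = n_rand,
    n_perm = n_perm,
    nbs_t_threshold = nbs_t_threshold,
    covariate_cols = covariate_cols,
    n_subjects = n_subjects(cohort),
    config_hash = rlang::hash(list(as.numeric(grid), weighted, n_rand,
                                   n_perm, nbs_t_threshold, covariate_cols,
                                   seed))
  )

  bundle <- structure(list(cohort = cohort, curves = curves,
                           global_auc = global_auc,
                           global_comparison = global_cmp,
                           nodal_findings = nodal_find,
                           nbs = nbs, correlations = correlations,
                           prediction = pred, manifest = manifest),
                      class = "wm_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(global_auc, file.path(out_dir, "global_auc.tsv"))
    write_result_table(global_cmp,
                       file.path(out_dir, "global_comparison.tsv"))
    write_result_table(nodal_find,
                       file.path(out_dir, "nodal_findings.tsv"))
    write_result_json(list(glance = glance(nbs), edges = tidy(nbs)),
                      file.path(out_dir, "nbs.json"))
    write_result_table(correlations,
                       file.path(out_dir, "correlations.tsv"))
    if (!is.null(pred)) {
      write_result_json(list(glance = glance(pred),
                             fold_accuracies = pred$fold_accuracies,
                             top_connections = tidy(pred)),
                        file.path(out_dir, "prediction.json"))
    }
    write_result_json(manifest, file.path(out_dir, "manifest.json"))
  }
  bundle
}

#' @export
print.wm_bundle <- function(x, ...) {
  cat("<wm_bundle>\n")
  print(x$cohort)
  sig <- x$global_comparison[x$global_comparison$significant, "metric"]
  cat("  significant global metrics: ",
      if (nrow(sig)) paste(sig$metric, collapse = ", ") else "none", "\n",
      sep = "")
  cat("  nodal findings: ", nrow(x$nodal_findings), " node(s)\n", sep = "")
  print(x$nbs)
  if (!is.null(x$prediction)) print(x$prediction)
  invisible(x)
}
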