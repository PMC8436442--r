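#' NBS configuration
#'
#' @param t_threshold Primary edge threshold on the two-sample t statistic
#'   (default 2.62).
#' @param n_perm Number of label permutations (default 10000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed.
#' @param direction Contrast(s) to analyse: `"less"` (patient < control),
#'   `"greater"`, or `"both"` (each direction analysed separately, as is
#'   conventional for the NBS).
#' @param edge_universe `"min_fraction"` (default) restricts tests to edges
#'   with nonzero weight in at least `min_presence` of all subjects —
#'   t statistics on near-absent tracts are unstable; `"all_edges"` tests
#'   every pair.
#' @param min_presence Presence fraction for the default universe.
#' @return List of class `wm_nbs_config`.
#' @export
nbs_config <- function(t_threshold = 2.62, n_perm = 10000, alpha = 0.05,
                       seed = 1L,
                       direction = c("less", "greater", "both"),
                       edge_universe = c("min_fraction", "all_edges"),
                       min_presence = 0.5) {
  if (t_threshold <= 0) abort("t_threshold must be > 0.",
                              class = "wm_config_error")
  if (n_perm < 100) abort("n_perm must be >= 100.", class = "wm_config_error")
  structure(list(t_threshold = t_threshold, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = check_seed(seed),
                 direction = match.arg(direction),
                 edge_universe = match.arg(edge_universe),
                 min_presence = min_presence),
            class = "wm_nbs_config")
}

#' Edgewise two-sample t matrix
#'
#' Pooled-variance two-sample t statistic per connection (patient minus
#' control contrast), returned as a symmetric N x N matrix with zero
#' diagonal.  Edges with zero variance (e.g. absent in all subjects) get
#' t = 0.
#'
#' @param cohort A `wm_cohort`.
#' @param edge_mask Optional logical vector over the
#'   [vectorize_edges()] layout restricting the tested universe; masked
#'   edges get t = 0.
#' @return Symmetric numeric matrix of t values.
#' @export
edgewise_t <- function(cohort, edge_mask = NULL) {
  X <- cohort_edge_matrix(cohort)
  is_pat <- cohort$metadata$group == "patient"
  stopifnot(sum(is_pat) >= 2, sum(!is_pat) >= 2)
  t_vec <- numeric(ncol(X))
  cols <- if (is.null(edge_mask)) seq_len(ncol(X)) else which(edge_mask)
  t_vec[cols] <- two_sample_t_cols(X[, cols, drop = FALSE], is_pat)
  devectorize_edges(t_vec, length(cohort$atlas))
}

#' Stack a cohort's matrices into a subjects-by-edges matrix
#'
#' @param cohort A `wm_cohort`.
#' @return Numeric matrix, one row per subject (metadata order), columns in
#'   the [vectorize_edges()] layout.
#' @export
cohort_edge_matrix <- function(cohort) {
  X <- t(vapply(cohort$matrices, vectorize_edges,
                numeric(length(cohort$atlas) *
                          (length(cohort$atlas) - 1) / 2)))
  rownames(X) <- cohort$metadata$subject_id
  X
}

#' Connected components of supra-threshold edges
#'
#' Thresholds the signed t matrix in the requested direction and returns
#' the connected components of the surviving graph.  `"less"` keeps edges
#' with `t <= -t_threshold` (patient < control for a patient-minus-control
#' t matrix), `"greater"` keeps `t >= t_threshold`.
#'
#' @param t_matrix Symmetric t matrix (e.g. from [edgewise_t()]).
#' @param t_threshold Positive threshold.
#' @param sign `"less"` or `"greater"`.
#' @return List of components, each a list with `nodes` (integer vector)
#'   and `edges` (tibble `i`, `j`, `t`); empty list when no edge survives.
#' @export
supra_components <- function(t_matrix, t_threshold,
                             sign = c("less", "greater")) {
  sign <- match.arg(sign)
  n <- nrow(t_matrix)
  idx <- edge_index_table(n)
  tv <- vectorize_edges(t_matrix)
  keep <- if (sign == "less") tv <= -t_threshold else tv >= t_threshold
  if (!any(keep)) return(list())
  el <- cbind(idx$i[keep], idx$j[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_ids <- sort(unique(memb[el[, 1]]))
  lapply(comp_ids, function(cid) {
    in_comp <- memb[el[, 1]] == cid
    list(nodes = sort(unique(c(el[in_comp, ]))),
         edges = tibble(i = el[in_comp, 1], j = el[in_comp, 2],
                        t = tv[keep][in_comp]))
  })
}

max_component_edges <- function(t_vec, ij, thr, sign) {
  keep <- if (sign == "less") t_vec <= -thr else t_vec >= thr
  if (!any(keep)) return(0L)
  .max_component_edges_impl(ij[keep, 1L], ij[keep, 2L], max(ij))
}

#' Network-based statistic
#'
#' Connection-level group inference with family-wise error control:
#' edgewise two-sample t statistics are thresholded at
#' `config$t_threshold`, connected components of the surviving edges are
#' extracted, and each component's FWER-corrected p-value is the fraction
#' of label permutations whose *maximum* component size (edge count)
#' reaches the observed size, with the add-one estimator.  Raw FA weights
#' of the unthresholded matrices are tested.
#'
#' @param cohort A `wm_cohort` with both groups present.
#' @param config An [nbs_config()].
#' @return Object of class `wm_nbs`: list with `components` (tibble:
#'   `component`, `direction`, `n_nodes`, `n_edges`, `p_fwer`,
#'   `significant`, plus list-columns `nodes` and `edges`), `null_max`
#'   (matrix of per-permutation maximum component sizes, one column per
#'   direction), `t_matrix`, `config`, `atlas`.
#' @export
nbs_test <- function(cohort, config = nbs_config()) {
  stopifnot(inherits(config, "wm_nbs_config"))
  X <- cohort_edge_matrix(cohort)
  is_pat <- cohort$metadata$group == "patient"
  stopifnot(sum(is_pat) >= 2, sum(!is_pat) >= 2)
  n <- length(cohort$atlas)
  idx <- edge_index_table(n)

  mask <- if (config$edge_universe == "min_fraction") {
    colMeans(X > 0) >= config$min_presence
  } else {
    rep(TRUE, ncol(X))
  }
  Xu <- X[, mask, drop = FALSE]
  ij <- cbind(idx$i[mask], idx$j[mask])

  dirs <- if (config$direction == "both") c("less", "greater") else
    config$direction
  thr <- config$t_threshold

  stat_fn <- function(tv) {
    vapply(dirs, function(d) max_component_edges(tv, ij, thr, d),
           integer(1))
  }
  res <- perm_t_apply(Xu, is_pat, config$n_perm, config$seed,
                      stat_fn = stat_fn)
  null_max <- res$perm_stats
  colnames(null_max) <- dirs

  t_full <- numeric(ncol(X))
  t_full[mask] <- res$t_obs
  t_matrix <- devectorize_edges(t_full, n)

  comp_rows <- purrr::map_dfr(dirs, function(d) {
    comps <- supra_components(t_matrix, thr, d)
    if (!length(comps)) return(tibble())
    purrr::map_dfr(seq_along(comps), function(k) {
      comp <- comps[[k]]
      size <- nrow(comp$edges)
      p <- (1 + sum(null_max[, d] >= size)) / (config$n_perm + 1)
      tibble(component = k, direction = d,
             n_nodes = length(comp$nodes), n_edges = size,
             p_fwer = p, significant = p <= config$alpha,
             nodes = list(comp$nodes), edges = list(comp$edges))
    })
  })

  structure(list(components = comp_rows, null_max = null_max,
                 t_matrix = t_matrix, config = config,
                 atlas = cohort$atlas),
            class = "wm_nbs")
}

#' @export
print.wm_nbs <- function(x, ...) {
  cat("<wm_nbs> t-threshold ", x$config$t_threshold, ", ",
      x$config$n_perm, " permutations\n", sep = "")
  if (!nrow(x$components)) {
    cat("  no supra-threshold components\n")
  } else {
    sig <- x$components[x$components$significant, , drop = FALSE]
    cat("  ", nrow(x$components), " component(s), ",
        nrow(sig), " significant at alpha = ", x$config$alpha, "\n",
        sep = "")
    for (r in seq_len(nrow(sig))) {
      cat(sprintf("    [%s] %d nodes / %d edges, p_fwer = %.4g\n",
                  sig$direction[r], sig$n_nodes[r], sig$n_edges[r],
                  sig$p_fwer[r]))
    }
  }
  invisible(x)
}

#' @describeIn nbs_test Tidy the component edge list: one row per
#'   supra-threshold edge with region names and component-level p.
#' @param x A `wm_nbs` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.wm_nbs <- function(x, ...) {
  if (!nrow(x$components)) {
    return(tibble(component = integer(), direction = character(),
                  region_i = character(), region_j = character(),
                  t = numeric(), p_fwer = numeric()))
  }
  x$components |>
    dplyr::select("component", "direction", "p_fwer", "significant",
                  "edges") |>
    tidyr::unnest("edges") |>
    dplyr::mutate(region_i = unclass(x$atlas)[.data$i],
                  region_j = unclass(x$atlas)[.data$j]) |>
    dplyr::relocate("region_i", "region_j", .after = "j")
}

#' @describeIn nbs_test One-row summary of the NBS run.
#' @exportS3Method generics::glance
glance.wm_nbs <- function(x, ...) {
  tibble(
    n_components = nrow(x$components),
    n_significant = sum(x$components$significant %||% logical()),
    largest_component = if (nrow(x$components)) max(x$components$n_edges)
      else 0L,
    min_p_fwer = if (nrow(x$components)) min(x$components$p_fwer)
      else NA_real_,
    t_threshold = x$config$t_threshold,
    n_perm = x$config$n_perm
  )
}
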