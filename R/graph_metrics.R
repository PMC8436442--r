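#' @section Metric conventions:
#' All metrics operate on a `wm_network` produced by [apply_sparsity()].
#' For weighted networks the shortest-path distance of an edge is the
#' reciprocal of its weight (a stronger FA connection is a shorter effective
#' distance), and the weighted clustering coefficient is the Onnela
#' geometric-mean variant with weights normalised by the network maximum.
#' @name metric-conventions
#' @keywords internal
NULL

as_wm_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

dist_weights <- function(g) 1 / igraph::E(g)$weight

#' Clustering coefficient
#'
#' Binary networks: per-node triangle density `2 t_i / (k_i (k_i - 1))`,
#' zero for degree below 2.  Weighted networks: Onnela's variant, the mean
#' of cube-rooted products of max-normalised weights around each node.
#' `cp` is the mean over all nodes.
#'
#' @param net A `wm_network`.
#' @return List with `local` (per-node values) and `cp`.
#' @export
clustering_coefficient <- function(net) {
  adj <- net$adjacency
  a <- (adj > 0) + 0
  k <- rowSums(a)
  if (net$weighted && max(adj) > 0) {
    w3 <- (adj / max(adj))^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3) / 2
  } else {
    tri <- diag(a %*% a %*% a) / 2
  }
  local <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(local = local, cp = mean(local))
}

#' Path-based metrics
#'
#' All-pairs shortest paths (distance = 1/weight on kept edges) give the
#' characteristic path length `lp` (mean over *finite* ordered pairs, with
#' the number of infinite pairs reported), global efficiency `e_glob`
#' (mean of `1/d` with `1/Inf = 0` over all ordered pairs) and per-node
#' efficiency (mean of `1/d` from each node to all others).
#'
#' @param net A `wm_network`.
#' @param lp_scope `"finite_pairs"` (default) averages the path length
#'   over all finite ordered pairs; `"largest_component"` restricts the
#'   average to pairs inside the largest connected component.
#' @return List with `lp`, `e_glob`, `nodal_efficiency`,
#'   `n_infinite_pairs`.
#' @export
path_metrics <- function(net, lp_scope = c("finite_pairs",
                                           "largest_component")) {
  lp_scope <- match.arg(lp_scope)
  n <- nrow(net$adjacency)
  d0 <- 1 / net$adjacency
  d0[net$adjacency == 0] <- Inf
  diag(d0) <- 0
  d <- .fw_distances(d0)
  off <- !diag(n)
  finite <- is.finite(d) & off
  n_inf <- sum(off) - sum(finite)
  lp_pairs <- if (lp_scope == "finite_pairs") {
    finite
  } else {
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      (net$adjacency > 0) + 0, mode = "undirected"))
    big <- which.max(comp$csize)
    inlcc <- comp$membership == big
    finite & outer(inlcc, inlcc)
  }
  lp <- if (any(lp_pairs)) mean(d[lp_pairs]) else NaN
  inv <- ifelse(finite, 1 / d, 0)
  list(
    lp = lp,
    e_glob = sum(inv) / (n * (n - 1)),
    nodal_efficiency = rowSums(inv) / (n - 1),
    n_infinite_pairs = n_inf
  )
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness (Brandes algorithm via igraph)
#' with fractional credit split over equal-length shortest paths; weighted
#' networks use distance = 1/weight.
#'
#' @param net A `wm_network`.
#' @return Numeric vector, one value per node.
#' @export
betweenness_centrality <- function(net) {
  g <- as_wm_igraph(net)
  as.numeric(igraph::betweenness(g, weights = dist_weights(g),
                                 normalized = FALSE))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' neighbours (zero for degree < 2); `e_loc` is the mean over nodes.
#'
#' @param net A `wm_network`.
#' @return List with `local` (per-node) and `e_loc`.
#' @export
local_efficiency <- function(net) {
  le <- .local_efficiency_impl(net$adjacency)
  list(local = as.numeric(le), e_loc = mean(le))
}

#' Nodal centralities of a thresholded network
#'
#' @param net A `wm_network`.
#' @return Tibble with one row per node: `node`, `degree` (strength for
#'   weighted networks), `betweenness`, `efficiency`.
#' @export
nodal_metrics <- function(net) {
  pm <- path_metrics(net)
  tibble(
    node = seq_len(nrow(net$adjacency)),
    degree = rowSums(net$adjacency),
    betweenness = betweenness_centrality(net),
    efficiency = pm$nodal_efficiency
  )
}

#' Degree-preserving random reference networks
#'
#' Generates null networks by Maslov-Sneppen double-edge swaps, preserving
#' every node's binary degree exactly.  For weighted networks the topology
#' is rewired and the original multiset of edge weights is reassigned to
#' the rewired edges in random order.  Identical seeds give identical
#' references.
#'
#' @param net A `wm_network` with at least 2 edges.
#' @param n_rand Number of references (default 100).
#' @param n_swaps_per_edge Swap attempts per edge (default 10); 0 returns
#'   exact copies of the input.
#' @param seed Integer seed.
#' @return List of `wm_network` objects.
#' @export
random_reference <- function(net, n_rand = 100, n_swaps_per_edge = 10,
                             seed = 1L) {
  seed <- check_seed(seed)
  if (net$n_edges < 2) {
    abort("Need at least 2 edges to rewire.", class = "wm_config_error")
  }
  a <- (net$adjacency > 0) + 0
  g0 <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  wts <- vectorize_edges(net$adjacency)
  wts <- wts[wts > 0]
  n <- nrow(net$adjacency)
  with_seed(seed, {
    lapply(seq_len(n_rand), function(r) {
      g <- if (n_swaps_per_edge > 0) {
        igraph::rewire(g0, igraph::keeping_degseq(
          niter = n_swaps_per_edge * igraph::ecount(g0)))
      } else {
        g0
      }
      if (n_swaps_per_edge == 0) {
        return(structure(list(adjacency = net$adjacency,
                              sparsity = net$sparsity,
                              weighted = net$weighted,
                              n_edges = net$n_edges),
                         class = "wm_network"))
      }
      el <- igraph::as_edgelist(g, names = FALSE)
      adj <- matrix(0, n, n)
      val <- if (net$weighted) sample(wts) else rep(1, nrow(el))
      adj[el] <- val
      adj <- adj + t(adj)
      structure(list(adjacency = adj, sparsity = net$sparsity,
                     weighted = net$weighted, n_edges = net$n_edges),
                class = "wm_network")
    })
  })
}

#' Normalised global metrics
#'
#' Computes the seven global metrics of a network, normalising clustering
#' and path length against the mean over a list of degree-preserving random
#' references: `gamma = cp / mean(cp_ref)`, `lambda = lp / mean(lp_ref)`,
#' `sigma = gamma / lambda`.
#'
#' @param net A `wm_network`.
#' @param refs List of reference networks from [random_reference()].
#' @return One-row tibble: `cp`, `lp`, `e_loc`, `e_glob`, `gamma`,
#'   `lambda`, `sigma`, `n_infinite_pairs`.
#' @export
normalized_globals <- function(net, refs) {
  if (!length(refs)) {
    abort("refs must be a nonempty list of reference networks.",
          class = "wm_config_error")
  }
  cc <- clustering_coefficient(net)
  pm <- path_metrics(net)
  le <- local_efficiency(net)
  cp_ref <- mean(vapply(refs, function(r) clustering_coefficient(r)$cp,
                        numeric(1)))
  lp_ref <- mean(vapply(refs, function(r) path_metrics(r)$lp, numeric(1)))
  if (!is.finite(cp_ref) || cp_ref == 0) {
    abort("Undefined normalisation: reference clustering is zero.",
          class = "wm_normalization_error")
  }
  gamma <- cc$cp / cp_ref
  lambda <- pm$lp / lp_ref
  tibble(
    cp = cc$cp, lp = pm$lp, e_loc = le$e_loc, e_glob = pm$e_glob,
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    n_infinite_pairs = pm$n_infinite_pairs
  )
}

#' Global metrics with internally generated references
#'
#' @param net A `wm_network`.
#' @param n_rand,n_swaps_per_edge,seed Passed to [random_reference()].
#' @return One-row tibble as in [normalized_globals()].
#' @export
global_metrics <- function(net, n_rand = 100, n_swaps_per_edge = 10,
                           seed = 1L) {
  normalized_globals(net, random_reference(net, n_rand = n_rand,
                                           n_swaps_per_edge = n_swaps_per_edge,
                                           seed = seed))
}

global_metric_names <- c("cp", "lp", "e_loc", "e_glob",
                         "gamma", "lambda", "sigma")

#' Global metric curves for every subject of a cohort
#'
#' Thresholds each subject's matrix at every grid sparsity and computes the
#' seven global metrics, normalising against `n_rand` degree-preserving
#' random references per network.
#'
#' @param cohort A `wm_cohort`.
#' @param grid A [sparsity_grid()].
#' @param weighted Metric representation (default weighted).
#' @param n_rand,n_swaps_per_edge Reference-network settings.
#' @param seed Integer seed.
#' @return Tibble of class `wm_metric_curves`: `subject_id`, `group`, `S`
#'   and one column per metric.
#' @export
cohort_global_curves <- function(cohort, grid = sparsity_grid(),
                                 weighted = TRUE, n_rand = 100,
                                 n_swaps_per_edge = 10, seed = 1L) {
  seed <- check_seed(seed)
  ids <- cohort$metadata$subject_id
  rows <- purrr::map2_dfr(ids, seq_along(ids), function(id, ii) {
    purrr::map2_dfr(as.numeric(grid), seq_along(grid), function(s, si) {
      net <- apply_sparsity(cohort$matrices[[id]], s, weighted = weighted)
      gm <- global_metrics(net, n_rand = n_rand,
                           n_swaps_per_edge = n_swaps_per_edge,
                           seed = seed + 7919L * si + ii)
      dplyr::bind_cols(tibble(subject_id = id, S = s), gm)
    })
  })
  out <- dplyr::left_join(rows,
                          dplyr::select(cohort$metadata, "subject_id", "group"),
                          by = "subject_id")
  out <- dplyr::relocate(out, "group", .after = "subject_id")
  class(out) <- c("wm_metric_curves", class(out))
  out
}

#' Nodal metric curves for every subject of a cohort
#'
#' @inheritParams cohort_global_curves
#' @return Tibble: `subject_id`, `group`, `S`, `node`, `degree`,
#'   `betweenness`, `efficiency`.
#' @export
cohort_nodal_curves <- function(cohort, grid = sparsity_grid(),
                                weighted = TRUE) {
  ids <- cohort$metadata$subject_id
  rows <- purrr::map_dfr(ids, function(id) {
    purrr::map_dfr(as.numeric(grid), function(s) {
      net <- apply_sparsity(cohort$matrices[[id]], s, weighted = weighted)
      dplyr::bind_cols(tibble(subject_id = id, S = s), nodal_metrics(net))
    })
  })
  out <- dplyr::left_join(rows,
                          dplyr::select(cohort$metadata, "subject_id", "group"),
                          by = "subject_id")
  dplyr::relocate(out, "group", .after = "subject_id")
}

#' Per-subject AUC of global metric curves
#'
#' @param curves Output of [cohort_global_curves()].
#' @return Tibble: `subject_id`, `group`, `metric`, `auc` (long format).
#' @export
global_auc_table <- function(curves) {
  s <- sort(unique(curves$S))
  curves |>
    tidyr::pivot_longer(dplyr::all_of(global_metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$subject_id, .data$group, .data$metric) |>
    dplyr::arrange(.data$S, .by_group = TRUE) |>
    dplyr::summarise(auc = metric_auc(.data$value, s), .groups = "drop")
}

#' Per-subject, per-node AUC of nodal metric curves
#'
#' @param nodal_curves Output of [cohort_nodal_curves()].
#' @return Tibble: `subject_id`, `group`, `node`, `measure`, `auc`.
#' @export
nodal_auc_table <- function(nodal_curves) {
  s <- sort(unique(nodal_curves$S))
  nodal_curves |>
    tidyr::pivot_longer(c("degree", "betweenness", "efficiency"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$subject_id, .data$group, .data$node,
                    .data$measure) |>
    dplyr::arrange(.data$S, .by_group = TRUE) |>
    dplyr::summarise(auc = metric_auc(.data$value, s), .groups = "drop")
}
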