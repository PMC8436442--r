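# Independent brute-force implementations used as oracles for the graph
# metrics.  Everything here is deliberately naive (exhaustive enumeration,
# O(n^4) shortest paths) and shares no code with the package internals.

# random symmetric test matrix; weighted draws U(0.2, 1), binary gives 0/1
rand_sym_matrix <- function(n, density = 0.5, weighted = TRUE, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < density) {
          m[i, j] <- m[j, i] <- if (weighted) runif(1, 0.2, 1) else 1
        }
      }
    }
    m
  })
}

as_net <- function(adj, weighted = TRUE) {
  structure(list(adjacency = adj, sparsity = NA_real_, weighted = weighted,
                 n_edges = sum(adj[upper.tri(adj)] > 0)),
            class = "wm_network")
}

# min-plus closure: all-pairs shortest paths with distance 1/weight
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- ifelse(adj > 0, 1 / adj, Inf)
  diag(D) <- 0
  for (rep in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
        }
      }
    }
  }
  D
}

oracle_lp <- function(adj) {
  D <- oracle_distances(adj)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  }
  s / (n * (n - 1))
}

oracle_nodal_eff <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    v <- D[i, -i]
    sum(1 / v[is.finite(v)]) / (n - 1)
  }, numeric(1))
}

# exhaustive triangle enumeration; weighted = Onnela (weights / max, cube
# root of the triple product)
oracle_clustering <- function(adj, weighted = TRUE) {
  n <- nrow(adj)
  a <- adj > 0
  wn <- if (weighted && max(adj) > 0) adj / max(adj) else (adj > 0) + 0
  local <- vapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    if (k < 2) return(0)
    s <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h && a[i, j] && a[i, h] && a[j, h]) {
          s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
        }
      }
    }
    s / (k * (k - 1))
  }, numeric(1))
  list(local = local, cp = mean(local))
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  list(local = local, e_loc = mean(local))
}

# betweenness by exhaustive enumeration of all simple paths per pair,
# keeping the shortest and splitting credit equally among them
oracle_betweenness <- function(adj, tol = 1e-9) {
  n <- nrow(adj)
  W <- ifelse(adj > 0, 1 / adj, Inf)
  bt <- numeric(n)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (nxt in which(adj[last, ] > 0)) {
        if (!(nxt %in% path)) walk(c(path, nxt), len + W[last, nxt])
      }
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      short <- which(lens <= min(lens) + tol)
      for (pidx in short) {
        inner <- setdiff(paths[[pidx]]$path, c(s, t))
        bt[inner] <- bt[inner] + 1 / length(short)
      }
    }
  }
  bt
}

# tiny cohort: n_a patients + n_b controls with given per-subject matrices
make_cohort <- function(mats_patient, mats_control, atlas = NULL) {
  n <- nrow(mats_patient[[1]])
  atlas <- atlas %||% node_atlas(sprintf("R%02d", seq_len(n)))
  ids <- c(sprintf("p%02d", seq_along(mats_patient)),
           sprintf("c%02d", seq_along(mats_control)))
  mats <- c(mats_patient, mats_control)
  names(mats) <- ids
  meta <- tibble::tibble(
    subject_id = ids,
    group = rep(c("patient", "control"),
                c(length(mats_patient), length(mats_control))),
    age = 50, sex = 0L
  )
  wm_cohort(atlas, mats, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
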