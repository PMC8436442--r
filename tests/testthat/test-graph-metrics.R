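ring <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    m[i, j] <- m[j, i] <- 1
  }
  m
}

star <- function(leaves) {
  m <- matrix(0, leaves + 1, leaves + 1)
  m[1, -1] <- m[-1, 1] <- 1
  m
}

test_that("closed-form values on canonical graphs are reproduced", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(clustering_coefficient(as_net(k4, weighted = FALSE))$cp, 1)
  expect_equal(local_efficiency(as_net(k4, weighted = FALSE))$e_loc, 1)

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(clustering_coefficient(as_net(p3, weighted = FALSE))$cp, 0)

  c5 <- ring(5)
  pm <- path_metrics(as_net(c5, weighted = FALSE))
  expect_equal(pm$lp, 1.5)
  expect_equal(pm$e_glob, 0.75)

  s4 <- star(4)
  bt <- betweenness_centrality(as_net(s4, weighted = FALSE))
  expect_equal(bt, c(6, 0, 0, 0, 0))   # (n-1)(n-2)/2 through the hub
  expect_equal(path_metrics(as_net(s4, weighted = FALSE))$nodal_efficiency[1], 1)
  expect_equal(local_efficiency(as_net(s4, weighted = FALSE))$e_loc, 0)

  c4 <- ring(4)
  expect_equal(betweenness_centrality(as_net(c4, weighted = FALSE)),
               rep(0.5, 4))            # tie-splitting over two geodesics

  two_k2 <- matrix(0, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1
  pm2 <- path_metrics(as_net(two_k2, weighted = FALSE))
  expect_equal(pm2$e_glob, 1 / 3)      # 4 finite of 12 ordered pairs
  expect_equal(pm2$lp, 1)              # finite pairs only
  expect_equal(pm2$n_infinite_pairs, 8)
})

test_that("all metrics match exhaustive oracles on random small graphs", {
  for (s in 1:40) {
    n <- 4 + (s %% 4)
    weighted <- s %% 2 == 0
    adj <- rand_sym_matrix(n, density = 0.35 + 0.1 * (s %% 6),
                           weighted = weighted, seed = 2000 + s)
    net <- as_net(adj, weighted = weighted)
    pm <- path_metrics(net)
    olp <- oracle_lp(adj)
    if (is.nan(olp)) expect_true(is.nan(pm$lp)) else
      expect_equal(pm$lp, olp, tolerance = 1e-9)
    expect_equal(pm$e_glob, oracle_global_eff(adj), tolerance = 1e-9)
    expect_equal(pm$nodal_efficiency, oracle_nodal_eff(adj),
                 tolerance = 1e-9)
    expect_equal(clustering_coefficient(net)$local,
                 oracle_clustering(adj, weighted)$local, tolerance = 1e-9)
    expect_equal(local_efficiency(net)$local,
                 oracle_local_eff(adj)$local, tolerance = 1e-9)
    expect_equal(betweenness_centrality(net), oracle_betweenness(adj),
                 tolerance = 1e-9)
  }
})

test_that("degree-preserving rewiring keeps the degree sequence and weights", {
  m <- rand_sym_matrix(30, density = 0.3, seed = 5)
  net <- apply_sparsity(m, 0.25)
  refs <- random_reference(net, n_rand = 10, seed = 9)
  deg0 <- rowSums(net$adjacency > 0)
  w0 <- sort(net$adjacency[upper.tri(net$adjacency)])
  for (r in refs) {
    expect_equal(rowSums(r$adjacency > 0), deg0)
    expect_equal(sort(r$adjacency[upper.tri(r$adjacency)]), w0)
  }
  # identical seed, identical references
  refs2 <- random_reference(net, n_rand = 10, seed = 9)
  expect_identical(refs, refs2)
  # zero swaps returns the input topology and weights
  refs0 <- random_reference(net, n_rand = 3, n_swaps_per_edge = 0, seed = 1)
  for (r in refs0) expect_equal(r$adjacency, net$adjacency)
})

test_that("rewiring a clustered network lowers its clustering", {
  w <- generate_backbone(simulation_config(seed = 8))
  net <- apply_sparsity(w, 0.2)
  refs <- random_reference(net, n_rand = 20, seed = 3)
  cp_ref <- mean(vapply(refs, function(r) clustering_coefficient(r)$cp,
                        numeric(1)))
  expect_lt(cp_ref, clustering_coefficient(net)$cp)
})

test_that("normalisation against self gives gamma = lambda = sigma = 1", {
  m <- rand_sym_matrix(20, density = 0.4, seed = 3)
  net <- as_net(m)
  gm <- normalized_globals(net, list(net, net, net))
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda, 1)
  expect_equal(gm$sigma, 1)
})

test_that("sigma is exactly gamma over lambda", {
  m <- rand_sym_matrix(30, density = 0.4, seed = 6)
  net <- apply_sparsity(m, 0.3)
  gm <- global_metrics(net, n_rand = 5, seed = 2)
  expect_identical(gm$sigma, gm$gamma / gm$lambda)
  expect_gt(gm$gamma, 0)
  expect_gt(gm$lambda, 0)
})

test_that("an edgeless reference set is an error", {
  m <- rand_sym_matrix(10, density = 0.5, seed = 1)
  net <- as_net(m)
  expect_error(normalized_globals(net, list()), class = "wm_config_error")
})

test_that("nodal metrics are equivariant under node relabelling", {
  m <- rand_sym_matrix(12, density = 0.5, seed = 10)
  perm <- withr::with_seed(4, sample(12))
  mp <- m[perm, perm]
  a <- nodal_metrics(as_net(m))
  b <- nodal_metrics(as_net(mp))
  expect_equal(b$degree, a$degree[perm], tolerance = 1e-12)
  expect_equal(b$betweenness, a$betweenness[perm], tolerance = 1e-9)
  expect_equal(b$efficiency, a$efficiency[perm], tolerance = 1e-12)
  # global metrics are invariant
  expect_equal(clustering_coefficient(as_net(mp))$cp,
               clustering_coefficient(as_net(m))$cp, tolerance = 1e-12)
  expect_equal(path_metrics(as_net(mp))$lp, path_metrics(as_net(m))$lp,
               tolerance = 1e-12)
})

test_that("binary degree averages to 2K/N at every sparsity", {
  m <- rand_sym_matrix(50, density = 0.6, seed = 12)
  for (S in c(0.1, 0.2, 0.3)) {
    net <- apply_sparsity(m, S, weighted = FALSE)
    expect_equal(mean(rowSums(net$adjacency)),
                 2 * edges_at_sparsity(S, 50) / 50)
  }
})
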