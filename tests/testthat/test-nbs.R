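# brute-force component extraction: flood fill over the supra-threshold
# edge list
oracle_components <- function(t_matrix, thr, sign) {
  n <- nrow(t_matrix)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tv <- t_matrix[i, j]
      ok <- if (sign == "less") tv <= -thr else tv >= thr
      if (ok) keep[i, j] <- keep[j, i] <- TRUE
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s] || !any(keep[s, ])) next
    comp <- s; frontier <- s; seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(keep[, frontier, drop = FALSE]) > 0),
                     comp)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    edges <- sum(keep[comp, comp]) / 2
    comps[[length(comps) + 1]] <- list(nodes = sort(comp),
                                       n_edges = edges)
  }
  comps
}

sym_t <- function(n, entries) {
  m <- matrix(0, n, n)
  for (e in entries) m[e[1], e[2]] <- m[e[2], e[1]] <- e[3]
  m
}

test_that("edgewise t equals the per-edge textbook t statistic", {
  mats_p <- lapply(1:6, function(s) rand_sym_matrix(6, 0.9, TRUE, 300 + s))
  mats_c <- lapply(1:7, function(s) rand_sym_matrix(6, 0.9, TRUE, 400 + s))
  coh <- make_cohort(mats_p, mats_c)
  tm <- edgewise_t(coh)
  expect_identical(tm, t(tm))
  expect_true(all(diag(tm) == 0))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      a <- vapply(mats_p, function(m) m[i, j], numeric(1))
      b <- vapply(mats_c, function(m) m[i, j], numeric(1))
      if (var(c(a, b)) == 0) {
        expect_equal(tm[i, j], 0)
      } else {
        expect_equal(tm[i, j],
                     unname(t.test(a, b, var.equal = TRUE)$statistic),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("identical groups give an all-zero t matrix", {
  mats <- lapply(1:4, function(s) rand_sym_matrix(5, 0.8, TRUE, s))
  coh <- make_cohort(mats[1:2], mats[1:2])
  expect_true(all(edgewise_t(coh) == 0))
})

test_that("a single strongly shifted edge carries the maximum |t|", {
  base <- rand_sym_matrix(6, 1, TRUE, 77)
  mats_p <- lapply(1:8, function(s) {
    m <- base + rand_sym_matrix(6, 1, TRUE, 500 + s) * 0.01
    diag(m) <- 0
    m[2, 5] <- m[5, 2] <- m[2, 5] + 10
    m
  })
  mats_c <- lapply(1:8, function(s) {
    m <- base + rand_sym_matrix(6, 1, TRUE, 600 + s) * 0.01
    diag(m) <- 0
    m
  })
  tm <- edgewise_t(make_cohort(mats_p, mats_c))
  expect_equal(which.max(abs(vectorize_edges(tm))),
               which(edge_index_table(6)$i == 2 &
                       edge_index_table(6)$j == 5))
})

test_that("component extraction matches hand-worked examples and brute force", {
  tm <- sym_t(6, list(c(1, 2, 3), c(2, 3, 3), c(4, 5, 3)))
  comps <- supra_components(tm, 2.62, "greater")
  sizes <- vapply(comps, function(cc) nrow(cc$edges), integer(1))
  nodesets <- lapply(comps, `[[`, "nodes")
  expect_equal(sort(sizes), c(1, 2))
  expect_true(any(vapply(nodesets, identical, logical(1), c(1L, 2L, 3L))))
  expect_equal(length(supra_components(tm, 2.62, "less")), 0)
  k4 <- matrix(3, 4, 4); diag(k4) <- 0
  expect_equal(nrow(supra_components(k4, 2.62, "greater")[[1]]$edges), 6)

  for (s in 1:30) {
    n <- 4 + s %% 3
    tm <- rand_sym_matrix(n, 0.6, TRUE, 700 + s) * 6 - 3
    tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
    diag(tm) <- 0
    for (sign in c("less", "greater")) {
      got <- supra_components(tm, 1.5, sign)
      want <- oracle_components(tm, 1.5, sign)
      expect_equal(length(got), length(want))
      got_sizes <- sort(vapply(got, function(cc) nrow(cc$edges),
                               integer(1)))
      want_sizes <- sort(vapply(want, function(cc) cc$n_edges, numeric(1)))
      expect_equal(got_sizes, as.integer(want_sizes))
    }
  }
})

test_that("raising the threshold never grows a component", {
  tm <- rand_sym_matrix(10, 0.7, TRUE, 31) * 8 - 4
  tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
  diag(tm) <- 0
  max_size <- function(thr) {
    comps <- supra_components(tm, thr, "greater")
    if (!length(comps)) 0L else
      max(vapply(comps, function(cc) nrow(cc$edges), integer(1)))
  }
  sizes <- vapply(seq(0.5, 3.5, 0.5), max_size, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("NBS p-values respect the add-one bounds and the seed", {
  cfg <- simulation_config(seed = 19, n_nodes = 20, n_patients = 5,
                           n_controls = 5,
                           nbs_edges = data.frame(i = c(1, 7), j = c(7, 13)),
                           nbs_effect = 0.3,
                           pred_edges = data.frame(i = 2, j = 8))
  coh <- simulate_cohort(cfg)
  res <- nbs_test(coh, nbs_config(n_perm = 100, seed = 2,
                                  direction = "both"))
  expect_true(all(res$components$p_fwer >= 1 / 101))
  expect_true(all(res$components$p_fwer <= 1))
  res2 <- nbs_test(coh, nbs_config(n_perm = 100, seed = 2,
                                   direction = "both"))
  expect_identical(res$components, res2$components)
  # every supra-threshold edge exceeds the threshold with a consistent sign
  ed <- tidy(res)
  if (nrow(ed)) {
    expect_true(all(abs(ed$t) >= 2.62))
    expect_true(all(tapply(sign(ed$t),
                           paste(ed$direction, ed$component),
                           function(x) length(unique(x)) == 1)))
  }
})

test_that("the edge universe drops rarely present connections", {
  base <- rand_sym_matrix(8, 1, TRUE, 55)
  mats <- lapply(1:10, function(s) {
    m <- base
    m[1, 2] <- m[2, 1] <- if (s <= 2) 0.5 else 0   # present in 20% only
    m
  })
  coh <- make_cohort(mats[1:5], mats[6:10])
  tm <- edgewise_t(coh, edge_mask = colMeans(
    cohort_edge_matrix(coh) > 0) >= 0.5)
  expect_equal(tm[1, 2], 0)
})
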