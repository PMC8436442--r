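#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes in
#' real FA-weighted connectome cohorts: a shared modular small-world
#' template, per-subject weight noise, a diffuse within-module weakening in
#' patients (which lowers clustering, gamma and sigma), a small connected
#' subnetwork of additionally weakened connections (the target of the NBS),
#' and a set of connections whose weights carry a fast/slow progression
#' signal.  Group sizes and clinical moments default to a 73-patient /
#' 100-control cohort with ALSFRS-R-style scores.
#'
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param n_nodes Atlas size (default 90).
#' @param n_controls,n_patients Group sizes (defaults 100 and 73).
#' @param n_modules Modules of the backbone (default 6); nodes are assigned
#'   round-robin by index.
#' @param p_within,p_between Edge probabilities inside/between modules.
#' @param weight_mean,weight_sd FA-like weight distribution, truncated to
#'   (0, 1).
#' @param within_weight_boost Additive raise of the mean weight of
#'   within-module edges, so that sparsity thresholding preserves the
#'   modular (small-world) structure.
#' @param subject_noise_sd Per-subject, per-edge weight jitter.
#' @param group_effect Fractional reduction of within-module weights in
#'   patients.
#' @param nbs_edges Two-column matrix/data frame of node pairs forming a
#'   connected planted subnetwork, additionally weakened in patients.
#' @param nbs_effect Additive weight reduction on `nbs_edges` in patients.
#' @param pred_edges Node pairs carrying the fast/slow progression signal.
#' @param pred_effect Additive weight reduction on `pred_edges` in
#'   fast-progressing patients.
#' @param frac_fast Fraction of patients labelled fast progressors.
#' @param rate_cutoff Progression-rate cut-off, units per month.
#' @return A validated list of class `wm_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_nodes = 90L,
                              n_controls = 100L,
                              n_patients = 73L,
                              n_modules = 6L,
                              p_within = 0.9,
                              p_between = 0.26,
                              weight_mean = 0.45,
                              weight_sd = 0.1,
                              within_weight_boost = 0.12,
                              subject_noise_sd = 0.05,
                              group_effect = 0.15,
                              nbs_edges = default_nbs_edges(),
                              nbs_effect = 0.06,
                              pred_edges = default_pred_edges(),
                              pred_effect = 0.075,
                              frac_fast = 0.5,
                              rate_cutoff = 0.68) {
  cfg <- list(seed = check_seed(seed), n_nodes = as.integer(n_nodes),
              n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              n_modules = as.integer(n_modules),
              p_within = p_within, p_between = p_between,
              weight_mean = weight_mean, weight_sd = weight_sd,
              within_weight_boost = within_weight_boost,
              subject_noise_sd = subject_noise_sd,
              group_effect = group_effect,
              nbs_edges = as_edge_df(nbs_edges),
              nbs_effect = nbs_effect,
              pred_edges = as_edge_df(pred_edges),
              pred_effect = pred_effect,
              frac_fast = frac_fast, rate_cutoff = rate_cutoff)
  probs <- c(cfg$p_within, cfg$p_between)
  if (any(probs < 0 | probs > 1)) {
    abort("Edge probabilities must lie in [0, 1].", class = "wm_config_error")
  }
  if (any(c(cfg$group_effect, cfg$nbs_effect, cfg$pred_effect) < 0)) {
    abort("Planted effects must be >= 0.", class = "wm_config_error")
  }
  if (!(cfg$frac_fast > 0 && cfg$frac_fast < 1)) {
    abort("frac_fast must lie strictly in (0, 1).", class = "wm_config_error")
  }
  if (nrow(cfg$nbs_edges) && !edges_connected(cfg$nbs_edges)) {
    abort("nbs_edges must form a connected subgraph.",
          class = "wm_config_error")
  }
  if (max(c(0, cfg$nbs_edges$i, cfg$nbs_edges$j,
            cfg$pred_edges$i, cfg$pred_edges$j)) > cfg$n_nodes) {
    abort("Planted edges reference nodes beyond n_nodes.",
          class = "wm_config_error")
  }
  structure(cfg, class = "wm_sim_config")
}

as_edge_df <- function(edges) {
  if (is.null(edges)) return(tibble(i = integer(), j = integer()))
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("i", "j")
  ii <- pmin(edges$i, edges$j)
  jj <- pmax(edges$i, edges$j)
  if (any(ii == jj)) abort("Self-loop in planted edge list.",
                           class = "wm_config_error")
  tibble(i = as.integer(ii), j = as.integer(jj))
}

edges_connected <- function(edges) {
  g <- igraph::graph_from_edgelist(cbind(edges$i, edges$j), directed = FALSE)
  g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
  igraph::components(g)$no == 1L
}

# A 5-edge path inside one backbone module (nodes 1,7,...,31 all fall in the
# same module under round-robin assignment with 6 modules).
default_nbs_edges <- function() {
  nodes <- c(1L, 7L, 13L, 19L, 25L, 31L)
  tibble(i = nodes[-length(nodes)], j = nodes[-1])
}

# 20 within-module edges, disjoint from the NBS path.
default_pred_edges <- function() {
  i <- 32:51
  tibble(i = as.integer(i), j = as.integer(i + 6L))
}

module_of <- function(nodes, n_modules) (nodes - 1L) %% n_modules

rtrunc_norm01 <- function(n, mean, sd, lo = 1e-3, hi = 1 - 1e-3) {
  if (sd == 0) return(pmin(pmax(rep_len(mean, n), lo), hi))
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# Template generation under the *current* RNG state.
backbone_impl <- function(config) {
  n <- config$n_nodes
  idx <- edge_index_table(n)
  within <- module_of(idx$i, config$n_modules) ==
    module_of(idx$j, config$n_modules)
  p <- ifelse(within, config$p_within, config$p_between)
  present <- runif(nrow(idx)) < p
  planted <- rbind(config$nbs_edges, config$pred_edges)
  if (nrow(planted)) {
    pl_idx <- edge_df_to_index(planted, n)
    present[pl_idx] <- TRUE
  }
  mu <- config$weight_mean + ifelse(within, config$within_weight_boost, 0)
  w <- numeric(nrow(idx))
  w[present] <- rtrunc_norm01(sum(present), mu[present], config$weight_sd)
  devectorize_edges(w, n)
}

edge_df_to_index <- function(edges, n) {
  # row-major upper-triangle index of (i, j), i < j
  (edges$i - 1L) * n - edges$i * (edges$i - 1L) %/% 2L + (edges$j - edges$i)
}

#' Generate the weighted backbone template
#'
#' Builds the shared modular small-world template from which every
#' synthetic subject is derived.  The template is checked to stay connected
#' when thresholded at the minimum analysis sparsity.
#'
#' @param config A [simulation_config()].
#' @param s_check Sparsity at which connectivity of the thresholded
#'   template is required (default 0.10, the lower end of the default
#'   analysis grid).
#' @return A symmetric weighted matrix (the template connectivity matrix).
#' @export
generate_backbone <- function(config, s_check = 0.10) {
  w <- with_seed(config$seed, backbone_impl(config))
  net <- apply_sparsity(w, s_check, weighted = FALSE)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected")
  if (igraph::components(g)$no != 1L) {
    abort(sprintf(
      "Backbone is disconnected at sparsity %.2f; raise p_between or p_within.",
      s_check
    ), class = "wm_simulation_error")
  }
  w
}

#' Simulate a full cohort
#'
#' Draws one connectivity matrix per subject from the backbone template
#' plus per-subject noise, applies the planted patient and progression
#' effects, and generates a matching clinical metadata table (ages,
#' disease durations, ALSFRS-R totals and subscores consistent with the
#' generated progression rates, mood scores and head-motion covariates).
#' ALSFRS-R values are derived from a simulated progression rate so that
#' the rate formula `(48 - ALSFRS-R) / duration` is exercised end to end
#' and the fast/slow labels straddle the configured cut-off.
#'
#' @param config A [simulation_config()].
#' @return A validated [wm_cohort()] whose atlas is [aal90_atlas()] when
#'   `n_nodes == 90` and generic region labels otherwise.  The metadata
#'   carries the motion covariates in columns `motion_1` ... `motion_8`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "wm_sim_config"))
  n <- config$n_nodes
  atlas <- if (n == 90L) aal90_atlas() else
    node_atlas(sprintf("region_%03d", seq_len(n)))
  idx <- edge_index_table(n)
  within <- module_of(idx$i, config$n_modules) ==
    module_of(idx$j, config$n_modules)
  nbs_idx <- edge_df_to_index(config$nbs_edges, n)
  pred_idx <- edge_df_to_index(config$pred_edges, n)

  with_seed(config$seed, {
    template <- backbone_impl(config)
    w0 <- vectorize_edges(template)
    present <- w0 > 0

    meta <- simulate_metadata(config)
    is_pat <- meta$group == "patient"
    is_fast <- !is.na(meta$progression_class) &
      meta$progression_class == "fast"

    matrices <- lapply(seq_len(nrow(meta)), function(s) {
      w <- w0
      if (is_pat[s]) {
        w[within & present] <- w[within & present] * (1 - config$group_effect)
        w[nbs_idx] <- w[nbs_idx] - config$nbs_effect
        if (is_fast[s]) w[pred_idx] <- w[pred_idx] - config$pred_effect
      }
      w[present] <- pmin(pmax(
        w[present] + rnorm(sum(present), 0, config$subject_noise_sd),
        1e-3), 1 - 1e-3)
      devectorize_edges(w, n)
    })
    names(matrices) <- meta$subject_id
    wm_cohort(atlas, matrices,
              dplyr::select(meta, -"progression_class"))
  })
}

simulate_metadata <- function(config) {
  np <- config$n_patients
  nc <- config$n_controls

  # disease duration, months: lognormal matched to mean 10.58, sd 5.86
  dur_sdlog <- sqrt(log(1 + (5.86 / 10.58)^2))
  dur_meanlog <- log(10.58) - dur_sdlog^2 / 2
  duration <- rlnorm(np, dur_meanlog, dur_sdlog)

  # progression rate: lognormal matched to mean 0.71, sd 0.63, then scaled
  # so its (1 - frac_fast) quantile sits at the cut-off
  rate_sdlog <- sqrt(log(1 + (0.63 / 0.71)^2))
  rate_meanlog <- log(0.71) - rate_sdlog^2 / 2
  rate <- rlnorm(np, rate_meanlog, rate_sdlog)
  rate <- rate * config$rate_cutoff /
    quantile(rate, 1 - config$frac_fast, names = FALSE)

  alsfrs <- pmin(pmax(round(48 - rate * duration), 0L), 47L)
  rate_final <- progression_rate(alsfrs, duration)
  cls <- progression_class(rate_final, config$rate_cutoff)

  deficit <- 48L - alsfrs
  b_def <- pmin(round(deficit / 3), 12L)
  m_def <- pmin(deficit - b_def, 24L)
  r_def <- deficit - b_def - m_def

  pat <- tibble(
    subject_id = sprintf("pat%03d", seq_len(np)),
    group = "patient",
    age = round(rnorm(np, 49.8, 7.9), 1),
    sex = rbinom(np, 1, 40 / 73),
    education = pmax(0, round(rnorm(np, 9.0, 3.2))),
    duration_months = round(duration, 2),
    alsfrs_r = as.integer(alsfrs),
    bulbar = as.integer(12L - b_def),
    motor = as.integer(24L - m_def),
    respiratory = as.integer(12L - r_def),
    anxiety = pmax(0, round(rnorm(np, 4.1, 5.2))),
    depression = pmax(0, round(rnorm(np, 7.2, 7.2))),
    progression_class = cls
  )
  con <- tibble(
    subject_id = sprintf("con%03d", seq_len(nc)),
    group = "control",
    age = round(rnorm(nc, 49.8, 8.7), 1),
    sex = rbinom(nc, 1, 43 / 100),
    education = pmax(0, round(rnorm(nc, 8.9, 4.1))),
    duration_months = NA_real_,
    alsfrs_r = NA_integer_, bulbar = NA_integer_, motor = NA_integer_,
    respiratory = NA_integer_,
    anxiety = NA_real_, depression = NA_real_,
    progression_class = NA_character_
  )
  meta <- dplyr::bind_rows(pat, con)
  motion <- matrix(abs(rnorm(nrow(meta) * 8, 0,
                             rep(c(0.15, 0.15, 0.15, 0.1, 0.1, 0.1, 0.2, 0.2),
                                 each = nrow(meta)))),
                   ncol = 8,
                   dimnames = list(NULL, paste0("motion_", 1:8)))
  dplyr::bind_cols(meta, as_tibble(motion))
}

#' Null version of a simulation config
#'
#' Convenience: the same cohort conditions with every planted effect set to
#' zero, so group labels and progression labels are independent of the
#' matrices.
#'
#' @param config A [simulation_config()].
#' @param seed Optional replacement seed.
#' @return A `wm_sim_config`.
#' @export
null_config <- function(config = simulation_config(), seed = NULL) {
  cfg <- unclass(config)
  cfg$group_effect <- 0
  cfg$nbs_effect <- 0
  cfg$pred_effect <- 0
  if (!is.null(seed)) cfg$seed <- check_seed(seed)
  do.call(simulation_config, cfg[setdiff(names(cfg), character())])
}
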