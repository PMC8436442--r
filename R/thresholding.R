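#' Sparsity grid
#'
#' The analysis sweeps network sparsity S (fraction of possible edges kept)
#' over an evenly spaced grid; all threshold-dependent metrics are summarised
#' by their area under the curve over this grid.  The default grid matches
#' the range conventionally selected for 90-node FA networks, S in
#' \[0.10, 0.34\] with a 0.01 step.
#'
#' @param s_min,s_max Grid end points, in (0, 1).
#' @param step Grid spacing.
#' @return Object of class `wm_sparsity_grid`: the numeric vector of S
#'   values.
#' @examples
#' sparsity_grid()            # 0.10, 0.11, ..., 0.34
#' sparsity_grid(0.05, 0.5)
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_max < 1 && s_min < s_max)) {
    abort("Require 0 < s_min < s_max < 1.", class = "wm_config_error")
  }
  k <- (s_max - s_min) / step
  if (abs(k - round(k)) > 1e-9) {
    abort("(s_max - s_min) / step must be an integer.",
          class = "wm_config_error")
  }
  s <- s_min + step * (0:round(k))
  structure(s, class = "wm_sparsity_grid", step = step)
}

#' Number of edges kept at sparsity S
#'
#' `K = round(S * N * (N - 1) / 2)`, rounding half away from zero, so every
#' subject's thresholded network has exactly the same edge count.
#'
#' @param S Sparsity in (0, 1).
#' @param n Node count.
#' @return Integer edge count.
#' @export
edges_at_sparsity <- function(S, n) {
  m <- n * (n - 1) / 2
  as.integer(floor(S * m + 0.5))
}

#' Threshold a weighted matrix at a target sparsity
#'
#' Keeps exactly the top-K edges by weight, where
#' `K = round(S * N(N-1)/2)`; ties at the K-th weight are broken by
#' lexicographic (i, j) node order, so the kept edge set is deterministic
#' and nested across increasing S.
#'
#' @param weights Validated symmetric matrix (or a `wm_cohort` subject
#'   matrix).
#' @param S Target sparsity in (0, 1).
#' @param weighted If `TRUE` (default) kept edges retain their original
#'   weights; if `FALSE` the result is binary.
#' @return Object of class `wm_network`: list with `adjacency`, `sparsity`,
#'   `weighted`, `n_edges`.
#' @examples
#' w <- matrix(runif(16), 4); w <- (w + t(w)) / 2; diag(w) <- 0
#' net <- apply_sparsity(w, 0.5)
#' net$n_edges  # 3 of the 6 possible edges
#' @export
apply_sparsity <- function(weights, S, weighted = TRUE) {
  if (!(S > 0 && S < 1)) {
    abort("S must be in (0, 1).", class = "wm_config_error")
  }
  n <- nrow(weights)
  m <- n * (n - 1) / 2
  k <- edges_at_sparsity(S, n)
  if (k == 0L || k == m) {
    warn(sprintf("Degenerate threshold: S = %.3g keeps %d of %d edges.",
                 S, k, m))
  }
  idx <- edge_index_table(n)
  w <- vectorize_edges(weights)
  ord <- order(-w, idx$i, idx$j, method = "radix")
  keep <- ord[seq_len(k)]
  v <- numeric(m)
  v[keep] <- if (weighted) w[keep] else 1
  adj <- devectorize_edges(v, n)
  structure(list(adjacency = adj, sparsity = S, weighted = weighted,
                 n_edges = k),
            class = "wm_network")
}

#' @export
print.wm_network <- function(x, ...) {
  cat("<wm_network> ", nrow(x$adjacency), " nodes, ", x$n_edges,
      " edges (S = ", format(x$sparsity), ", ",
      if (x$weighted) "weighted" else "binary", ")\n", sep = "")
  invisible(x)
}

#' Select the valid sparsity range for a cohort
#'
#' Scans a candidate grid and returns the maximal contiguous sub-grid on
#' which, for every subject, (1) the mean nodal degree of the thresholded
#' network exceeds `2 * log(N)` (natural log) and (2) small-worldness sigma
#' exceeds `sigma_min`.  These are the two standard criteria for choosing a
#' sparsity window in which thresholded brain networks are estimable and
#' small-world.
#'
#' @param cohort A `wm_cohort`.
#' @param candidate Candidate grid (default `sparsity_grid(0.01, 0.50)`).
#' @param sigma_min Small-worldness floor (default 1.1).  Set to 0 to apply
#'   the degree criterion alone.
#' @param n_rand Random references per network for sigma (see
#'   [random_reference()]).
#' @param seed Seed for the random references.
#' @param weighted Metric representation.
#' @return A `wm_sparsity_grid` restricted to the valid range, with a
#'   `diagnostics` attribute: tibble of per-S criterion outcomes including
#'   the exact mean degree `2K/N` and the nominal `S * (N - 1)`.
#' @export
select_sparsity_range <- function(cohort,
                                  candidate = sparsity_grid(0.01, 0.50),
                                  sigma_min = 1.1,
                                  n_rand = 20,
                                  seed = 1L,
                                  weighted = TRUE) {
  seed <- check_seed(seed)
  n <- length(cohort$atlas)
  deg_floor <- 2 * log(n)
  s_vals <- as.numeric(candidate)
  k_vals <- vapply(s_vals, edges_at_sparsity, integer(1), n = n)
  mean_deg <- 2 * k_vals / n
  deg_ok <- mean_deg > deg_floor

  sigma_ok <- rep(TRUE, length(s_vals))
  min_sigma <- rep(NA_real_, length(s_vals))
  if (sigma_min > 0) {
    for (si in seq_along(s_vals)) {
      if (!deg_ok[si]) next   # sigma only decides within the degree-valid set
      sig <- vapply(seq_along(cohort$matrices), function(ii) {
        net <- apply_sparsity(cohort$matrices[[ii]], s_vals[si],
                              weighted = weighted)
        refs <- random_reference(net, n_rand = n_rand,
                                 seed = seed + si * 1000L + ii)
        normalized_globals(net, refs)$sigma
      }, numeric(1))
      min_sigma[si] <- min(sig)
      sigma_ok[si] <- min_sigma[si] > sigma_min
    }
  }

  ok <- deg_ok & sigma_ok
  diagnostics <- tibble(
    S = s_vals, K = k_vals,
    mean_degree = mean_deg,
    nominal_degree = s_vals * (n - 1),
    degree_ok = deg_ok,
    min_sigma = min_sigma,
    sigma_ok = sigma_ok,
    ok = ok
  )
  if (!any(ok)) {
    abort(paste0(
      "No sparsity satisfies both criteria (degree > ",
      format(deg_floor, digits = 4), " and sigma > ", sigma_min,
      "); degree criterion passes at ", sum(deg_ok), "/", length(ok),
      " grid points, sigma at ", sum(sigma_ok & deg_ok), "."
    ), class = "wm_empty_range_error")
  }
  # maximal contiguous run of TRUE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  keep <- starts[best]:ends[best]
  out <- sparsity_grid(s_vals[keep[1]], s_vals[keep[length(keep)]],
                       attr(candidate, "step") %||% diff(s_vals[1:2]))
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of a metric over S, the standard summary that frees
#' group comparisons from any single threshold choice.  A rectangle
#' (left-sum) rule is available for parity with toolboxes that use it.
#'
#' @param values Metric values, one per grid point (may be a matrix with one
#'   row per subject).
#' @param s_values The sparsity grid.
#' @param rule `"trapezoid"` (default) or `"rectangle"`.
#' @return Scalar AUC (or one per row of a matrix input).  NaN values
#'   propagate with a warning.
#' @examples
#' metric_auc(rep(1, 25), sparsity_grid())  # 0.24
#' @export
metric_auc <- function(values, s_values, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  s <- as.numeric(s_values)
  if (length(s) < 2) {
    abort("Need at least 2 grid points for an AUC.", class = "wm_config_error")
  }
  one <- function(v) {
    if (any(is.nan(v))) {
      warn(sprintf("NaN metric value at S = %s; AUC is NaN.",
                   paste(format(s[is.nan(v)]), collapse = ", ")))
    }
    if (rule == "trapezoid") {
      sum(diff(s) * (head(v, -1) + v[-1]) / 2)
    } else {
      sum(diff(s) * head(v, -1))
    }
  }
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(s))
    apply(values, 1L, one)
  } else {
    stopifnot(length(values) == length(s))
    one(values)
  }
}
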