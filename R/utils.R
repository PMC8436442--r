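#' Flatten a connectivity matrix to its upper-triangle edge vector
#'
#' Edges are ordered row-major over the upper triangle (i < j):
#' (1,2), (1,3), ..., (1,N), (2,3), ...  The first edge (1,2) has index 1.
#' This fixed order is the feature layout used throughout the prediction
#' module and the NBS, and [devectorize_edges()] is its exact inverse.
#'
#' @param m Symmetric N x N matrix.
#' @return Numeric vector of length `N * (N - 1) / 2`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 5
#' vectorize_edges(m)  # 5 0 0
#' @export
vectorize_edges <- function(m) {
  t(m)[lower.tri(m)]
}

#' @rdname vectorize_edges
#' @param v Edge vector of length `n * (n - 1) / 2`.
#' @param n Node count.
#' @return `devectorize_edges()`: the symmetric matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, n) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  mt <- t(m)
  mt[lower.tri(mt)] <- v
  m <- t(mt)
  m + t(m)
}

#' Edge index table for an atlas of n nodes
#'
#' @param n Node count.
#' @return Tibble with columns `edge` (1-based index in the
#'   [vectorize_edges()] order), `i`, `j` (1-based node indices, i < j).
#' @export
edge_index_table <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  tibble(edge = seq_along(i), i = i, j = j)
}

# Pooled-variance two-sample t statistics for many variables at once.
# X: subjects x variables; is_a: logical group indicator.  Zero-variance
# variables yield t = 0.  Returns a numeric vector (one t per variable),
# contrast mean(A) - mean(B).
two_sample_t_cols <- function(X, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  stopifnot(na >= 2, nb >= 2)
  sa <- colSums(X[is_a, , drop = FALSE])
  sb <- colSums(X[!is_a, , drop = FALSE])
  qa <- colSums(X[is_a, , drop = FALSE]^2)
  qb <- colSums(X[!is_a, , drop = FALSE]^2)
  ma <- sa / na; mb <- sb / nb
  ssa <- qa - na * ma^2
  ssb <- qb - nb * mb^2
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[!is.finite(t)] <- 0
  t
}

# Draw n_perm permuted group indicators (logical matrix n_perm x n),
# deterministically under `seed`.
permute_labels <- function(is_a, n_perm, seed) {
  n <- length(is_a)
  na <- sum(is_a)
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n, na)
      out <- logical(n)
      out[idx] <- TRUE
      out
    }, logical(n)))
  })
}

# Residualise columns of X on a covariate matrix (intercept included).
residualize <- function(X, covariates) {
  X <- as.matrix(X)
  if (is.null(covariates)) return(X)
  Z <- cbind(1, as.matrix(covariates))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[setdiff(seq_len(ncol(Z)), qrz$pivot[seq_len(qrz$rank)])]
    abort(paste0("Covariate matrix is rank deficient (collinear column(s): ",
                 paste(drop_cols %||% "unnamed", collapse = ", "), ")."),
          class = "wm_collinearity_error")
  }
  X - Z %*% qr.coef(qrz, X)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.finite(seed)) {
    abort("A seed is required for every stochastic stage.",
          class = "wm_config_error")
  }
  as.integer(seed)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards (lighter-weight than withr::with_seed; called in hot loops).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  code
}
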