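#' Fuzzy c-means objective
#'
#' The classic FCM cost `J = sum_i sum_j u_ij^m ||x_j - z_i||^2`: the
#' membership-weighted within-cluster scatter, with the fuzzifier `m`
#' controlling how strongly soft assignments are discounted.
#'
#' @param x numeric matrix `N x p`, rows are samples.
#' @param centers numeric matrix `C x p`, rows are cluster centers.
#' @param membership numeric matrix `C x N`, column-stochastic.
#' @param m fuzzifier, `> 1` (default 2).
#' @return Nonnegative scalar.
#' @seealso [fcm_fit()]
#' @export
fcm_objective <- function(x, centers, membership, m = 2) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  if (nrow(membership) != nrow(centers))
    stop("membership has ", nrow(membership), " rows but there are ",
         nrow(centers), " centers")
  if (ncol(membership) != nrow(x))
    stop("membership has ", ncol(membership), " columns but there are ",
         nrow(x), " samples")
  sum(membership^m * sq_dist(x, centers))
}

#' Fuzzy c-means center update
#'
#' Each center is the `u^m`-weighted mean of the data:
#' `z_i = sum_j u_ij^m x_j / sum_j u_ij^m`.
#'
#' @inheritParams fcm_objective
#' @return `C x p` matrix of centers.
#' @export
fcm_update_centers <- function(x, membership, m = 2) {
  x <- as.matrix(x)
  g <- membership^m
  den <- rowSums(g)
  if (any(den < 1e-12))
    stop("degenerate cluster: total membership weight is zero for cluster ",
         paste(which(den < 1e-12), collapse = ", "))
  (g %*% x) / den
}

#' Fuzzy c-means membership update
#'
#' `u_ij = 1 / sum_r (d_ij / d_rj)^(2/(m-1))`, i.e. the exact minimizer of
#' the FCM objective over the probability simplex for fixed centers. A zero
#' distance yields the analytic limit: full membership split equally among
#' the zero-distance centers.
#'
#' @param distances `C x N` matrix of squared Euclidean distances.
#' @param m fuzzifier, `> 1`.
#' @return `C x N` column-stochastic membership matrix.
#' @export
fcm_update_memberships <- function(distances, m = 2) {
  if (m <= 1) stop("fuzzifier m must be > 1")
  memberships_from_sqdist(as.matrix(distances), 1 / (m - 1))
}

#' Fit single-view fuzzy c-means
#'
#' Alternates the center and membership updates until the objective change
#' drops below `tol` or `max_iter` is reached. Initialization is a random
#' column-stochastic membership matrix (uniform Dirichlet per column) drawn
#' after `set.seed(seed)`. A cluster that loses all its weight is re-seeded
#' at the sample with the lowest maximum membership.
#'
#' @param x numeric matrix `N x p` (or vector, treated as `N x 1`).
#' @param k number of clusters `C`, `2 <= C <= N`.
#' @param m fuzzifier, `> 1` (default 2).
#' @param tol convergence threshold on `|J_(l+1) - J_l|` (default 0.001);
#'   `tol = 0` disables the test so exactly `max_iter` iterations run.
#' @param max_iter maximum number of iterations (default 100).
#' @param seed optional RNG seed for the initialization.
#' @param init optional explicit initial membership matrix (`C x N`),
#'   overriding the random initialization.
#' @return A list with `membership` (`C x N`), `cluster` (length-`N` argmax
#'   labels), `centers` (`C x p`), `objective` (per-iteration trace),
#'   `converged`, `n_iter` and `constraint_violation` (largest observed
#'   deviation of any column sum from 1 across all iterations).
#' @examples
#' x <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
#' fit <- fcm_fit(x, 2, seed = 1)
#' sort(fit$centers)
#' @export
fcm_fit <- function(x, k, m = 2, tol = 1e-3, max_iter = 100, seed = NULL,
                    init = NULL) {
  x <- as.matrix(x)
  N <- nrow(x)
  if (k > N) stop("more clusters (", k, ") than samples (", N, ")")
  if (m <= 1) stop("fuzzifier m must be > 1")
  resolve_seed(seed)
  u <- if (is.null(init)) random_membership(k, N) else as.matrix(init)
  stopifnot_stochastic(u, 2L, 1e-6, "initial membership")

  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  viol <- 0
  for (it in seq_len(max_iter)) {
    z <- weighted_centers_safe(x, u^m, u)
    D <- sq_dist(x, z)
    u <- fcm_update_memberships(D, m)
    viol <- max(viol, max(abs(colSums(u) - 1)))
    J <- sum(u^m * D)
    trace[it] <- J
    if (tol > 0 && abs(J_prev - J) < tol) { converged <- TRUE; break }
    J_prev <- J
  }
  list(membership = u, cluster = column_argmax(u), centers = z,
       objective = trace, converged = converged, n_iter = length(trace),
       constraint_violation = viol)
}
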