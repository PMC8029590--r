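#' CoFKM fused membership coefficients
#'
#' The collaborative fusion term for view `v`:
#' `u~_ij = (1 - eta) u_ij,v^m + eta/(V-1) sum_{v' != v} u_ij,v'^m`,
#' a convex combination of the current view's fuzzified memberships and the
#' average over the other views.
#'
#' @param memberships list of `V` column-stochastic `C x N` matrices.
#' @param eta collaboration strength, in `[0, (V-1)/V]`.
#' @param m fuzzifier.
#' @param v index of the view whose fusion coefficients are computed.
#' @return `C x N` matrix of nonnegative fusion coefficients.
#' @export
cofkm_fused_membership <- function(memberships, eta, m = 2, v = 1) {
  V <- length(memberships)
  if (eta > 0 && V < 2)
    stop("collaboration (eta > 0) requires at least two views")
  if (eta < 0 || eta > (V - 1) / max(V, 2))
    stop("eta must lie in [0, (V-1)/V]")
  um <- memberships[[v]]^m
  if (eta == 0 || V == 1) return(um)
  others <- Reduce(`+`, lapply(memberships[-v], function(u) u^m))
  (1 - eta) * um + eta / (V - 1) * others
}

#' CoFKM center update
#'
#' Per-view centers weighted by the fused membership coefficients:
#' `z_i,v = sum_j u~_ij,v x_j,v / sum_j u~_ij,v`. With `eta = 0` this is the
#' plain FCM center update applied independently per view.
#'
#' @param data a [multiview_data] object (or list of view matrices).
#' @inheritParams cofkm_fused_membership
#' @return list of `V` center matrices (`C x p_v`).
#' @export
cofkm_update_centers <- function(data, memberships, eta, m = 2) {
  data <- as_multiview(data)
  lapply(seq_len(data$n_views), function(v) {
    g <- cofkm_fused_membership(memberships, eta, m, v)
    weighted_centers_safe(data$views[[v]], g, memberships[[v]])
  })
}

#' CoFKM membership update
#'
#' Per-view memberships from collaboratively aggregated squared distances
#' `(1 - eta) d2_ij,v + eta/(V-1) sum_{v' != v} d2_ij,v'`. The published
#' update is the `m = 2` instantiation (ratio exponent 1); for other `m` the
#' exponent generalizes to `1/(m-1)`, consistent with the single-view update.
#'
#' @param distances list of `V` matrices (`C x N`) of squared distances.
#' @inheritParams cofkm_fused_membership
#' @return list of `V` column-stochastic membership matrices.
#' @export
cofkm_update_memberships <- function(distances, eta, m = 2) {
  V <- length(distances)
  if (eta > 0 && V < 2)
    stop("collaboration (eta > 0) requires at least two views")
  total <- Reduce(`+`, distances)
  lapply(seq_len(V), function(v) {
    agg <- if (eta == 0 || V == 1) distances[[v]]
           else (1 - eta) * distances[[v]] + eta / (V - 1) * (total - distances[[v]])
    memberships_from_sqdist(agg, 1 / (m - 1))
  })
}

#' Geometric-mean ensemble of per-view partitions
#'
#' Elementwise geometric mean `(prod_v U_v)^(1/V)`. The result is not
#' column-stochastic in general; crisp labels are taken as the per-column
#' argmax, which is invariant to any positive rescaling of a column.
#'
#' @param memberships list of `C x N` membership matrices.
#' @return `C x N` matrix (elementwise geometric mean).
#' @export
cofkm_geometric_ensemble <- function(memberships) {
  V <- length(memberships)
  Reduce(`*`, memberships)^(1 / V)
}

#' Fit collaborative multi-view fuzzy k-means (CoFKM)
#'
#' Alternates the per-view center and membership updates of the
#' collaborative objective
#' `J = sum_v sum_i sum_j u~_ij,v ||x_j,v - z_i,v||^2`
#' and fuses the converged per-view partitions by their elementwise
#' geometric mean. The coupling parameter `eta` shares membership
#' information across views; `eta = 0` decouples the views into `V`
#' independent FCM runs.
#'
#' @param data a [multiview_data] object or list of `N x p_v` matrices.
#' @param k number of clusters.
#' @param eta collaboration strength in `[0, (V-1)/V]`; default is the
#'   midpoint `(V-1)/(2V)` of the admissible range.
#' @param m fuzzifier (default 2; the published membership update is the
#'   `m = 2` case and is generalized otherwise).
#' @param tol convergence threshold on the objective change (`0` disables).
#' @param max_iter maximum iterations.
#' @param seed optional RNG seed (per-view initial memberships are drawn in
#'   view order).
#' @param init optional list of `V` initial membership matrices.
#' @return A list with `per_view_membership`, `fused` (geometric-mean matrix),
#'   `fused_normalized` (columns renormalized to sum to 1, for validity
#'   indices), `cluster`, `centers`, `objective` trace, `converged`,
#'   `n_iter`, `constraint_violation`.
#' @export
cofkm_fit <- function(data, k, eta = NULL, m = 2, tol = 1e-3, max_iter = 100,
                      seed = NULL, init = NULL) {
  data <- as_multiview(data)
  V <- data$n_views
  N <- data$n_samples
  if (k > N) stop("more clusters than samples")
  if (is.null(eta)) eta <- (V - 1) / (2 * V)
  if (eta > 0 && V < 2) stop("eta > 0 requires at least two views")
  if (m != 2)
    message("CoFKM membership update generalized to m = ", m,
            " with ratio exponent 1/(m-1)")
  resolve_seed(seed)
  u <- if (is.null(init)) replicate(V, random_membership(k, N), simplify = FALSE)
       else init
  stopifnot(length(u) == V)

  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  viol <- 0
  for (it in seq_len(max_iter)) {
    z <- cofkm_update_centers(data, u, eta, m)
    D <- lapply(seq_len(V), function(v) sq_dist(data$views[[v]], z[[v]]))
    u <- cofkm_update_memberships(D, eta, m)
    viol <- max(viol, max(vapply(u, function(ui) max(abs(colSums(ui) - 1)),
                                 numeric(1))))
    J <- sum(vapply(seq_len(V), function(v)
      sum(cofkm_fused_membership(u, eta, m, v) * D[[v]]), numeric(1)))
    trace[it] <- J
    if (tol > 0 && abs(J_prev - J) < tol) { converged <- TRUE; break }
    J_prev <- J
  }
  fused <- cofkm_geometric_ensemble(u)
  cs <- colSums(fused)
  fused_norm <- fused
  pos <- cs > 0
  fused_norm[, pos] <- sweep(fused[, pos, drop = FALSE], 2L, cs[pos], "/")
  fused_norm[, !pos] <- 1 / k
  list(per_view_membership = u, fused = fused, fused_normalized = fused_norm,
       cluster = column_argmax(fused), centers = z, objective = trace,
       converged = converged, n_iter = length(trace),
       constraint_violation = viol, eta = eta)
}
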