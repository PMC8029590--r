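#' IMV-FCM objective
#'
#' The entropy-regularized multi-view FCM cost
#' `J = sum_v sum_i sum_j sum_t w_vt u_ij,t^m d2_ij,v
#'      + gamma * sum_v sum_t w_vt log(w_vt)`,
#' where `w_vt` is the learned importance of view `t`'s partition inside
#' view `v`'s clustering task and the entropy term (natural log, with
#' `0 log 0 = 0`) keeps the weight rows away from degenerate corners.
#'
#' @param data a [multiview_data] object or list of view matrices.
#' @param centers list of `V` center matrices (`C x p_v`).
#' @param memberships list of `V` column-stochastic `C x N` matrices.
#' @param weights `V x V` row-stochastic weight matrix.
#' @param m fuzzifier, `> 1`.
#' @param gamma entropy-regularization strength, `> 0`.
#' @return Scalar objective value.
#' @export
imv_objective <- function(data, centers, memberships, weights, m = 2, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  data <- as_multiview(data)
  D <- lapply(seq_len(data$n_views), function(v)
    sq_dist(data$views[[v]], centers[[v]]))
  S <- imv_scatter(D, memberships, m)
  sum(weights * S) + gamma * sum(xlogx(weights))
}

xlogx <- function(w) ifelse(w > 0, w * log(w), 0)

# S[v, t] = sum_ij u_ij,t^m d2_ij,v -- the fit of partition t to view v's
# geometry. Shared by the weight update and the objective.
imv_scatter <- function(distances, memberships, m) {
  V <- length(distances)
  um <- lapply(memberships, function(u) u^m)
  S <- matrix(0, V, V)
  for (v in seq_len(V))
    for (t in seq_len(V))
      S[v, t] <- sum(um[[t]] * distances[[v]])
  S
}

#' IMV-FCM center update
#'
#' `z_i,v = sum_j sum_t w_vt u_ij,t^m x_j,v / sum_j sum_t w_vt u_ij,t^m`:
#' each view's centers are weighted means under the view's own mixture of
#' all partitions. With `V = 1` this reduces to the FCM center update.
#'
#' @inheritParams imv_objective
#' @return list of `V` center matrices.
#' @export
imv_update_centers <- function(data, memberships, weights, m = 2) {
  data <- as_multiview(data)
  V <- data$n_views
  um <- lapply(memberships, function(u) u^m)
  lapply(seq_len(V), function(v) {
    g <- Reduce(`+`, Map(`*`, weights[v, ], um))
    weighted_centers_safe(data$views[[v]], g, memberships[[v]])
  })
}

#' IMV-FCM membership update
#'
#' `u_ij,t = 1 / sum_h [ (sum_v w_vt d2_ij,v) / (sum_v w_vt d2_hj,v) ]^(1/(m-1))`:
#' partition `t` clusters on squared distances aggregated over all views
#' with the weights of column `t`. With `V = 1` this is the FCM update.
#'
#' @param distances list of `V` squared-distance matrices (`C x N`).
#' @inheritParams imv_objective
#' @return list of `V` column-stochastic membership matrices.
#' @export
imv_update_memberships <- function(distances, weights, m = 2) {
  V <- length(distances)
  lapply(seq_len(V), function(t) {
    agg <- Reduce(`+`, Map(`*`, weights[, t], distances))
    memberships_from_sqdist(agg, 1 / (m - 1))
  })
}

#' IMV-FCM view-weight update
#'
#' Row `v` of the weight matrix is the softmax over `t` of `-S_vt / gamma`,
#' where `S_vt = sum_ij u_ij,t^m d2_ij,v`: the better partition `t` fits
#' view `v`'s distances, the more weight it gets, with `gamma` acting as the
#' softmax temperature. Evaluated with row-max subtraction so large
#' `S/gamma` cannot underflow to an all-zero row.
#'
#' @inheritParams imv_update_memberships
#' @param gamma entropy-regularization strength, `> 0`.
#' @return `V x V` row-stochastic weight matrix.
#' @export
imv_update_weights <- function(distances, memberships, m = 2, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  S <- imv_scatter(distances, memberships, m)
  t(apply(S, 1L, function(s) {
    e <- exp(-(s - min(s)) / gamma)
    e / sum(e)
  }))
}

#' Weighted-ensemble fusion of per-view partitions
#'
#' The final partition is the weighted average `U = sum_t a_t U_t` with
#' `a_t = sum_v w_vt / V` (the column mass of the weight matrix, normalized
#' by the total mass `V`); crisp labels are the per-column argmax.
#'
#' @param memberships list of `V` column-stochastic `C x N` matrices.
#' @param weights `V x V` row-stochastic weight matrix.
#' @return list with `fused` (`C x N`, column-stochastic), `labels`
#'   (length-`N` integer) and `a` (fusion coefficients, summing to 1).
#' @export
imv_ensemble <- function(memberships, weights) {
  V <- length(memberships)
  a <- colSums(as.matrix(weights)) / V
  fused <- Reduce(`+`, Map(`*`, a, memberships))
  list(fused = fused, labels = column_argmax(fused), a = a)
}

#' Fit IMV-FCM: multi-view fuzzy c-means with adaptive view weights
#'
#' Block-coordinate descent on the entropy-regularized objective: per-view
#' centers, per-view memberships and the view-weight matrix are each updated
#' to their exact constrained minimizer in turn, so the objective is
#' non-increasing across iterations. After convergence the per-view
#' partitions are fused by the weighted ensemble.
#'
#' @param data a [multiview_data] object or list of `N x p_v` matrices.
#' @param k number of clusters.
#' @param m fuzzifier, `> 1` (default 2).
#' @param gamma entropy-regularization strength, `> 0`; default `N` (the
#'   number of samples), which puts the softmax temperature on the scale of
#'   the summed per-sample distortion.
#' @param tol convergence threshold on `|J_(l+1) - J_l|` (default 0.001;
#'   `0` disables so exactly `max_iter` iterations run).
#' @param max_iter maximum iterations (default 100).
#' @param seed optional RNG seed; per-view initial memberships are drawn in
#'   view order.
#' @param init optional list of `V` initial membership matrices.
#' @param weight_init how to initialize the view-weight matrix.
#'   `"anchored"` (default) starts each row at `(1-a) I + a/V` with
#'   `a = 1/2`: view `v`'s task begins with half its weight on its own
#'   partition, which anchors partition `t` to view `t` — the semantics the
#'   weight matrix assumes — and lets the entropy-regularized updates
#'   redistribute importance from there. `"random"` draws each row from the
#'   simplex (seeded). `"uniform"` starts at `1/V` everywhere; note this is
#'   an exact symmetric fixed point of the block updates (every partition
#'   then aggregates identical distances, all per-view partitions coincide
#'   and the weights never move), so it disables the adaptive mechanism and
#'   reduces the fit to an equal-weight multi-view FCM.
#' @return A list with `per_view_membership`, `fused` (column-stochastic),
#'   `cluster`, `centers` (per view), `weights` (`V x V`), `objective`
#'   trace, `converged`, `n_iter`, `constraint_violation`, `gamma`.
#' @examples
#' sim <- generate_mixture_mvd(n = 120, k = 2, v = 2, seed = 1)
#' fit <- imv_fit(sim$data, 2, seed = 1)
#' table(fit$cluster, sim$labels)
#' @export
imv_fit <- function(data, k, m = 2, gamma = NULL, tol = 1e-3, max_iter = 100,
                    seed = NULL, init = NULL,
                    weight_init = c("anchored", "random", "uniform")) {
  data <- as_multiview(data)
  weight_init <- match.arg(weight_init)
  V <- data$n_views
  N <- data$n_samples
  if (k > N) stop("more clusters than samples")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (is.null(gamma)) gamma <- N
  if (gamma <= 0) stop("gamma must be > 0")
  resolve_seed(seed)
  u <- if (is.null(init)) replicate(V, random_membership(k, N), simplify = FALSE)
       else init
  stopifnot(length(u) == V)
  w <- if (V == 1) matrix(1, 1, 1)
       else switch(weight_init,
         anchored = 0.5 * diag(V) + 0.5 / V,
         uniform  = matrix(1 / V, V, V),
         random   = t(replicate(V, { g <- stats::rexp(V); g / sum(g) })))

  trace <- numeric(0)
  J_prev <- Inf
  converged <- FALSE
  viol <- 0
  for (it in seq_len(max_iter)) {
    z <- imv_update_centers(data, u, w, m)
    D <- lapply(seq_len(V), function(v) sq_dist(data$views[[v]], z[[v]]))
    u <- imv_update_memberships(D, w, m)
    w <- imv_update_weights(D, u, m, gamma)
    viol <- max(viol,
                max(vapply(u, function(ui) max(abs(colSums(ui) - 1)),
                           numeric(1))),
                max(abs(rowSums(w) - 1)))
    S <- imv_scatter(D, u, m)
    J <- sum(w * S) + gamma * sum(xlogx(w))
    trace[it] <- J
    if (tol > 0 && abs(J_prev - J) < tol) { converged <- TRUE; break }
    J_prev <- J
  }
  ens <- imv_ensemble(u, w)
  list(per_view_membership = u, fused = ens$fused, cluster = ens$labels,
       fusion_coefficients = ens$a, centers = z, weights = w,
       objective = trace, converged = converged, n_iter = length(trace),
       constraint_violation = viol, gamma = gamma)
}
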