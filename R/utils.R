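# Shared numerical internals for the clustering engines.

# Squared Euclidean distances between C centers (rows of z, C x p) and
# N samples (rows of x, N x p). Returns C x N.
sq_dist <- function(x, z) {
  x <- as.matrix(x); z <- as.matrix(z)
  if (ncol(x) != ncol(z))
    stop("dimension mismatch: data has ", ncol(x),
         " columns but centers have ", ncol(z))
  d <- -2 * tcrossprod(z, x)
  d <- d + rowSums(z^2)
  d <- sweep(d, 2L, rowSums(x^2), "+")
  d[d < 0] <- 0
  d
}

# Column-stochastic memberships from (aggregated) squared distances.
# u_ij = (D_ij)^(-e) / sum_r (D_rj)^(-e), computed through the bounded
# ratio (Dmin_j / D_ij)^e so large exponents cannot overflow. Columns with
# one or more zero distances get the analytic limit: equal split over the
# zero-distance clusters.
memberships_from_sqdist <- function(D, exponent) {
  if (any(D < 0)) stop("squared distances must be nonnegative")
  C <- nrow(D); N <- ncol(D)
  u <- matrix(0, C, N)
  dmin <- apply(D, 2L, min)
  zc <- dmin <= 0
  if (any(!zc)) {
    Dp <- D[, !zc, drop = FALSE]
    W <- sweep(Dp, 2L, dmin[!zc], "/")^(-exponent)
    u[, !zc] <- sweep(W, 2L, colSums(W), "/")
  }
  if (any(zc)) {
    Z <- D[, zc, drop = FALSE] <= 0
    u[, zc] <- sweep(Z * 1, 2L, colSums(Z), "/")
  }
  u
}

# Random column-stochastic C x N matrix, Dirichlet(1, ..., 1) per column
# (uniform on the simplex), drawn from the current RNG stream.
random_membership <- function(C, N) {
  g <- matrix(stats::rexp(C * N), C, N)
  sweep(g, 2L, colSums(g), "/")
}

# u^m-weighted centers with degenerate-cluster re-seeding: a cluster whose
# total weight vanishes is re-seeded at the sample with the lowest maximum
# membership (the sample no cluster claims).
weighted_centers_safe <- function(x, g, u_for_reseed) {
  den <- rowSums(g)
  dead <- den < 1e-12
  z <- matrix(0, nrow(g), ncol(x))
  if (any(!dead))
    z[!dead, ] <- (g[!dead, , drop = FALSE] %*% x) / den[!dead]
  if (any(dead)) {
    j <- order(apply(u_for_reseed, 2L, max))
    j <- j[seq_len(sum(dead))]
    z[dead, ] <- x[j, , drop = FALSE]
  }
  z
}

resolve_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# argmax over clusters for each column of a C x N matrix
column_argmax <- function(m) {
  max.col(t(m), ties.method = "first")
}
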