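# Shared helpers: independent numerical oracles and small fixtures.

# random column-stochastic matrix (uniform Dirichlet per column)
rand_membership <- function(C, N) {
  g <- matrix(rexp(C * N), C, N)
  sweep(g, 2, colSums(g), "/")
}

# Numerical minimizer of sum_i u_i^m * d_i over the probability simplex
# (softmax parameterization + BFGS, multiple starts). Independent of the
# closed-form membership update it is used to check.
simplex_min_membership <- function(d, m, n_starts = 5) {
  C <- length(d)
  obj <- function(a) {
    u <- exp(a - max(a)); u <- u / sum(u)
    sum(u^m * d)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    a0 <- if (s == 1) rep(0, C) else rnorm(C)
    o <- optim(a0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  u <- exp(best$par - max(best$par))
  u / sum(u)
}

# Numerical minimizer of sum_t w_t s_t + gamma * sum_t w_t log w_t over the
# simplex (1-D golden search for V = 2).
simplex_min_weights2 <- function(s, gamma) {
  f <- function(w1) {
    w <- c(w1, 1 - w1)
    sum(w * s) + gamma * sum(ifelse(w > 0, w * log(w), 0))
  }
  o <- optimize(f, c(1e-12, 1 - 1e-12), tol = 1e-12)
  c(o$minimum, 1 - o$minimum)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# mixture with an appended scale-matched pure-noise view
mixture_with_noise_view <- function(seed, n = 300, k = 3) {
  generate_mixture_mvd(n = n, k = k, v = 2, n_noise_views = 1, seed = seed)
}
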