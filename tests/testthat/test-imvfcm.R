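test_that("objective matches hand evaluations", {
  # all points on their centers, uniform weights: only the entropy term
  x <- list(matrix(c(0, 6), 2), matrix(c(1, 3), 2))
  z <- list(matrix(c(0, 6), 2), matrix(c(1, 3), 2))
  u <- list(diag(2), diag(2))
  W <- matrix(0.5, 2, 2)
  gamma <- 1.7
  expect_equal(imv_objective(x, z, u, W, m = 2, gamma = gamma),
               -gamma * 2 * log(2))

  # one-hot weight rows: zero entropy, pure distortion term
  expect_equal(imv_objective(x, z, u, diag(2), m = 2, gamma = gamma), 0)

  # V = 1 reduces to the single-view objective
  x1 <- matrix(rnorm(8), 4)
  z1 <- matrix(rnorm(4), 2)
  u1 <- rand_membership(2, 4)
  expect_equal(imv_objective(list(x1), list(z1), list(u1),
                             matrix(1, 1, 1), m = 2, gamma = 5),
               fcm_objective(x1, z1, u1, 2))

  expect_error(imv_objective(x, z, u, W, m = 2, gamma = 0), "gamma")
})

test_that("center update matches hand evaluation and reductions", {
  x1 <- matrix(c(0, 6), 2)
  x2 <- matrix(c(2, 4), 2)
  u1 <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  u2 <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  W <- rbind(c(0.75, 0.25), c(0.5, 0.5))
  z <- imv_update_centers(list(x1, x2), list(u1, u2), W, m = 2)
  expect_equal(z[[1]][1, 1], 0.42 / 0.64)  # 0.65625

  # V = 1 reduces to the FCM center update
  expect_equal(imv_update_centers(list(x1), list(u1), matrix(1, 1, 1), 2)[[1]],
               fcm_update_centers(x1, u1, 2))

  # uniform weights + equal view memberships reduce per view
  zu <- imv_update_centers(list(x1, x2), list(u1, u1),
                           matrix(0.5, 2, 2), m = 2)
  expect_equal(zu[[1]], fcm_update_centers(x1, u1, 2))
  expect_equal(zu[[2]], fcm_update_centers(x2, u1, 2))
})

test_that("membership update matches hand value and the block optimum", {
  # weighted aggregates (1, 4) -> (0.8, 0.2)
  D <- list(matrix(c(1, 4), 2), matrix(c(1, 4), 2))
  u <- imv_update_memberships(D, matrix(0.5, 2, 2), m = 2)
  expect_equal(u[[1]][1, 1], 0.8)

  # V = 1, any m: exactly the single-view update
  D1 <- matrix(runif(6, 0.1, 2), 3)
  expect_equal(imv_update_memberships(list(D1), matrix(1, 1, 1), 2.5)[[1]],
               fcm_update_memberships(D1, 2.5))

  # equal aggregates -> uniform
  ue <- imv_update_memberships(list(matrix(3, 4, 1)), matrix(1, 1, 1), 2)
  expect_equal(as.vector(ue[[1]]), rep(0.25, 4))

  # closed form equals the numerical constrained minimizer of the block
  set.seed(5)
  W <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  Ds <- list(matrix(runif(8, 0.05, 3), 2), matrix(runif(8, 0.05, 3), 2))
  u <- imv_update_memberships(Ds, W, m = 2)
  for (t in 1:2) {
    agg <- W[1, t] * Ds[[1]] + W[2, t] * Ds[[2]]
    for (j in 1:4)
      expect_equal(u[[t]][, j], simplex_min_membership(agg[, j], 2),
                   tolerance = 1e-6)
  }
})

test_that("weight update is the entropy-regularized softmax", {
  # S row (1, 2), gamma = 1: softmax of (-1, -2)
  u_fix <- list(diag(2), diag(2))
  # engineer distances so S = rbind(c(1, 2), c(2, 1)) exactly:
  # S[v, t] = sum(U_t^m * D_v); with crisp identity memberships S[v, t] =
  # sum of diagonal entries of D_v for t = 1 and off-diagonal for t = 2
  D1 <- rbind(c(1, 0), c(2, 0))   # S[1, 1] = d11 + d22 = 1; S[1, 2] = 2
  D2 <- rbind(c(2, 0), c(1, 0))
  u2 <- list(diag(2), matrix(c(0, 1, 0, 0), 2))  # u2: cluster 2 for sample 1
  S <- mvfcm:::imv_scatter(list(D1, D2), u2, 2)
  expect_equal(S, rbind(c(1, 2), c(2, 1)))
  w <- imv_update_weights(list(D1, D2), u2, m = 2, gamma = 1)
  expect_equal(w[1, ], exp(c(-1, -2)) / sum(exp(c(-1, -2))))
  expect_equal(w[1, 1], 0.73106, tolerance = 1e-5)

  # numerical constrained optimizer agrees
  expect_equal(w[1, ], simplex_min_weights2(c(1, 2), gamma = 1),
               tolerance = 1e-6)

  # equal scatters -> uniform rows; huge gamma -> uniform rows
  w_eq <- imv_update_weights(list(D1, D1), list(diag(2), diag(2)), 2, 1)
  expect_equal(w_eq[1, ], c(0.5, 0.5))
  w_big <- imv_update_weights(list(D1, D2), u2, 2, gamma = 1e9)
  expect_true(all(abs(w_big - 0.5) < 1e-6))

  # overflow safety: huge scatters with tiny gamma stay finite, rows sum 1
  Dh <- list(D1 * 1e8, D2 * 1e8)
  wh <- imv_update_weights(Dh, u2, 2, gamma = 1e-3)
  expect_true(all(is.finite(wh)))
  expect_equal(rowSums(wh), c(1, 1))
  # and concentrate on the row-wise argmin scatter
  expect_true(all(apply(wh, 1, max) >= 1 - 1e-6))
  expect_equal(apply(wh, 1, which.max),
               apply(mvfcm:::imv_scatter(Dh, u2, 2), 1, which.min))
})

test_that("weighted ensemble fuses and labels as specified", {
  u1 <- matrix(c(0.6, 0.4), 2)
  u2 <- matrix(c(0.3, 0.7), 2)
  ens <- imv_ensemble(list(u1, u2), matrix(0.5, 2, 2))
  expect_equal(as.vector(ens$fused), c(0.45, 0.55))
  expect_equal(ens$labels, 2L)
  expect_equal(sum(ens$a), 1)

  # V = 1: identity
  e1 <- imv_ensemble(list(u1), matrix(1, 1, 1))
  expect_equal(e1$fused, u1)

  # fused matrix stays column-stochastic for stochastic inputs
  set.seed(8)
  us <- list(rand_membership(3, 5), rand_membership(3, 5))
  W <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  ef <- imv_ensemble(us, W)
  expect_equal(colSums(ef$fused), rep(1, 5))
})

test_that("V = 1 fit reduces exactly to FCM from the same initialization", {
  set.seed(12)
  x <- matrix(rnorm(100), 50)
  u0 <- rand_membership(3, 50)
  fa <- fcm_fit(x, 3, init = u0)
  fb <- imv_fit(list(x), 3, init = list(u0))
  expect_lt(max(abs(fa$membership - fb$per_view_membership[[1]])), 1e-8)
  expect_equal(fa$cluster, fb$cluster)
})

test_that("objective is non-increasing and constraints conserved", {
  set.seed(13)
  for (rep in 1:5) {
    sim <- generate_mixture_mvd(n = 80, k = 3, v = 3, seed = 40 + rep)
    f <- imv_fit(sim$data, 3, seed = rep, tol = 0, max_iter = 25)
    expect_true(all(diff(f$objective) <= 1e-10))
    expect_lt(f$constraint_violation, 1e-9)
  }
})

test_that("fits are deterministic and equivariant to view permutation", {
  sim <- generate_mixture_mvd(n = 60, k = 2, v = 3, seed = 50)
  f1 <- imv_fit(sim$data, 2, seed = 5)
  f2 <- imv_fit(sim$data, 2, seed = 5)
  expect_identical(f1, f2)

  # permuting views permutes per-view results and the weight matrix
  perm <- c(2, 3, 1)
  u0 <- replicate(3, rand_membership(2, 60), simplify = FALSE)
  fa <- imv_fit(sim$data, 2, init = u0, weight_init = "anchored",
                gamma = 50, tol = 0, max_iter = 10)
  fb <- imv_fit(multiview_data(sim$data$views[perm]), 2, init = u0[perm],
                weight_init = "anchored", gamma = 50, tol = 0, max_iter = 10)
  expect_equal(fb$centers, fa$centers[perm])
  expect_equal(fb$weights, fa$weights[perm, perm])
  expect_equal(fb$per_view_membership, fa$per_view_membership[perm])
})

test_that("IMV-FCM recovers well-separated multi-view mixtures", {
  sim <- generate_mixture_mvd(n = 200, k = 3, v = 2, seed = 61)
  f <- imv_fit(sim$data, 3, seed = 61)
  expect_gte(ari(f$cluster, sim$labels), 0.95)
})
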