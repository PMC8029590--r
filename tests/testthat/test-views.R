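test_that("gradient view matches the Sobel oracle", {
  expect_lt(max(gradient_view(matrix(0.4, 8, 8))), 1e-12)

  # horizontal ramp v(r, c) = c: interior Sobel-x response (1+2+1)*2 = 8
  ramp <- matrix(rep(1:7, each = 7), 7)  # value = column index
  g <- matrix(gradient_view(ramp), 7, byrow = TRUE)
  expect_true(all(g[2:6, 2:6] == 8))

  # transposition swaps Gx and Gy; the magnitude map transposes
  set.seed(1)
  img <- matrix(runif(49), 7)
  g1 <- matrix(gradient_view(img), 7, byrow = TRUE)
  g2 <- matrix(gradient_view(t(img)), 7, byrow = TRUE)
  expect_equal(g2, t(g1))
})

test_that("entropy view matches the histogram oracle", {
  expect_true(all(entropy_view(matrix(0.3, 6, 6), 1) == 0))

  # 3x3 window split 4/5 between two gray levels
  img <- matrix(c(10, 10, 10, 10, 40, 40, 40, 40, 40) / 255, 3)
  e <- matrix(entropy_view(img, 1), 3, byrow = TRUE)
  expect_equal(e[2, 2], -(4 / 9) * log2(4 / 9) - (5 / 9) * log2(5 / 9),
               tolerance = 1e-9)
  expect_equal(e[2, 2], 0.99108, tolerance = 1e-5)

  # uniform bound: entropy <= log2(window pixel count)
  set.seed(2)
  noisy <- matrix(runif(100), 10)
  expect_true(all(entropy_view(noisy, 2) <= log2(25) + 1e-12))
})

test_that("contrast view is the window range", {
  expect_true(all(contrast_view(matrix(0.7, 6, 6), 2) == 0))

  edge <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  co <- matrix(contrast_view(edge, 1), 6, byrow = TRUE)
  expect_true(all(co[, 3:4] == 1))  # windows straddling the edge
  expect_true(all(co[, 1] == 0))

  img <- matrix(seq(10, 90, by = 10), 3)  # 3x3 with values 10..90
  co3 <- matrix(contrast_view(img, 1), 3, byrow = TRUE)
  expect_equal(co3[2, 2], 80)
})

test_that("HOG view produces normalized orientation histograms", {
  h0 <- hog_view(matrix(0.5, 8, 8), 1, 9)
  expect_true(all(h0 == 0))  # no gradient anywhere

  # vertical edge: gradient along x, orientation 0 degrees -> first bin
  edge <- cbind(matrix(0, 9, 4), matrix(1, 9, 5))
  h <- hog_view(edge, 1, 9)
  active <- which(rowSums(h) > 0)
  expect_true(length(active) > 0)
  expect_true(all(abs(sqrt(rowSums(h[active, , drop = FALSE]^2)) - 1) < 1e-9))
  expect_true(all(h[active, 2:9] == 0))  # all mass in the 0-degree bin

  # rotating the image 90 degrees moves the mass to the bin 90 degrees away
  rot <- t(edge)[, ncol(t(edge)):1]  # 90-degree rotation
  hr <- hog_view(rot, 1, 9)
  activer <- which(rowSums(hr) > 0)
  # 90 degrees falls in bin 5 ([80, 100))
  expect_true(all(hr[activer, setdiff(1:9, 5)] == 0))
  expect_true(all(hr[activer, 5] > 0))
})

test_that("build_multiview assembles, z-scores and records the shape", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64)

  mv <- build_multiview(img, views = c("hog", "entropy", "gradient",
                                       "contrast"))
  expect_equal(mv$n_views, 4)
  expect_equal(mv$n_samples, 4096)
  expect_equal(vapply(mv$views, ncol, integer(1)),
               c(hog = 9L, entropy = 1L, gradient = 1L, contrast = 1L))
  expect_equal(mv$sample_shape, c(64L, 64L))
  # z-scored dimensions
  expect_lt(max(abs(vapply(mv$views, function(v) mean(v[, 1]), numeric(1)))),
            1e-12)

  one <- build_multiview(img, views = "intensity")
  expect_equal(one$n_views, 1)
  expect_equal(as.vector(one$views[[1]]),
               as.vector(scale(as.vector(t(img)))))

  # duplicated specs give identical views
  two <- build_multiview(img, views = c("gradient", "gradient"))
  expect_identical(two$views[[1]], two$views[[2]])

  expect_error(build_multiview(img, views = character(0)), "disabled")
})

test_that("features are translation-consistent in the interior", {
  set.seed(4)
  base <- matrix(runif(400), 20)
  shifted <- base
  shifted[, 2:20] <- base[, 1:19]  # shift content right by one column

  for (fun in list(function(i) gradient_view(i),
                   function(i) entropy_view(i, 2),
                   function(i) contrast_view(i, 2))) {
    f1 <- matrix(fun(base), 20, byrow = TRUE)
    f2 <- matrix(fun(shifted), 20, byrow = TRUE)
    # interior (margin 4 > window radius + sobel support)
    expect_equal(f2[5:16, 6:16], f1[5:16, 5:15])
  }
})

test_that("median filter removes isolated impulse noise", {
  img <- matrix(0.5, 9, 9)
  img[5, 5] <- 1
  expect_equal(median_filter3(img), matrix(0.5, 9, 9))
})
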