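# Synthetic data: brain-like 4-class phantom images and tabular multi-view
# Gaussian mixtures with known labels.

#' Generate a brain-like 4-class phantom image
#'
#' Builds a deterministic (given its seeds) 2D phantom with the nested
#' structure of an axial T1 brain slice: an elliptical head whose outline is
#' perturbed by low-frequency sinusoids, an outer gray-matter band, a
#' cerebrospinal-fluid ribbon between the band and the white-matter
#' interior (whose boundary carries higher-frequency folds), two ventricle
#' blobs of CSF inside the white matter, and zero background. Every pixel's
#' clean intensity is exactly its class mean, so the noiseless histogram has
#' support on the four class means only.
#'
#' Classes are labeled 1 = background, 2 = CSF, 3 = GM, 4 = WM. The default
#' means follow the T1-weighted gray-level ordering (CSF dark, GM gray,
#' WM bright).
#'
#' @param size `c(H, W)`, at least 32 in each dimension (default 128 x 128).
#' @param means named numeric vector of class gray levels (8-bit scale),
#'   `c(background, csf, gm, wm)`; must be distinct.
#' @param noise_percent Gaussian noise level as a percent of the full
#'   intensity range (see [add_gaussian_noise()]); 0 for a clean phantom.
#' @param geometry_seed seed for the boundary-perturbation phases.
#' @param noise_seed seed for the noise field.
#' @return List with `image` (`H x W`, 8-bit scale gray values), `labels`
#'   (`H x W` integer matrix, values 1-4), `means`, `noise_percent`.
#' @examples
#' ph <- generate_phantom(size = c(64, 64))
#' table(ph$labels)
#' @export
generate_phantom <- function(size = c(128, 128),
                             means = c(background = 0, csf = 70,
                                       gm = 130, wm = 200),
                             noise_percent = 0,
                             geometry_seed = 1, noise_seed = 1) {
  size <- as.integer(size)
  if (any(size < 32)) stop("phantom must be at least 32 x 32")
  if (length(means) != 4 || anyDuplicated(means))
    stop("means must be 4 distinct class gray levels")
  H <- size[1]; W <- size[2]
  set.seed(geometry_seed)
  phi <- stats::runif(4, 0, 2 * pi)

  r0 <- (H + 1) / 2; c0 <- (W + 1) / 2
  Ar <- 0.44 * H; Ac <- 0.40 * W
  rr <- matrix((row(matrix(0, H, W)) - r0) / Ar, H, W)
  cc <- matrix((col(matrix(0, H, W)) - c0) / Ac, H, W)
  e <- sqrt(rr^2 + cc^2)
  theta <- atan2(rr, cc)

  outer_pert <- 1 + 0.04 * sin(3 * theta + phi[1]) +
                    0.03 * sin(5 * theta + phi[2])
  f <- e / outer_pert
  # higher-frequency folds on the inner (cortical) boundaries
  f2 <- f + 0.05 * sin(8 * theta + phi[3]) + 0.03 * sin(11 * theta + phi[4])

  labels <- matrix(1L, H, W)              # background
  labels[f <= 1 & f2 > 0.78] <- 3L        # GM band
  labels[f <= 1 & f2 <= 0.78 & f2 > 0.70] <- 2L  # CSF ribbon
  labels[f <= 1 & f2 <= 0.70] <- 4L       # WM interior

  # ventricles: two small CSF ellipses inside the WM
  for (s in c(-1, 1)) {
    vr <- r0 - 0.02 * H; vc <- c0 + s * 0.10 * W
    ev <- ((row(labels) - vr) / (0.10 * H))^2 +
          ((col(labels) - vc) / (0.045 * W))^2
    labels[ev <= 1 & labels == 4L] <- 2L
  }

  image <- matrix(means[labels], H, W)
  if (noise_percent > 0)
    image <- add_gaussian_noise(image, noise_percent, seed = noise_seed,
                                range = 255)
  list(image = image, labels = labels, means = means,
       noise_percent = noise_percent)
}

#' Add Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `percent/100 * range`, where `range` is the full intensity range (255
#' for 8-bit images, 1 for normalized ones), then clips to the valid range.
#' At the higher levels the clipping slightly truncates the noise tails.
#'
#' @param image numeric matrix.
#' @param percent noise level, `>= 0` (e.g. 3, 5, 7, 9).
#' @param seed optional RNG seed for the noise field.
#' @param range full intensity range; default 255 if any value exceeds 1,
#'   else 1.
#' @return Noisy image matrix (identical to the input when `percent = 0`).
#' @export
add_gaussian_noise <- function(image, percent, seed = NULL, range = NULL) {
  if (percent < 0) stop("noise percent must be >= 0")
  image <- as.matrix(image)
  if (percent == 0) return(image)
  if (is.null(range)) range <- if (max(image) > 1) 255 else 1
  resolve_seed(seed)
  out <- image + stats::rnorm(length(image), 0, percent / 100 * range)
  out[out < 0] <- 0
  out[out > range] <- range
  matrix(out, nrow(image), ncol(image))
}

#' Generate a multi-view Gaussian-mixture dataset with known labels
#'
#' Parameter-recovery fixture: each sample draws one latent class from the
#' mixing proportions; every informative view then draws from that class's
#' Gaussian, while pure-noise views draw class-independent standard
#' Gaussians. Default informative views are one-dimensional with class
#' means `0, sep*sd, 2*sep*sd, ...` — adjacent classes separated by
#' `sep` standard deviations (default 5, making classes essentially
#' linearly separable in every informative view).
#'
#' @param n number of samples (default 300).
#' @param k number of clusters (default 3).
#' @param v number of informative views (default 2).
#' @param dim_per_view dimension of each informative view (default 1).
#' @param sep separation between adjacent class means, in units of `sd`.
#' @param sd within-class standard deviation (default 1).
#' @param n_noise_views number of pure-noise views appended after the
#'   informative ones (default 0).
#' @param noise_sd standard deviation of the pure-noise views; defaults to
#'   the marginal standard deviation of an informative view,
#'   `sd * sqrt(1 + sep^2 (k^2 - 1) / 12)`, so a noise view is a
#'   scale-commensurate nuisance rather than a trivially ignorable one.
#' @param proportions mixing proportions (default uniform).
#' @param seed optional RNG seed.
#' @return List with `data` (a [multiview_data]) and `labels` (integer
#'   vector in `1..k`).
#' @export
generate_mixture_mvd <- function(n = 300, k = 3, v = 2, dim_per_view = 1,
                                 sep = 5, sd = 1, n_noise_views = 0,
                                 noise_sd = NULL, proportions = NULL,
                                 seed = NULL) {
  if (k > n) stop("more clusters than samples")
  if (sd <= 0) stop("sd must be positive")
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("mixing proportions must sum to 1")
  if (is.null(noise_sd))
    noise_sd <- sd * sqrt(1 + sep^2 * (k^2 - 1) / 12)
  resolve_seed(seed)
  labels <- sample.int(k, n, replace = TRUE, prob = proportions)
  class_means <- (seq_len(k) - 1) * sep * sd
  views <- c(
    lapply(seq_len(v), function(.)
      matrix(stats::rnorm(n * dim_per_view, mean = class_means[labels],
                          sd = sd), n, dim_per_view)),
    lapply(seq_len(n_noise_views), function(.)
      matrix(stats::rnorm(n * dim_per_view, sd = noise_sd), n, dim_per_view))
  )
  list(data = multiview_data(views), labels = labels)
}

#' Export a mixture dataset as CSV files
#'
#' Writes one CSV per view (`view1.csv`, ...) plus `labels.csv` into a
#' directory.
#'
#' @param mixture list as returned by [generate_mixture_mvd()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mixture_csv <- function(mixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in seq_along(mixture$data$views))
    utils::write.csv(mixture$data$views[[v]],
                     file.path(dir, sprintf("view%d.csv", v)),
                     row.names = FALSE)
  utils::write.csv(data.frame(label = mixture$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
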