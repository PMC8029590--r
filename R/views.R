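# Dense per-pixel feature views for grayscale images.
#
# Pixel (r, c) of an H x W image maps to sample index (r-1)*W + c
# (row-major), so feature maps are flattened with as.vector(t(m)).

flatten_rowmajor <- function(m) as.vector(t(m))

unflatten_rowmajor <- function(v, shape) {
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

check_image <- function(image) {
  image <- as.matrix(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("image must be at least 3 x 3")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  image
}

# mirror padding (edge row/column included in the reflection)
pad_reflect <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(pmin(r:1, H), 1:H, H - pmin(1:r, H) + 1L)
  ci <- c(pmin(r:1, W), 1:W, W - pmin(1:r, W) + 1L)
  m[ri, ci, drop = FALSE]
}

# 3x3 correlation with reflect padding
conv3 <- function(m, kernel) {
  p <- pad_reflect(m, 1L)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (di in 0:2)
    for (dj in 0:2)
      if (kernel[di + 1, dj + 1] != 0)
        out <- out + kernel[di + 1, dj + 1] * p[di + 1:H, dj + 1:W]
  out
}

sobel_xy <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  list(gx = conv3(image, kx), gy = conv3(image, t(kx)))
}

# moving-window sum with reflect padding, via cumulative sums
box_sum <- function(m, r) {
  k <- 2L * r + 1L
  run_cols <- function(p) {
    cs <- rbind(0, apply(p, 2L, cumsum))
    cs[(k + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - k), , drop = FALSE]
  }
  p <- pad_reflect(m, r)
  t(run_cols(t(run_cols(p))))
}

# stack of all (2r+1)^2 window-shifted copies; rows = pixels (row-major),
# columns = window offsets
shift_stack <- function(image, r) {
  p <- pad_reflect(image, r)
  H <- nrow(image); W <- ncol(image)
  k <- 2L * r + 1L
  out <- matrix(0, H * W, k * k)
  col <- 0L
  for (di in seq_len(k))
    for (dj in seq_len(k)) {
      col <- col + 1L
      out[, col] <- flatten_rowmajor(p[di - 1L + 1:H, dj - 1L + 1:W])
    }
  out
}

#' Gradient-magnitude feature view
#'
#' Per-pixel Sobel gradient magnitude `sqrt(Gx^2 + Gy^2)` (3x3 kernels,
#' reflect-padded borders).
#'
#' @param image numeric matrix `H x W`.
#' @return `N x 1` matrix in row-major pixel order (`N = H * W`).
#' @export
gradient_view <- function(image) {
  image <- check_image(image)
  g <- sobel_xy(image)
  matrix(flatten_rowmajor(sqrt(g$gx^2 + g$gy^2)), ncol = 1)
}

#' Local-entropy feature view
#'
#' Per-pixel Shannon entropy (bits) of the 256-level gray histogram in the
#' `(2r+1)^2` window around each pixel, reflect-padded. Images on `[0, 1]`
#' are quantized to 256 levels; 8-bit images are used as-is.
#'
#' @param image numeric matrix `H x W`.
#' @param window_radius window radius `r >= 1` (default 3, a 7x7 window).
#' @return `N x 1` matrix in row-major pixel order.
#' @export
entropy_view <- function(image, window_radius = 3) {
  image <- check_image(image)
  q <- quantize256(image)
  M <- shift_stack(q, window_radius)
  K <- ncol(M)
  ent <- apply(M, 1L, function(v) {
    tb <- tabulate(v + 1L, 256L)
    p <- tb[tb > 0L] / K
    -sum(p * log2(p))
  })
  matrix(ent, ncol = 1)
}

quantize256 <- function(image) {
  if (max(image) <= 1 && min(image) >= 0) image <- image * 255
  q <- floor(image)
  q[q < 0] <- 0; q[q > 255] <- 255
  storage.mode(q) <- "integer"
  q
}

#' Local-contrast feature view
#'
#' Per-pixel contrast = (max - min) of the gray values in the `(2r+1)^2`
#' window, reflect-padded.
#'
#' @inheritParams entropy_view
#' @return `N x 1` matrix in row-major pixel order.
#' @export
contrast_view <- function(image, window_radius = 3) {
  image <- check_image(image)
  M <- shift_stack(image, window_radius)
  hi <- do.call(pmax, as.data.frame(M))
  lo <- do.call(pmin, as.data.frame(M))
  matrix(hi - lo, ncol = 1)
}

#' Dense HOG feature view
#'
#' Per-pixel descriptor: the gradient-magnitude-weighted histogram of
#' unsigned gradient orientation (`[0, 180)` degrees, `n_bins` bins) over
#' the `(2r+1)^2` window, L2-normalized per pixel (all-zero descriptors are
#' left as zeros).
#'
#' @inheritParams entropy_view
#' @param n_bins number of orientation bins (default 9).
#' @return `N x n_bins` matrix in row-major pixel order.
#' @export
hog_view <- function(image, window_radius = 3, n_bins = 9) {
  image <- check_image(image)
  if (n_bins < 2) stop("n_bins must be >= 2")
  g <- sobel_xy(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  theta <- (atan2(g$gy, g$gx) * 180 / pi) %% 180
  bin <- pmin(floor(theta / (180 / n_bins)), n_bins - 1) + 1L
  desc <- matrix(0, length(image), n_bins)
  for (b in seq_len(n_bins)) {
    mb <- mag * (bin == b)
    desc[, b] <- flatten_rowmajor(box_sum(mb, window_radius))
  }
  nrm <- sqrt(rowSums(desc^2))
  # descriptors that are numerically zero (flat windows) are left at zero
  pos <- nrm > 1e-12
  desc[!pos, ] <- 0
  desc[pos, ] <- desc[pos, , drop = FALSE] / nrm[pos]
  desc
}

#' 3x3 median filter
#'
#' Optional denoising preprocessing step for the image-segmentation
#' pipeline (reflect-padded).
#'
#' @param image numeric matrix.
#' @return Filtered matrix of the same shape.
#' @export
median_filter3 <- function(image) {
  image <- check_image(image)
  M <- shift_stack(image, 1L)
  med <- apply(M, 1L, stats::median)
  unflatten_rowmajor(med, dim(image))
}

#' View specification
#'
#' Describes one feature view for [build_multiview()].
#'
#' @param name one of `"intensity"`, `"hog"`, `"entropy"`, `"gradient"`,
#'   `"contrast"`.
#' @param window_radius window radius for windowed features (default 3).
#' @param n_bins HOG orientation bins (default 9).
#' @param enabled logical.
#' @return A list of class `view_spec`.
#' @export
view_spec <- function(name, window_radius = 3, n_bins = 9, enabled = TRUE) {
  name <- match.arg(name,
                    c("intensity", "hog", "entropy", "gradient", "contrast"))
  if (window_radius < 1) stop("window_radius must be >= 1")
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(name = name, window_radius = window_radius,
                 n_bins = n_bins, enabled = isTRUE(enabled)),
            class = "view_spec")
}

#' Build multi-view data from a grayscale image
#'
#' Extracts the enabled feature views (raw intensity, dense HOG, local
#' entropy, gradient magnitude, local contrast), flattens each to `N = H*W`
#' rows in row-major pixel order, and z-scores every feature dimension
#' (zero-variance dimensions are set to 0) so that Euclidean distances are
#' commensurate across views. The image is rescaled to `[0, 1]` first
#' (values above 1 are treated as 8-bit and divided by 255).
#'
#' @param image numeric matrix `H x W` (gray values in `[0, 1]` or 8-bit).
#' @param views character vector naming the enabled views, or a list of
#'   [view_spec()] objects. Default: all five.
#' @param window_radius shared window radius for windowed features.
#' @param n_bins HOG orientation bins.
#' @param denoise apply the 3x3 median filter before feature extraction
#'   (default `FALSE`).
#' @param zscore z-score each feature dimension (default `TRUE`).
#' @return A [multiview_data] object with `sample_shape = dim(image)` and
#'   named views.
#' @examples
#' img <- matrix(rep(c(0, 1), each = 32), 8)
#' build_multiview(img, views = c("intensity", "gradient"))
#' @export
build_multiview <- function(image,
                            views = c("intensity", "hog", "entropy",
                                      "gradient", "contrast"),
                            window_radius = 3, n_bins = 9,
                            denoise = FALSE, zscore = TRUE) {
  image <- check_image(image)
  if (is.list(views)) {
    specs <- Filter(function(s) s$enabled, views)
    if (length(specs) == 0) stop("all views are disabled")
  } else {
    if (length(views) == 0) stop("all views are disabled")
    specs <- lapply(views, view_spec,
                    window_radius = window_radius, n_bins = n_bins)
  }
  if (max(image) > 1) image <- image / 255
  if (denoise) image <- median_filter3(image)

  feats <- lapply(specs, function(s) {
    switch(s$name,
      intensity = matrix(flatten_rowmajor(image), ncol = 1),
      hog       = hog_view(image, s$window_radius, s$n_bins),
      entropy   = entropy_view(image, s$window_radius),
      gradient  = gradient_view(image),
      contrast  = contrast_view(image, s$window_radius))
  })
  names(feats) <- vapply(specs, `[[`, character(1), "name")
  if (zscore) feats <- lapply(feats, zscore_columns)
  multiview_data(feats, sample_shape = dim(image))
}

zscore_columns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  out <- sweep(m, 2L, mu, "-")
  pos <- sd > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2L, sd[pos], "/")
  out[, !pos] <- 0
  out
}

#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG (multi-channel PNGs are converted by
#' luminance averaging) or a single 2D slice of a NIfTI volume (requires
#' the RNifti package).
#'
#' @param path file path (`.png`, `.nii` or `.nii.gz`).
#' @param slice_axis axis along which to slice a NIfTI volume (1-3).
#' @param slice_index slice index along `slice_axis`.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path, slice_axis = 3, slice_index = 1) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                            c(1, 2), mean)
    return(img)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI images requires the RNifti package")
    vol <- RNifti::readNifti(path)
    vol <- as.array(vol)
    if (length(dim(vol)) == 2) img <- vol
    else img <- switch(slice_axis,
                       vol[slice_index, , ],
                       vol[, slice_index, ],
                       vol[, , slice_index])
    img <- as.matrix(img)
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
    return(img)
  }
  stop("unsupported image format: ", path)
}

#' Write a grayscale image or label map as PNG
#'
#' @param image numeric matrix; values in `[0, 1]`, 8-bit values, or
#'   integer labels when `labels = TRUE`.
#' @param path output path.
#' @param labels treat `image` as an integer label map and spread the label
#'   range over `[0, 1]` gray levels.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path, labels = FALSE) {
  m <- as.matrix(image)
  if (labels) m <- (m - min(m)) / max(1, diff(range(m)))
  else if (max(m) > 1) m <- m / 255
  m[m < 0] <- 0; m[m > 1] <- 1
  png::writePNG(m, path)
  invisible(path)
}
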