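# End-to-end image segmentation pipeline, grid search and the
# noise-robustness experiment harness.

#' Segment a grayscale image
#'
#' Reproduces the two study flows: the single-view baseline (`"fcm"`)
#' clusters the raw intensity view only, while the multi-view methods
#' (`"imvfcm"`, `"cofkm"`) first denoise (3x3 median, on by default for
#' them), construct the dense feature views, and cluster the resulting
#' multi-view data. When reference labels are supplied, a per-class
#' Jaccard/Dice/ME report is computed after optimal label alignment.
#'
#' @param image numeric `H x W` matrix (gray values in `[0, 1]` or 8-bit),
#'   or a path accepted by [read_gray_image()].
#' @param algorithm `"imvfcm"` (default), `"cofkm"` or `"fcm"`.
#' @param k number of clusters (default 4: background, CSF, GM, WM).
#' @param reference optional reference label map (`H x W` matrix or
#'   length-`N` vector, 1-based classes).
#' @param views enabled feature views for the multi-view methods.
#' @param window_radius window radius for windowed features.
#' @param denoise apply the median filter before feature extraction;
#'   default `TRUE` for multi-view methods, `FALSE` for `"fcm"`.
#' @param m,gamma,eta,tol,max_iter,seed passed to [mvfcm()].
#' @param background reference class excluded from the mean metric row
#'   (default 1).
#' @param out_dir optional directory: writes the label map PNG, the fused
#'   membership dump, the metrics report and a run manifest.
#' @return List with `fit` (the [mvfcm] object), `label_map` (`H x W`
#'   integer matrix) and `metrics` (data.frame or `NULL`).
#' @examples
#' ph <- generate_phantom(size = c(64, 64))
#' seg <- segment_image(ph$image, "fcm", k = 4, reference = ph$labels,
#'                      seed = 1)
#' seg$metrics
#' @export
segment_image <- function(image, algorithm = c("imvfcm", "cofkm", "fcm"),
                          k = 4, reference = NULL,
                          views = c("intensity", "hog", "entropy",
                                    "gradient", "contrast"),
                          window_radius = 3, denoise = NULL,
                          m = 2, gamma = NULL, eta = NULL, tol = 1e-3,
                          max_iter = 100, seed = 1, background = 1,
                          out_dir = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.character(image)) image <- read_gray_image(image)
  image <- check_image(image)
  if (is.null(denoise)) denoise <- algorithm != "fcm"
  if (algorithm == "fcm") views <- "intensity"
  data <- build_multiview(image, views = views,
                          window_radius = window_radius, denoise = denoise)
  fit <- mvfcm(data, k, method = algorithm, m = m, gamma = gamma, eta = eta,
               tol = tol, max_iter = max_iter, seed = seed)
  lm <- label_map(fit)

  metrics <- NULL
  if (!is.null(reference)) {
    ref <- if (is.matrix(reference)) flatten_rowmajor(reference)
           else as.integer(reference)
    if (length(ref) != fit$n_samples)
      stop("reference labels have length ", length(ref),
           " but the image has ", fit$n_samples, " pixels")
    metrics <- evaluate_segmentation(fit$cluster, ref, k,
                                     background = background)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gray_png(lm, file.path(out_dir, "labels.png"), labels = TRUE)
    utils::write.csv(fit$membership,
                     file.path(out_dir, "fused_membership.csv"),
                     row.names = FALSE)
    if (!is.null(metrics))
      write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    write_manifest(file.path(out_dir, "manifest.json"), list(
      command = "segment", algorithm = algorithm, k = k, m = m,
      gamma = fit$gamma, eta = fit$eta, tol = tol, max_iter = max_iter,
      seed = seed, views = views, window_radius = window_radius,
      denoise = denoise, image_size = dim(image)))
  }
  list(fit = fit, label_map = lm, metrics = metrics)
}

write_manifest <- function(path, params) {
  params$package_version <- as.character(utils::packageVersion("mvfcm"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default grid-search ranges
#'
#' The study's grid ranges: fuzzifier `m` over
#' `{1.05, 1.1, 1.2, ..., 2}` for every method; `gamma` over `2^(-12..12)`
#' for the adaptive method; `eta` over 11 equispaced points of
#' `[0, (V-1)/V]` for CoFKM.
#'
#' @param algorithm method name.
#' @param v number of views (needed for the `eta` range).
#' @return Named list of parameter grids.
#' @export
default_grids <- function(algorithm = c("imvfcm", "cofkm", "fcm"), v = 2) {
  algorithm <- match.arg(algorithm)
  m_grid <- c(1.05, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2)
  switch(algorithm,
    fcm = list(m = m_grid),
    cofkm = list(m = m_grid, eta = seq(0, (v - 1) / v, length.out = 11)),
    imvfcm = list(m = m_grid, gamma = 2^(-12:12)))
}

#' Exhaustive grid search over clustering parameters
#'
#' Evaluates every combination of the supplied parameter grids on one
#' image (or pre-built multi-view data). With reference labels the score is
#' the mean foreground Jaccard index after label alignment (higher is
#' better); without labels the partition coefficient of the fused partition
#' is used. Deterministic for a fixed seed: every configuration is fitted
#' from the same seeded initialization.
#'
#' @param x image matrix or [multiview_data] object.
#' @param algorithm method name.
#' @param grids named list of parameter vectors; allowed names: `m`,
#'   `gamma`, `eta`. Defaults to [default_grids()] for the method.
#' @param reference optional reference labels (matrix or vector).
#' @param k number of clusters.
#' @param seed RNG seed shared by all fits.
#' @param background reference class excluded from the mean Jaccard.
#' @param ... further arguments to [segment_image()] / [mvfcm()]
#'   (`tol`, `max_iter`, `views`, ...).
#' @return List with `best` (one-row data.frame) and `results` (one row per
#'   configuration, with its score).
#' @export
grid_search <- function(x, algorithm = c("imvfcm", "cofkm", "fcm"),
                        grids = NULL, reference = NULL, k = 4, seed = 1,
                        background = 1, ...) {
  algorithm <- match.arg(algorithm)
  is_image <- is.matrix(x) && !inherits(x, "multiview_data")
  if (is_image) {
    args <- list(...)
    data <- build_multiview(x,
      views = if (algorithm == "fcm") "intensity"
              else args$views %||% c("intensity", "hog", "entropy",
                                     "gradient", "contrast"),
      window_radius = args$window_radius %||% 3,
      denoise = args$denoise %||% (algorithm != "fcm"))
  } else data <- as_multiview(x)
  if (is.null(grids)) grids <- default_grids(algorithm, data$n_views)
  allowed <- c("m", "gamma", "eta")
  if (length(grids) == 0 || any(!nzchar(names(grids))))
    stop("grids must be a named, non-empty list")
  bad <- setdiff(names(grids), allowed)
  if (length(bad) > 0)
    stop("unknown grid parameter(s): ", paste(bad, collapse = ", "))
  configs <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)

  ref <- NULL
  if (!is.null(reference))
    ref <- if (is.matrix(reference)) flatten_rowmajor(reference)
           else as.integer(reference)

  fit_args <- list(...)
  fit_args <- fit_args[names(fit_args) %in%
                         c("tol", "max_iter", "init", "weight_init")]
  scores <- vapply(seq_len(nrow(configs)), function(i) {
    cfg <- as.list(configs[i, , drop = FALSE])
    fit <- do.call(mvfcm, c(list(data, k, method = algorithm, seed = seed),
                            cfg, fit_args))
    if (!is.null(ref))
      evaluate_segmentation(fit$cluster, ref, k, background = background) |>
        (\(df) df$js[df$class == "mean"])()
    else partition_coefficient(fit$membership)
  }, numeric(1))
  results <- cbind(configs, score = scores)
  list(best = results[which.max(scores), , drop = FALSE], results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise-robustness experiment on synthetic phantoms
#'
#' For each replicate seed, generates a phantom, adds Gaussian noise at
#' each level, segments with each algorithm, and records the mean
#' foreground Jaccard and Dice scores. The summary reports, per algorithm
#' and level, the across-seed means plus the drop rate relative to the
#' 0%-noise baseline (`(JS_0 - JS) / JS_0 * 100`).
#'
#' @param levels noise levels in percent; must include 0 (the baseline).
#' @param algorithms methods to compare.
#' @param n_seeds number of replicate phantoms per level.
#' @param size phantom size `c(H, W)`.
#' @param k number of clusters.
#' @param seed base seed; replicate `i` uses geometry seed `seed + i` and
#'   a distinct noise seed.
#' @param out_dir optional directory for the CSV results, degradation-curve
#'   plot and run manifest.
#' @param ... further arguments to [segment_image()] (e.g. `gamma`, `m`,
#'   `max_iter`, `window_radius`).
#' @return List with `runs` (one row per algorithm x level x seed) and
#'   `summary` (across-seed means with drop rates).
#' @export
noise_experiment <- function(levels = c(0, 3, 5, 7, 9),
                             algorithms = c("fcm", "imvfcm"),
                             n_seeds = 10, size = c(128, 128), k = 4,
                             seed = 1, out_dir = NULL, ...) {
  if (!0 %in% levels) stop("levels must include 0 for baselining")
  rows <- list()
  for (i in seq_len(n_seeds)) {
    ph <- generate_phantom(size = size, geometry_seed = seed + i)
    for (lev in levels) {
      img <- add_gaussian_noise(ph$image, lev,
                                seed = seed + 10000L + 100L * i + lev,
                                range = 255)
      for (alg in algorithms) {
        sg <- segment_image(img, alg, k = k, reference = ph$labels,
                            seed = seed + i, ...)
        mrow <- sg$metrics[sg$metrics$class == "mean", ]
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, level = lev, seed = seed + i,
          mean_js = mrow$js, mean_dsc = mrow$dsc)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(mean_js, mean_dsc) ~ algorithm + level,
                              data = runs, FUN = mean)
  summary <- summary[order(summary$algorithm, summary$level), ]
  base <- summary[summary$level == 0, c("algorithm", "mean_js", "mean_dsc")]
  names(base) <- c("algorithm", "js0", "dsc0")
  summary <- merge(summary, base, by = "algorithm")
  summary$js_drop_pct <- (summary$js0 - summary$mean_js) / summary$js0 * 100
  summary$dsc_drop_pct <-
    (summary$dsc0 - summary$mean_dsc) / summary$dsc0 * 100
  summary$js0 <- summary$dsc0 <- NULL
  summary <- summary[order(summary$algorithm, summary$level), ]
  rownames(summary) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(out_dir, "noise_runs.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "noise_summary.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "degradation.png"),
                   width = 800, height = 600)
    plot_degradation(summary)
    grDevices::dev.off()
    write_manifest(file.path(out_dir, "manifest.json"), list(
      command = "noise-exp", levels = levels, algorithms = algorithms,
      n_seeds = n_seeds, size = size, k = k, seed = seed))
  }
  list(runs = runs, summary = summary)
}

plot_degradation <- function(summary) {
  algs <- unique(summary$algorithm)
  cols <- seq_along(algs)
  graphics::plot(NULL, xlim = range(summary$level),
                 ylim = range(summary$mean_js),
                 xlab = "noise level (%)", ylab = "mean foreground JS",
                 main = "Noise degradation")
  for (i in seq_along(algs)) {
    s <- summary[summary$algorithm == algs[i], ]
    graphics::lines(s$level, s$mean_js, type = "b", col = cols[i], pch = 19)
  }
  graphics::legend("bottomleft", legend = algs, col = cols, lty = 1,
                   pch = 19, bty = "n")
}
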