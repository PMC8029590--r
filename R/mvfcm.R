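#' Fit a (multi-view) fuzzy c-means model
#'
#' Unified front-end to the three clustering engines:
#' \describe{
#'   \item{`"imvfcm"`}{multi-view fuzzy c-means with adaptive,
#'     entropy-regularized view weights and weighted-ensemble fusion
#'     ([imv_fit()]); the package's centerpiece.}
#'   \item{`"cofkm"`}{collaborative multi-view fuzzy k-means with
#'     geometric-mean ensemble ([cofkm_fit()]).}
#'   \item{`"fcm"`}{classic single-view fuzzy c-means ([fcm_fit()]); with a
#'     multi-view input the views are concatenated column-wise.}
#' }
#'
#' @param x a [multiview_data] object, a list of `N x p_v` matrices, or a
#'   single matrix/vector.
#' @param k number of clusters, `2 <= k <= N`.
#' @param method clustering engine (see above).
#' @param m fuzzifier, `> 1` (default 2).
#' @param gamma entropy-regularization strength for `"imvfcm"` (default
#'   `N`, the number of samples).
#' @param eta collaboration strength for `"cofkm"` (default `(V-1)/(2V)`).
#' @param tol convergence threshold on the objective change (default 0.001;
#'   `0` forces exactly `max_iter` iterations).
#' @param max_iter maximum iterations (default 100).
#' @param seed optional RNG seed for the membership initialization.
#' @param ... further arguments passed to the engine (`init`,
#'   `weight_init`).
#' @return An object of class `mvfcm`: a list with components `method`,
#'   `k`, `m`, `membership` (fused, column-stochastic `C x N`), `cluster`
#'   (1-based crisp labels), `per_view_membership`, `centers` (per view),
#'   `weights` (`V x V`, `"imvfcm"` only), `objective` (per-iteration
#'   trace), `converged`, `n_iter`, `constraint_violation`,
#'   `sample_shape` and `call`.
#' @examples
#' sim <- generate_mixture_mvd(n = 150, k = 3, v = 2, seed = 7)
#' fit <- mvfcm(sim$data, 3, seed = 7)
#' fit
#' table(fit$cluster, sim$labels)
#' @seealso [predict.mvfcm()], [summary.mvfcm()], [plot.mvfcm()]
#' @export
mvfcm <- function(x, k, method = c("imvfcm", "cofkm", "fcm"), m = 2,
                  gamma = NULL, eta = NULL, tol = 1e-3, max_iter = 100,
                  seed = NULL, ...) {
  method <- match.arg(method)
  data <- as_multiview(x)
  res <- switch(method,
    imvfcm = imv_fit(data, k, m = m, gamma = gamma, tol = tol,
                     max_iter = max_iter, seed = seed, ...),
    cofkm  = cofkm_fit(data, k, eta = eta, m = m, tol = tol,
                       max_iter = max_iter, seed = seed, ...),
    fcm    = {
      xc <- do.call(cbind, data$views)
      f <- fcm_fit(xc, k, m = m, tol = tol, max_iter = max_iter,
                   seed = seed, ...)
      list(per_view_membership = list(f$membership), fused = f$membership,
           cluster = f$cluster, centers = list(f$centers),
           objective = f$objective, converged = f$converged,
           n_iter = f$n_iter, constraint_violation = f$constraint_violation)
    })
  membership <- if (method == "cofkm") res$fused_normalized else res$fused
  obj <- structure(
    list(method = method, k = k, m = m,
         gamma = res$gamma, eta = res$eta,
         membership = membership,
         fused_raw = res$fused,
         cluster = res$cluster,
         per_view_membership = res$per_view_membership,
         centers = res$centers,
         weights = res$weights,
         fusion_coefficients = res$fusion_coefficients,
         objective = res$objective,
         converged = res$converged,
         n_iter = res$n_iter,
         constraint_violation = res$constraint_violation,
         n_samples = data$n_samples, n_views = data$n_views,
         sample_shape = data$sample_shape,
         call = match.call()),
    class = "mvfcm")
  obj
}

#' @export
print.mvfcm <- function(x, ...) {
  cat("Multi-view fuzzy c-means fit (method: ", x$method, ")\n", sep = "")
  cat("  ", x$n_samples, " samples, ", x$n_views, " view(s), ",
      x$k, " clusters, m = ", x$m, "\n", sep = "")
  if (!is.null(x$gamma)) cat("  gamma =", format(x$gamma), "\n")
  if (!is.null(x$eta)) cat("  eta =", format(x$eta), "\n")
  cat("  ", x$n_iter, " iteration(s), ",
      if (x$converged) "converged" else "not converged",
      "; final objective ", format(x$objective[x$n_iter]), "\n", sep = "")
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Summarize an mvfcm fit
#'
#' Reports partition crispness (partition coefficient and entropy of the
#' fused partition), cluster sizes, convergence, and — for the adaptive
#' method — the learned view-weight matrix and fusion coefficients.
#'
#' @param object an `mvfcm` fit.
#' @param ... unused.
#' @return An object of class `summary.mvfcm`.
#' @export
summary.mvfcm <- function(object, ...) {
  structure(
    list(fit = object,
         v_pc = partition_coefficient(object$membership),
         v_pe = partition_entropy(object$membership),
         sizes = tabulate(object$cluster, object$k)),
    class = "summary.mvfcm")
}

#' @export
print.summary.mvfcm <- function(x, ...) {
  print(x$fit)
  cat("  partition coefficient V_pc =", format(x$v_pc, digits = 4),
      " (1 = crisp, ", format(1 / x$fit$k, digits = 3), " = uniform)\n")
  cat("  partition entropy    V_pe =", format(x$v_pe, digits = 4),
      " (0 = crisp, ", format(log(x$fit$k), digits = 3), " = uniform)\n")
  if (!is.null(x$fit$weights)) {
    cat("  view-weight matrix W (rows: view task; cols: partition):\n")
    print(round(x$fit$weights, 4))
    cat("  fusion coefficients:",
        paste(round(x$fit$fusion_coefficients, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.mvfcm <- function(object, ...) object$centers

#' @export
fitted.mvfcm <- function(object, type = c("membership", "cluster"), ...) {
  type <- match.arg(type)
  if (type == "membership") object$membership else object$cluster
}

#' Predict cluster assignments for new multi-view data
#'
#' Applies the fitted model's frozen parameters to new samples: per-view
#' squared distances to the stored centers, the method's membership formula
#' (with the learned view weights for `"imvfcm"`, the fitted `eta` for
#' `"cofkm"`), and the method's fusion rule.
#'
#' @param object an `mvfcm` fit.
#' @param newdata a [multiview_data] object (or list/matrix) with the same
#'   views and dimensions as the training data.
#' @param type `"cluster"` (default) for crisp labels or `"membership"` for
#'   the fused membership matrix.
#' @param ... unused.
#' @return Integer labels or a `C x N` membership matrix.
#' @export
predict.mvfcm <- function(object, newdata,
                          type = c("cluster", "membership"), ...) {
  type <- match.arg(type)
  data <- as_multiview(newdata)
  if (data$n_views != object$n_views)
    stop("newdata has ", data$n_views, " views; model was fitted with ",
         object$n_views)
  fused <- switch(object$method,
    fcm = {
      xc <- do.call(cbind, data$views)
      fcm_update_memberships(sq_dist(xc, object$centers[[1]]), object$m)
    },
    cofkm = {
      D <- Map(function(v, z) sq_dist(v, z), data$views, object$centers)
      u <- cofkm_update_memberships(D, object$eta, object$m)
      cofkm_geometric_ensemble(u)
    },
    imvfcm = {
      D <- Map(function(v, z) sq_dist(v, z), data$views, object$centers)
      u <- imv_update_memberships(D, object$weights, object$m)
      imv_ensemble(u, object$weights)$fused
    })
  if (type == "cluster") column_argmax(fused) else fused
}

#' Plot an mvfcm fit
#'
#' Plots the per-iteration objective trace; when the samples are image
#' pixels (`sample_shape` recorded), also draws the crisp label map.
#'
#' @param x an `mvfcm` fit.
#' @param ... passed to [graphics::plot()] for the trace panel.
#' @return `x`, invisibly.
#' @export
plot.mvfcm <- function(x, ...) {
  two <- !is.null(x$sample_shape)
  if (two) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_len(x$n_iter), x$objective, type = "b",
                 xlab = "iteration", ylab = "objective",
                 main = paste0(x$method, " objective"), ...)
  if (two) {
    lm <- label_map(x)
    graphics::image(t(lm[nrow(lm):1, , drop = FALSE]),
                    col = grDevices::gray.colors(x$k, 0, 1), axes = FALSE,
                    main = "label map", useRaster = TRUE)
  }
  invisible(x)
}

#' Crisp label map of an image fit
#'
#' Reshapes the crisp labels of a fit on image pixels back to the `H x W`
#' image grid (row-major pixel order).
#'
#' @param fit an `mvfcm` fit with a recorded `sample_shape`.
#' @return Integer `H x W` matrix.
#' @export
label_map <- function(fit) {
  if (is.null(fit$sample_shape))
    stop("fit has no sample_shape; samples are not image pixels")
  unflatten_rowmajor(fit$cluster, fit$sample_shape)
}
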