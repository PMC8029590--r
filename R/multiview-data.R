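#' Multi-view data container
#'
#' Bundles the same `N` samples observed in `V` feature views. View `v` is an
#' `N x p_v` numeric matrix; views may have different dimensionality. When the
#' samples are image pixels, `sample_shape = c(H, W)` records the image size,
#' with pixel `(r, c)` mapped to sample index `(r - 1) * W + c` (row-major).
#'
#' @param views a numeric matrix/vector (single view) or a list of numeric
#'   matrices, each with the same number of rows.
#' @param sample_shape optional integer vector `c(H, W)` with `H * W == N`.
#' @return An object of class `multiview_data`: a list with elements `views`
#'   (list of matrices), `n_samples`, `n_views` and `sample_shape`.
#' @examples
#' x <- multiview_data(list(matrix(rnorm(20), 10), matrix(rnorm(30), 10)))
#' x
#' @export
multiview_data <- function(views, sample_shape = NULL) {
  if (!is.list(views)) views <- list(views)
  if (length(views) < 1L) stop("at least one view is required")
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  n <- vapply(views, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stop("all views must have the same number of rows (samples); got ",
         paste(n, collapse = ", "))
  n <- unname(n[1L])
  if (n < 1L) stop("at least one sample is required")
  ok <- vapply(views, function(v) all(is.finite(v)), logical(1))
  if (!all(ok))
    stop("non-finite values in view(s) ", paste(which(!ok), collapse = ", "))
  if (!is.null(sample_shape)) {
    sample_shape <- as.integer(sample_shape)
    if (length(sample_shape) != 2L || prod(sample_shape) != n)
      stop("sample_shape must be c(H, W) with H * W == n_samples")
  }
  structure(
    list(views = views, n_samples = n, n_views = length(views),
         sample_shape = sample_shape),
    class = "multiview_data"
  )
}

#' @export
print.multiview_data <- function(x, ...) {
  dims <- vapply(x$views, ncol, integer(1))
  cat("Multi-view data: ", x$n_samples, " samples in ", x$n_views,
      " view(s), dims (", paste(dims, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$sample_shape))
    cat("Samples are pixels of a ", x$sample_shape[1], " x ",
        x$sample_shape[2], " image (row-major)\n", sep = "")
  invisible(x)
}

as_multiview <- function(x) {
  if (inherits(x, "multiview_data")) x else multiview_data(x)
}

#' Validate a fuzzy membership matrix
#'
#' A membership matrix is `C x N` with entries in \[0, 1\] and every column
#' summing to 1 (each sample's memberships over clusters form a probability
#' vector). Returns a validation report rather than throwing, so it can be
#' used both defensively and in tests.
#'
#' @param u numeric matrix, rows = clusters, columns = samples.
#' @param tol numeric tolerance on the column sums (default `1e-9`).
#' @return A list with `ok` (logical) and `violations` (character vector,
#'   empty when valid).
#' @examples
#' validate_membership(matrix(c(0.3, 0.7, 0.5, 0.5), 2))$ok
#' @export
validate_membership <- function(u, tol = 1e-9) {
  report_stochastic(u, margin = 2L, tol = tol, what = "membership")
}

#' Validate a view-weight matrix
#'
#' The view-weight matrix is `V x V`; entry `(v, t)` is the importance of view
#' `t` inside view `v`'s clustering task. Entries lie in \[0, 1\] and each row
#' sums to 1.
#'
#' @param w numeric matrix `V x V`.
#' @param tol numeric tolerance on the row sums (default `1e-9`).
#' @return A list with `ok` and `violations`, as [validate_membership()].
#' @export
validate_view_weights <- function(w, tol = 1e-9) {
  report_stochastic(w, margin = 1L, tol = tol, what = "view weights")
}

report_stochastic <- function(m, margin, tol, what) {
  violations <- character(0)
  m <- as.matrix(m)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    violations <- c(violations, sprintf(
      "%s: non-finite entry at (%d, %d)", what, bad[, 1], bad[, 2]))
  } else {
    if (any(m < -tol | m > 1 + tol))
      violations <- c(violations,
                      sprintf("%s: entries outside [0, 1]", what))
    s <- if (margin == 1L) rowSums(m) else colSums(m)
    off <- which(abs(s - 1) > tol)
    if (length(off) > 0) {
      lab <- if (margin == 1L) "row" else "column"
      violations <- c(violations, sprintf(
        "%s: %s %d sums to %.6g (expected 1)", what, lab, off, s[off]))
    }
  }
  list(ok = length(violations) == 0, violations = violations)
}

# hard check used inside the fitting loops
stopifnot_stochastic <- function(m, margin, tol = 1e-9, what = "matrix") {
  rep <- report_stochastic(m, margin, tol, what)
  if (!rep$ok) stop(paste(rep$violations, collapse = "; "))
  invisible(TRUE)
}
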