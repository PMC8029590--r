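# Segmentation validity indices and cluster-label alignment.

as_mask <- function(x) {
  m <- as.logical(x)
  if (anyNA(m)) stop("mask contains NA")
  m
}

check_pair <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (length(a) != length(b)) stop("masks have different lengths")
  list(a = a, b = b)
}

#' Jaccard similarity of two masks
#'
#' `JS = |A intersect B| / |A union B|`; 1 for identical non-empty masks,
#' 0 for disjoint ones.
#'
#' @param a,b logical masks (vectors or matrices of equal shape).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  p <- check_pair(a, b)
  un <- sum(p$a | p$b)
  if (un == 0) stop("both masks are empty (0/0)")
  sum(p$a & p$b) / un
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`; algebraically equal to
#' `2 JS / (1 + JS)` and to the kappa index of the induced confusion counts.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  p <- check_pair(a, b)
  den <- sum(p$a) + sum(p$b)
  if (den == 0) stop("both masks are empty")
  2 * sum(p$a & p$b) / den
}

#' Confusion counts of a predicted vs reference mask
#'
#' @param pred,ref logical masks of equal shape.
#' @return List with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, ref) {
  p <- check_pair(pred, ref)
  list(TP = sum(p$a & p$b), FP = sum(p$a & !p$b),
       FN = sum(!p$a & p$b), TN = sum(!p$a & !p$b))
}

#' Kappa index of confusion counts
#'
#' `KI = 2 TP / (2 TP + FP + FN)`; identical to the Dice coefficient of the
#' masks that generated the counts.
#'
#' @param counts list with `TP`, `FP`, `FN` (as from [confusion_counts()]).
#' @return Scalar in `[0, 1]`.
#' @export
kappa_index <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) stop("degenerate confusion counts: 2TP + FP + FN = 0")
  2 * counts$TP / den
}

#' Partition coefficient
#'
#' `V_pc = (1/n) sum_j sum_i u_ij^2`, in `[1/C, 1]`; 1 for a crisp
#' partition, `1/C` for the maximally ambiguous uniform one.
#'
#' @param membership column-stochastic `C x N` matrix.
#' @return Scalar.
#' @export
partition_coefficient <- function(membership) {
  sum(membership^2) / ncol(membership)
}

#' Partition entropy
#'
#' Bezdek's partition entropy `V_pe = -(1/n) sum_j sum_i u_ij ln(u_ij)`
#' (with `0 ln 0 = 0`), in `[0, ln C]`; 0 for a crisp partition.
#'
#' @param membership column-stochastic `C x N` matrix.
#' @return Scalar.
#' @export
partition_entropy <- function(membership) {
  -sum(xlogx(membership)) / ncol(membership)
}

#' Misclassification error of a segmentation against a gold standard
#'
#' `ME = (Area(A union B) - Area(A intersect B)) / Area(B)`: the
#' symmetric-difference area normalized by the gold-standard area `B`.
#' 0 for perfect agreement; asymmetric in its second argument.
#'
#' @param a segmentation mask.
#' @param b gold-standard mask (must be non-empty).
#' @return Scalar in `[0, Inf)`.
#' @export
misclassification_error <- function(a, b) {
  p <- check_pair(a, b)
  nb <- sum(p$b)
  if (nb == 0) stop("gold-standard mask is empty")
  (sum(p$a | p$b) - sum(p$a & p$b)) / nb
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  if (n > 8) stop("exhaustive assignment supported for up to 8 clusters")
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub), deparse.level = 0)
  }))
}

#' Align predicted cluster labels with reference classes
#'
#' Cluster indices are arbitrary, so predicted labels are matched to
#' reference classes by the permutation maximizing the total overlap of the
#' `C x C` contingency table (exhaustive optimal assignment). Labels are
#' 1-based integers in `1..k`.
#'
#' @param predicted,reference integer label vectors of equal length.
#' @param k number of classes.
#' @return List with `permutation` (`perm[i]` = reference class assigned to
#'   predicted cluster `i`), `relabeled` (predicted labels mapped onto
#'   reference classes), `agreement` (fraction of samples matching after
#'   relabeling) and `masks` (per reference class: `pred` and `ref` masks).
#' @export
align_labels <- function(predicted, reference, k) {
  predicted <- as.integer(predicted); reference <- as.integer(reference)
  if (length(predicted) != length(reference))
    stop("label vectors have different lengths")
  if (any(c(predicted, reference) < 1L) || any(c(predicted, reference) > k))
    stop("labels must lie in 1..k")
  tab <- table(factor(predicted, levels = 1:k),
               factor(reference, levels = 1:k))
  perms <- all_permutations(k)
  overlap <- apply(perms, 1L, function(p) sum(tab[cbind(1:k, p)]))
  best <- perms[which.max(overlap), ]
  relabeled <- best[predicted]
  masks <- lapply(1:k, function(cls)
    list(pred = relabeled == cls, ref = reference == cls))
  names(masks) <- paste0("class", 1:k)
  list(permutation = best, relabeled = relabeled,
       agreement = max(overlap) / length(predicted), masks = masks)
}

#' Per-class segmentation report
#'
#' Aligns predicted clusters with reference classes, then computes Jaccard,
#' Dice and misclassification error per class plus their mean over the
#' foreground classes (the background class, when given, is excluded from
#' the mean — the convention for tissue-wise scoring of brain segmentations
#' where WM/GM/CSF are averaged and background is not).
#'
#' @param predicted,reference integer label vectors (1-based) of equal
#'   length.
#' @param k number of classes.
#' @param background optional reference class index excluded from the mean
#'   row (e.g. `1` for phantoms whose class 1 is background).
#' @return A data.frame with one row per class and a final `"mean"` row;
#'   columns `class`, `js`, `dsc`, `me`.
#' @export
evaluate_segmentation <- function(predicted, reference, k, background = NULL) {
  al <- align_labels(predicted, reference, k)
  rows <- lapply(1:k, function(cls) {
    mk <- al$masks[[cls]]
    if (sum(mk$ref) == 0)
      return(data.frame(class = as.character(cls), js = NA_real_,
                        dsc = NA_real_, me = NA_real_))
    data.frame(class = as.character(cls),
               js = jaccard(mk$pred, mk$ref),
               dsc = dice(mk$pred, mk$ref),
               me = misclassification_error(mk$pred, mk$ref))
  })
  df <- do.call(rbind, rows)
  keep <- if (is.null(background)) 1:k else setdiff(1:k, background)
  mean_row <- data.frame(class = "mean",
                         js = mean(df$js[keep], na.rm = TRUE),
                         dsc = mean(df$dsc[keep], na.rm = TRUE),
                         me = mean(df$me[keep], na.rm = TRUE))
  rbind(df, mean_row)
}

#' Write a metrics report
#'
#' Writes a segmentation report (as from [evaluate_segmentation()]) as CSV
#' or JSON, chosen by the file extension.
#'
#' @param report data.frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
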