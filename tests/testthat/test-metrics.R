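test_that("overlap metrics match set-count oracles", {
  a <- c(rep(TRUE, 6), rep(FALSE, 4))
  b <- c(rep(TRUE, 4), FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  # |A| = 6, |B| = 6, |A & B| = 4, |A | B| = 8
  expect_equal(jaccard(a, b), 4 / 8)
  expect_equal(dice(a, b), 8 / 12)
  expect_equal(misclassification_error(a, b), (8 - 4) / 6)

  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, a), 1)
  expect_equal(misclassification_error(a, a), 0)
  expect_equal(jaccard(c(TRUE, FALSE), c(FALSE, TRUE)), 0)

  # empty segmentation misses everything
  expect_equal(misclassification_error(rep(FALSE, 4), c(TRUE, TRUE, FALSE,
                                                        FALSE)), 1)
  expect_error(jaccard(rep(FALSE, 3), rep(FALSE, 3)), "empty")
  expect_error(misclassification_error(a, rep(FALSE, 10)), "empty")
  expect_error(jaccard(a, b[1:5]), "length")
})

test_that("kappa index equals Dice on the generating masks", {
  expect_equal(kappa_index(list(TP = 4, FP = 2, FN = 2)), 8 / 12)
  expect_equal(kappa_index(list(TP = 5, FP = 0, FN = 0)), 1)
  expect_error(kappa_index(list(TP = 0, FP = 0, FN = 0)), "degenerate")

  set.seed(9)
  for (rep in 1:100) {
    a <- runif(30) > 0.5
    b <- runif(30) > 0.5
    if (!any(a | b)) next
    js <- jaccard(a, b)
    d <- dice(a, b)
    ki <- kappa_index(confusion_counts(a, b))
    # exact algebraic identities
    expect_identical(d, ki)
    expect_equal(d, 2 * js / (1 + js), tolerance = 1e-15)
  }
})

test_that("ME is asymmetric while JS and DSC are symmetric", {
  set.seed(10)
  a <- runif(40) > 0.4
  b <- runif(40) > 0.6
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_equal(dice(a, b), dice(b, a))
  expect_false(isTRUE(all.equal(misclassification_error(a, b),
                                misclassification_error(b, a))))
})

test_that("partition coefficient and entropy match hand values and bounds", {
  u <- cbind(c(0.8, 0.2), c(0.5, 0.5))
  expect_equal(partition_coefficient(u), (0.64 + 0.04 + 0.25 + 0.25) / 2)

  crisp <- diag(3)[, c(1, 2, 3, 1)]
  expect_equal(partition_coefficient(crisp), 1)
  expect_equal(partition_entropy(crisp), 0)

  unif <- matrix(1 / 4, 4, 6)
  expect_equal(partition_coefficient(unif), 1 / 4)
  expect_equal(partition_entropy(unif), log(4))

  expect_equal(partition_entropy(matrix(c(0.8, 0.2), 2)),
               -(0.8 * log(0.8) + 0.2 * log(0.2)))

  set.seed(11)
  for (rep in 1:20) {
    C <- sample(2:5, 1)
    u <- rand_membership(C, 20)
    vpc <- partition_coefficient(u)
    vpe <- partition_entropy(u)
    expect_gte(vpc, 1 / C - 1e-12); expect_lte(vpc, 1 + 1e-12)
    expect_gte(vpe, -1e-12); expect_lte(vpe, log(C) + 1e-12)
  }
})

test_that("label alignment finds the optimal permutation", {
  set.seed(12)
  truth <- sample.int(3, 60, replace = TRUE)
  perm <- c(3, 1, 2)
  pred <- perm[truth]  # renamed clusters
  al <- align_labels(pred, truth, 3)
  expect_equal(al$relabeled, truth)
  expect_equal(al$agreement, 1)
  for (cls in 1:3) expect_equal(jaccard(al$masks[[cls]]$pred,
                                        al$masks[[cls]]$ref), 1)

  # random small instances: match exhaustive search over permutations
  for (rep in 1:10) {
    pred <- sample.int(3, 30, replace = TRUE)
    truth <- sample.int(3, 30, replace = TRUE)
    al <- align_labels(pred, truth, 3)
    perms <- mvfcm:::all_permutations(3)
    brute <- max(apply(perms, 1, function(p) sum(p[pred] == truth)))
    expect_equal(sum(al$relabeled == truth), brute)
  }

  # independent balanced prediction: best overlap near one half
  set.seed(13)
  t2 <- rep(1:2, each = 100)
  p2 <- sample.int(2, 200, replace = TRUE)
  expect_lt(abs(align_labels(p2, t2, 2)$agreement - 0.5), 0.12)

  expect_error(align_labels(c(1, 5), c(1, 2), 2), "1..k")
})

test_that("segmentation report averages foreground classes only", {
  truth <- c(rep(1, 10), rep(2, 5), rep(3, 5))
  pred <- truth
  pred[1] <- 2  # one background pixel misassigned
  rep_df <- evaluate_segmentation(pred, truth, 3, background = 1)
  expect_equal(nrow(rep_df), 4)
  m <- rep_df[rep_df$class == "mean", ]
  # mean excludes class 1: classes 2 (5/6) and 3 (1)
  expect_equal(m$js, mean(c(5 / 6, 1)))

  tmp <- tempfile(fileext = ".csv")
  write_metrics(rep_df, tmp)
  expect_true(file.exists(tmp))
  back <- read.csv(tmp)
  expect_equal(back$js, rep_df$js)
  tmpj <- tempfile(fileext = ".json")
  write_metrics(rep_df, tmpj)
  expect_equal(tail(jsonlite::fromJSON(tmpj)$class, 1), "mean")
})
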