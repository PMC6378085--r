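test_that("binarize compares channels with ties to non-ISV", {
  pm <- array(c(rep(0.9, 16), rep(0.1, 16)), c(4, 4, 2))
  expect_equal(binarize(pm), matrix(1, 4, 4))
  expect_equal(binarize(array(0.5, c(4, 4, 2))), matrix(0, 4, 4))
  set.seed(3)
  pm <- array(runif(32), c(4, 4, 2))
  oracle <- matrix(0, 4, 4)
  for (r in 1:4) {
    for (c in 1:4) oracle[r, c] <- as.numeric(pm[r, c, 1] > pm[r, c, 2])
  }
  expect_equal(binarize(pm), oracle)
})

test_that("confusion counts tally the four pixel classes", {
  g <- square_mask(4, 2, 3)
  expect_equal(confusion_counts(g, g)$FP, 0)
  expect_equal(confusion_counts(g, g)$FN, 0)
  inv <- confusion_counts(1 - g, g)
  expect_equal(inv$TP, 0)
  expect_equal(inv$TN, 0)
  set.seed(8)
  p <- (matrix(runif(16), 4, 4) > 0.5) * 1
  q <- (matrix(runif(16), 4, 4) > 0.5) * 1
  cc <- confusion_counts(p, q)
  hand <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:16) {
    hand <- hand + c(TP = p[i] == 1 && q[i] == 1, FP = p[i] == 1 && q[i] == 0,
                     TN = p[i] == 0 && q[i] == 0, FN = p[i] == 0 && q[i] == 1)
  }
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]), hand)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 16)
  expect_error(confusion_counts(p, q[1:3, 1:3]), "differ")
})

test_that("accuracy and Dice follow their printed formulas", {
  cc <- structure(list(TP = 8, TN = 4, FP = 2, FN = 2),
                  class = "confusion_counts")
  expect_equal(pixel_accuracy(cc), 75.0)
  expect_equal(dice(cc), 0.8)
  perfect <- structure(list(TP = 5, TN = 11, FP = 0, FN = 0),
                       class = "confusion_counts")
  expect_equal(pixel_accuracy(perfect), 100)
  expect_equal(as.numeric(dice(perfect)), 1.0)
  none <- structure(list(TP = 0, TN = 10, FP = 3, FN = 3),
                    class = "confusion_counts")
  expect_equal(dice(none), 0)
  empty <- structure(list(TP = 0, TN = 16, FP = 0, FN = 0),
                     class = "confusion_counts")
  d <- dice(empty)
  expect_equal(as.numeric(d), 1)
  expect_true(isTRUE(attr(d, "empty_vs_empty")))
})

test_that("metrics via confusion counts equal direct mask formulas", {
  set.seed(12)
  for (rep in 1:4) {
    p <- (matrix(runif(64), 8, 8) > 0.4) * 1
    g <- (matrix(runif(64), 8, 8) > 0.6) * 1
    cc <- confusion_counts(p, g)
    direct_acc <- 100 * mean(p == g)
    direct_dice <- 2 * sum(p * g) / (sum(p) + sum(g))
    expect_equal(pixel_accuracy(cc), direct_acc)
    expect_equal(as.numeric(dice(cc)), direct_dice)
  }
})

test_that("a perfect scorer has ROC AUC 1 and a full-recall PR curve", {
  g <- square_mask(8, 3, 6)
  roc <- roc_curve(g, g)
  expect_equal(auc(roc), 1.0)
  pr <- pr_curve(g, g)
  expect_true(any(pr$precision == 1 & pr$recall == 1))
})

test_that("independent noise scores give AUC near one half", {
  set.seed(19)
  g <- (matrix(runif(70 * 70), 70, 70) > 0.5) * 1
  scores <- matrix(runif(70 * 70), 70, 70)
  a <- auc(roc_curve(scores, g))
  n1 <- sum(g)
  n0 <- sum(1 - g)
  sigma <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) # Mann-Whitney null sd
  expect_lt(abs(a - 0.5), 3 * sigma)
})

test_that("toy AUC equals the rank-statistic (Mann-Whitney) value", {
  g <- matrix(c(1, 1, 1, 0, 0, 0, 0, 1), 2, 4)
  set.seed(4)
  s <- matrix(runif(8), 2, 4) # distinct scores
  a <- auc(roc_curve(s, g))
  pos <- s[g == 1]
  neg <- s[g == 0]
  u <- sum(outer(pos, neg, ">"))
  expect_equal(a, u / (length(pos) * length(neg)), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  g <- (matrix(runif(100), 10, 10) > 0.5) * 1
  s <- matrix(runif(100), 10, 10)
  a1 <- auc(roc_curve(s, g))
  a2 <- auc(roc_curve(s^3, g))
  a3 <- auc(roc_curve(1 / (1 + exp(-5 * s)), g))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("degenerate ground truths are rejected for curves", {
  expect_error(roc_curve(matrix(0.5, 4, 4), matrix(0, 4, 4)), "single class")
  expect_error(pr_curve(matrix(0.5, 4, 4), matrix(0, 4, 4)), "no positive")
})

test_that("metric summaries follow the textbook formulas", {
  one <- summarize_metrics(88)
  expect_equal(one$median, 88)
  expect_equal(one$mean, 88)
  expect_equal(one$sd, 0)
  two <- summarize_metrics(c(80, 90))
  expect_equal(two$mean, 85)
  expect_equal(two$median, 85)
  set.seed(14)
  v <- rnorm(100, 85, 5)
  s <- summarize_metrics(v)
  expect_equal(s$mean, sum(v) / 100)
  expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / 99))
  expect_equal(s$median, sort(v)[50] / 2 + sort(v)[51] / 2)
})

test_that("the paired t-test matches the hand formula and edge cases", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  const <- paired_t_test(rep(5, 5) + 0.3, rep(5, 5))
  expect_true(const$degenerate)
  expect_true(const$significant)
  set.seed(22)
  a <- rnorm(10, 85, 4)
  b <- rnorm(10, 83, 4)
  out <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), 9), tolerance = 1e-12)
})

test_that("overlay tint counts equal the confusion counts", {
  set.seed(30)
  base <- matrix(runif(64, 0.1, 0.4), 8, 8)
  p <- (matrix(runif(64), 8, 8) > 0.5) * 1
  g <- (matrix(runif(64), 8, 8) > 0.5) * 1
  ov <- render_overlay(p, g, base)
  cc <- confusion_counts(p, g)
  is_col <- function(rgb) {
    sum(ov[, , 1] == rgb[1] & ov[, , 2] == rgb[2] & ov[, , 3] == rgb[3])
  }
  expect_equal(is_col(c(1, 0, 0)), cc$TP)
  expect_equal(is_col(c(0, 0, 1)), cc$FP)
  expect_equal(is_col(c(1, 1, 0)), cc$FN)
  # perfect prediction: only red tint on the foreground
  ov2 <- render_overlay(g, g, base)
  expect_equal(sum(ov2[, , 1] == 1 & ov2[, , 2] == 0 & ov2[, , 3] == 0),
               sum(g))
  # disjoint prediction: only blue and yellow
  g3 <- matrix(0, 8, 8)
  g3[1:2, ] <- 1
  p3 <- matrix(0, 8, 8)
  p3[5:6, ] <- 1
  ov3 <- render_overlay(p3, g3, base)
  expect_equal(sum(ov3[, , 1] == 1 & ov3[, , 2] == 0 & ov3[, , 3] == 0), 0)
})

test_that("evaluate_masks aggregates per-image metrics", {
  g <- square_mask(8, 3, 6)
  res <- evaluate_masks(list(g, 1 - g), list(g, g))
  expect_equal(nrow(res$per_image), 2)
  expect_equal(res$per_image$accuracy[1], 100)
  expect_equal(res$per_image$dice[2], 0)
  expect_equal(res$aggregate$mean[res$aggregate$metric == "accuracy"],
               mean(res$per_image$accuracy))
})
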