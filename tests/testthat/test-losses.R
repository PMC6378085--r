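# literal per-pixel loop transcriptions of each loss term, used as oracles
oracle_wce <- function(y, t, pos_weight = 1, eps = 1e-7) {
  total <- 0
  for (i in seq_along(y)) {
    yi <- min(max(y[i], eps), 1 - eps)
    total <- total + -(pos_weight * t[i] * log(yi) +
                         (1 - t[i]) * log(1 - yi))
  }
  total / length(y)
}

oracle_contour <- function(y, bands, eps = 1e-7) {
  I <- bands$total
  s_pos <- 0
  s_neg <- 0
  for (i in seq_along(y)) {
    yi <- min(max(y[i], eps), 1 - eps)
    if (bands$inner[i]) s_pos <- s_pos + log(yi)
    if (bands$outer[i]) s_neg <- s_neg + log(1 - yi)
  }
  -(bands$n_inner / I^2) * s_pos - (bands$n_outer / I^2) * s_neg
}

oracle_shape <- function(pred, t, eps = 1e-7) {
  total <- 0
  for (i in seq_along(t)) {
    p1 <- min(max(pred[, , 1][i], eps), 1 - eps)
    p2 <- min(max(pred[, , 2][i], eps), 1 - eps)
    u <- (if (t[i] == 1) p1 else p2) / (p1 + p2)
    total <- total + -log(u)
  }
  total / length(t)
}

test_that("contour bands of a centred square have the expected counts", {
  m <- square_mask(8, 3, 6)
  b <- compute_contour_bands(m, band_width = 1)
  expect_equal(b$n_inner, 12)
  expect_equal(b$n_outer, 20)
  expect_equal(b$total, 32)
  expect_true(all(m[b$inner] == 1))
  expect_true(all(m[b$outer] == 0))
})

test_that("contour bands satisfy their set identities", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rbinom(100, 1, 0.4), 10, 10)
    m <- (EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0) * 1
    b <- compute_contour_bands(m, band_width = sample(1:3, 1))
    expect_equal(sum(b$inner & b$outer), 0)
    expect_equal(sum(b$mu), b$total)
    expect_equal(b$total, b$n_inner + b$n_outer)
  }
})

test_that("degenerate masks yield empty flagged bands", {
  b0 <- compute_contour_bands(matrix(0, 6, 6))
  expect_true(b0$empty)
  expect_equal(b0$total, 0)
  b1 <- compute_contour_bands(matrix(1, 6, 6))
  expect_true(b1$empty)
})

test_that("widening the band never shrinks it", {
  m <- square_mask(12, 4, 9)
  totals <- vapply(1:4, function(bw)
    compute_contour_bands(m, bw)$total, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("weighted cross-entropy has its closed-form anchors", {
  m <- square_mask(6, 2, 4)
  pred <- array(0.5, c(6, 6, 2))
  expect_equal(weighted_cross_entropy(pred, m), log(2), tolerance = 1e-12)
  perfect <- array(c(m, 1 - m), c(6, 6, 2))
  expect_lte(weighted_cross_entropy(perfect, m), -log(1 - 1e-7) + 1e-12)
  expect_error(weighted_cross_entropy(array(0.5, c(4, 4, 2)), m), "shapes")
})

test_that("each loss term matches its per-pixel loop transcription", {
  set.seed(31)
  for (rep in 1:6) {
    side <- sample(4:8, 1)
    m <- (matrix(runif(side^2), side, side) > 0.6) * 1
    pred <- array(runif(side^2 * 2, 0.01, 0.99), c(side, side, 2))
    pw <- sample(c(1, 2, 5), 1)
    expect_equal(weighted_cross_entropy(pred, m, pw),
                 oracle_wce(pred[, , 1], m, pw), tolerance = 1e-6)
    b <- compute_contour_bands(m, 1)
    if (!b$empty) {
      expect_equal(as.numeric(contour_aware_loss(pred, m, b)),
                   oracle_contour(pred[, , 1], b), tolerance = 1e-6)
    }
    expect_equal(shape_constraint_loss(pred, m), oracle_shape(pred, m),
                 tolerance = 1e-6)
  }
})

test_that("perfect predictions drive every term to the clamping floor", {
  m <- square_mask(8, 3, 6)
  b <- compute_contour_bands(m, 1)
  perfect <- array(c(m, 1 - m), c(8, 8, 2))
  floor_ <- -log(1 - 1e-7)
  expect_lte(as.numeric(contour_aware_loss(perfect, m, b)), floor_)
  expect_lte(shape_constraint_loss(perfect, m), floor_)
  lb <- total_objective(perfect, m, b)
  expect_lte(lb$L, 2 * floor_)
})

test_that("contour loss falls back to cross-entropy on degenerate masks", {
  m <- matrix(0, 6, 6)
  b <- compute_contour_bands(m)
  pred <- random_pred(6, 6)
  lc <- contour_aware_loss(pred, m, b)
  expect_true(isTRUE(attr(lc, "fallback")))
  expect_equal(as.numeric(lc), weighted_cross_entropy(pred, m))
  lb <- total_objective(pred, m, b)
  expect_true(lb$fallback)
})

test_that("the shape term is log 2 at a uniform half prediction", {
  m <- square_mask(6, 2, 4)
  pred <- array(0.5, c(6, 6, 2))
  expect_equal(shape_constraint_loss(pred, m), log(2), tolerance = 1e-12)
})

test_that("the shape term strictly decreases along the blend to truth", {
  m <- square_mask(8, 3, 6)
  target <- array(c(m, 1 - m), c(8, 8, 2))
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    shape_constraint_loss((1 - a) * 0.5 + a * target, m)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the combined objective is additive and carries the decay default", {
  m <- square_mask(8, 3, 6)
  b <- compute_contour_bands(m)
  pred <- random_pred(8, 8, seed = 4)
  lb <- total_objective(pred, m, b, arm = "s+c")
  expect_equal(lb$L, lb$L_c + lb$L_s, tolerance = 1e-12)
  expect_equal(lb$weight_decay, 5e-4)
  expect_equal(total_objective(pred, m, b, arm = "wce")$L, lb$L_wce)
  expect_equal(total_objective(pred, m, b, arm = "c")$L, lb$L_c)
  expect_equal(total_objective(pred, m, b, arm = "s")$L,
               lb$L_wce + lb$L_s, tolerance = 1e-12)
  expect_true(all(c(lb$L, lb$L_wce, lb$L_c, lb$L_s) >= 0))
  expect_true(all(is.finite(c(lb$L, lb$L_wce, lb$L_c, lb$L_s))))
})

test_that("analytic loss gradients match central differences", {
  set.seed(77)
  m <- (matrix(runif(9), 3, 3) > 0.5) * 1
  m[1, 1] <- 1
  m[3, 3] <- 0 # both classes present
  b <- compute_contour_bands(m, 1)
  pred <- array(runif(18, 0.05, 0.95), c(3, 3, 2))
  eps <- 1e-6
  for (arm in c("wce", "c", "s", "s+c")) {
    ana <- isvseg:::objective_gradient(pred, m, b, arm = arm)
    for (i in seq_along(pred)) {
      pp <- pred
      pp[i] <- pp[i] + eps
      lp <- total_objective(pp, m, b, arm = arm)$L
      pp[i] <- pp[i] - 2 * eps
      lm <- total_objective(pp, m, b, arm = arm)$L
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - ana[i]) / max(abs(num), abs(ana[i]), 1e-8), 1e-4,
                label = sprintf("arm %s, element %d", arm, i))
    }
  }
})

test_that("the emphasis mode weights band pixels in full-image CE", {
  m <- square_mask(8, 3, 6)
  b <- compute_contour_bands(m, 1)
  pred <- random_pred(8, 8, seed = 9)
  w <- 1 + b$mu
  ce <- -(m * log(pred[, , 1]) + (1 - m) * log(1 - pred[, , 1]))
  expect_equal(as.numeric(contour_aware_loss(pred, m, b, mode = "emphasis")),
               sum(w * ce) / sum(w), tolerance = 1e-10)
})

test_that("swap_bands transposes the band-class pairing", {
  m <- square_mask(8, 3, 6)
  b <- compute_contour_bands(m, 1)
  pred <- random_pred(8, 8, seed = 10)
  straight <- as.numeric(contour_aware_loss(pred, m, b))
  swapped <- as.numeric(contour_aware_loss(pred, m, b, swap_bands = TRUE))
  y <- pred[, , 1]
  I <- b$total
  expected <- -(b$n_outer / I^2) * sum(log(y[b$outer])) -
    (b$n_inner / I^2) * sum(log(1 - y[b$inner]))
  expect_equal(swapped, expected, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(straight, swapped)))
})
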