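# independent plain-R layer implementations used as oracles
oracle_conv <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]; p <- (k - 1) / 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (kr in seq_len(k)) {
        for (kc in seq_len(k)) {
          for (h in seq_len(H)) {
            for (wd in seq_len(W)) {
              hs <- h + kr - 1 - p
              ws <- wd + kc - 1 - p
              if (hs >= 1 && hs <= H && ws >= 1 && ws <= W) {
                acc[h, wd] <- acc[h, wd] + x[hs, ws, ci] * w[kr, kc, ci, co]
              }
            }
          }
        }
      }
    }
    y[, , co] <- acc
  }
  y
}

oracle_bn_eval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  y <- x
  for (c in seq_len(dim(x)[3])) {
    y[, , c] <- gamma[c] * (x[, , c] - rm[c]) / sqrt(rv[c] + eps) + beta[c]
  }
  y
}

test_that("a residual unit with zeroed convolutions is the identity", {
  u <- build_residual_unit(3, 3, seed = 2)
  for (nm in names(u$params)) {
    if (grepl("conv[12]\\.w$", nm)) u$params[[nm]][] <- 0
  }
  x <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
  expect_equal(unit_forward(u, x), x, tolerance = 1e-12)
})

test_that("channel-changing units project the identity path", {
  u <- build_residual_unit(4, 8, seed = 2)
  expect_true("u.proj.w" %in% names(u$params))
  x <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  y <- unit_forward(u, x)
  expect_equal(dim(y), c(8, 8, 8, 1))
  expect_false("u.proj.w" %in% names(build_residual_unit(4, 4)$params))
})

test_that("a residual unit matches a hand-rolled per-layer composition", {
  set.seed(9)
  u <- build_residual_unit(4, 8, seed = 13)
  x4 <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  x <- array(x4, c(8, 8, 4))
  p <- u$params
  st <- u$state
  h <- oracle_bn_eval(x, p$u.bn1.gamma, p$u.bn1.beta, st$u.bn1.rm, st$u.bn1.rv)
  h <- pmax(h, 0)
  h <- oracle_conv(h, p$u.conv1.w, p$u.conv1.b)
  h <- oracle_bn_eval(h, p$u.bn2.gamma, p$u.bn2.beta, st$u.bn2.rm, st$u.bn2.rv)
  h <- pmax(h, 0)
  h <- oracle_conv(h, p$u.conv2.w, p$u.conv2.b)
  idp <- oracle_conv(x, p$u.proj.w, p$u.proj.b)
  expected <- idp + h
  got <- unit_forward(u, x4)
  expect_equal(array(got, dim(expected)), expected, tolerance = 1e-10)
})

test_that("variants build the stated number of residual units", {
  expect_equal(nrow(build_network(network_config("dual_resunet_14",
                                                 base_channels = 2))$unit_registry), 14)
  expect_equal(nrow(build_network(network_config("dual_resunet_10",
                                                 base_channels = 2))$unit_registry), 10)
  expect_equal(nrow(build_network(network_config("dual_resunet_18",
                                                 base_channels = 2))$unit_registry), 18)
  expect_equal(nrow(build_network(network_config("dual_unet_14",
                                                 base_channels = 2))$unit_registry), 14)
  expect_equal(nrow(build_network(network_config("single_resunet",
                                                 base_channels = 2))$unit_registry), 7)
  expect_error(network_config("resunet_99"), "variant")
})

test_that("parameter counts grow with unit count at equal base channels", {
  p10 <- n_parameters(build_network(network_config("dual_resunet_10",
                                                   base_channels = 4)))
  p14 <- n_parameters(build_network(network_config("dual_resunet_14",
                                                   base_channels = 4)))
  p18 <- n_parameters(build_network(network_config("dual_resunet_18",
                                                   base_channels = 4)))
  expect_lt(p10, p14)
  expect_lt(p14, p18)
})

test_that("forward produces sigmoid probability maps at the input size", {
  net <- build_network(network_config(base_channels = 2), seed = 4)
  x <- matrix(runif(128 * 128), 128, 128)
  pm <- forward(net, x)
  expect_equal(dim(pm), c(128, 128, 2))
  expect_true(all(pm > 0 & pm < 1))
  expect_true(all(is.finite(forward(net, matrix(0, 64, 64)))))
})

test_that("evaluation-mode forward is deterministic and batch independent", {
  net <- build_network(network_config(base_channels = 2), seed = 4)
  x <- matrix(runif(32 * 32), 32, 32)
  a <- forward(net, x)
  b <- forward(net, x)
  expect_identical(a, b)
  pair <- forward(net, array(c(x, x), c(32, 32, 2)))
  expect_equal(pair[, , , 1], a, tolerance = 1e-12)
  expect_equal(pair[, , , 2], a, tolerance = 1e-12)
})

test_that("bad input sizes and channel mismatches are rejected", {
  net <- build_network(network_config(base_channels = 2))
  expect_error(forward(net, matrix(0, 30, 30)), "divisible")
  expect_error(forward(net, array(0, c(32, 32, 3, 1))), "channel")
})

test_that("zeroing every residual branch still yields a working forward", {
  net <- build_network(network_config(base_channels = 2), seed = 6)
  for (nm in names(net$params)) {
    if (grepl("conv[12]\\.w$", nm)) net$params[[nm]][] <- 0
  }
  pm <- forward(net, matrix(runif(32 * 32), 32, 32))
  expect_true(all(is.finite(pm)))
  expect_true(all(pm > 0 & pm < 1))
})

test_that("gradient reaches every registered parameter (bridge connected)", {
  net <- build_network(network_config("dual_resunet_10", base_channels = 2),
                       seed = 3)
  x <- withr::with_seed(7, array(runif(16 * 16), c(16, 16, 1, 1)))
  g <- isvseg:::ad_graph()
  fw <- isvseg:::network_forward_graph(g, net, x, training = TRUE)
  pred <- isvseg:::ad_value(g, fw$out)
  seed_grad <- withr::with_seed(8, array(rnorm(length(pred)), dim(pred)))
  grads <- isvseg:::ad_backward(g, fw$out, seed_grad)
  expect_setequal(names(grads), names(net$params))
  for (nm in names(grads)) {
    expect_false(is.null(grads[[nm]]), info = nm)
    expect_true(all(is.finite(grads[[nm]])), info = nm)
  }
  # weights and batch-norm scales receive non-trivial gradient (conv biases
  # feeding straight into BN legitimately get ~0: BN subtracts the mean)
  for (nm in names(grads)) {
    if (grepl("(\\.w|gamma|beta)$", nm)) {
      expect_gt(max(abs(grads[[nm]])), 0, label = nm)
    }
  }
})

test_that("network backward matches central-difference gradients", {
  net <- build_network(network_config("dual_resunet_10", base_channels = 2),
                       seed = 3)
  x <- withr::with_seed(11, array(runif(16 * 16), c(16, 16, 1, 1)))
  m <- square_mask(16, 4, 12)
  bands <- compute_contour_bands(m, 2)
  loss_of <- function(net) {
    pm <- forward(net, x, training = TRUE)
    total_objective(pm[, , , 1], m, bands, arm = "s+c")$L
  }
  g <- isvseg:::ad_graph()
  fw <- isvseg:::network_forward_graph(g, net, x, training = TRUE)
  pred <- isvseg:::ad_value(g, fw$out)
  dpred <- array(isvseg:::objective_gradient(pred[, , , 1], m, bands,
                                             arm = "s+c"), dim(pred))
  grads <- isvseg:::ad_backward(g, fw$out, dpred)
  eps <- 1e-5
  pnames <- withr::with_seed(5, sample(names(net$params), 8))
  for (pn in pnames) {
    i <- withr::with_seed(6, sample(length(net$params[[pn]]), 1))
    n2 <- net
    n2$params[[pn]][i] <- n2$params[[pn]][i] + eps
    lp <- loss_of(n2)
    n2$params[[pn]][i] <- n2$params[[pn]][i] - 2 * eps
    lm <- loss_of(n2)
    num <- (lp - lm) / (2 * eps)
    ana <- grads[[pn]][i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3,
              label = pn)
  }
})

test_that("feature-map fusion reduces to identity and convexity cases", {
  f <- matrix(runif(16), 4, 4)
  expect_equal(fuse_feature_maps(list(f), 1), f)
  expect_equal(fuse_feature_maps(list(f, f), c(0.5, 0.5)), f)
  expect_error(fuse_feature_maps(list(), numeric(0)), "non-empty")
  expect_error(fuse_feature_maps(list(f), c(1, 2)), "one fusion weight")
})

test_that("fused upsampling matches hand-computed bilinear interpolation", {
  f <- matrix(c(1, 3, 2, 4), 2, 2)
  got <- fuse_feature_maps(list(f, matrix(0, 4, 4)), c(1, 1))
  # explicit transcription of half-pixel-centre bilinear interpolation
  expected <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      sy <- min(max((i - 0.5) * 2 / 4 - 0.5, 0), 1)
      sx <- min(max((j - 0.5) * 2 / 4 - 0.5, 0), 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, 1); x1 <- min(x0 + 1, 1)
      fy <- sy - y0; fx <- sx - x0
      expected[i, j] <- (1 - fy) * ((1 - fx) * f[y0 + 1, x0 + 1] +
                                      fx * f[y0 + 1, x1 + 1]) +
        fy * ((1 - fx) * f[y1 + 1, x0 + 1] + fx * f[y1 + 1, x1 + 1])
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("checkpoints and YAML configs round-trip", {
  dir <- withr::local_tempdir()
  net <- build_network(network_config("dual_resunet_10", base_channels = 2),
                       seed = 12)
  x <- matrix(runif(16 * 16), 16, 16)
  before <- forward(net, x)
  ck <- file.path(dir, "net.ckpt")
  save_checkpoint(net, ck)
  restored <- load_checkpoint(ck)
  expect_equal(forward(restored, x), before, tolerance = 1e-12)
  yml <- file.path(dir, "net.yaml")
  write_network_config(net$config, yml)
  expect_equal(read_network_config(yml), net$config)
})
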