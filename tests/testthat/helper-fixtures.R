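# Shared fixtures built in code.

# small centred-square binary mask
square_mask <- function(side = 8, lo = 3, hi = 6) {
  m <- matrix(0, side, side)
  m[lo:hi, lo:hi] <- 1
  m
}

# random two-channel probability maps strictly inside (0, 1)
random_pred <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 2, 0.02, 0.98), c(h, w, 2)))
}

# compact phantom settings for fast tests
small_phantom_config <- function(...) {
  phantom_config(image_size = c(64, 64), n_isv_pairs = 1, p_abnormal = 0,
                 background_vessel_prob = 0.5, seed = 7, ...)
}

# the 8-patch, 64x64 overfit fixture used by the capacity checks
overfit_patches <- function(seed = 100) {
  cfg <- phantom_config(image_size = c(64, 64), n_isv_pairs = 1,
                        p_abnormal = 0, background_vessel_prob = 0.5,
                        seed = seed)
  ds <- generate_dataset(8, cfg)
  lapply(ds$samples, function(s) list(image = s$image, mask = s$fg_mask))
}

# naive point-in-stroke rasterizer in plain R (independent of the package's
# rasterization path): a pixel is in the stroke iff its distance to the
# closest centerline segment is <= width / 2; pixel (r, c) sits at (x=c, y=r)
oracle_rasterize <- function(specs, h, w) {
  X <- matrix(rep(seq_len(w), each = h), h, w) # pixel x coords
  Y <- matrix(rep(seq_len(h), times = w), h, w) # pixel y coords
  mask <- matrix(FALSE, h, w)
  for (spec in specs) {
    pts <- spec$centerline
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]
      b <- pts[i + 1, ]
      v <- b - a
      L2 <- sum(v^2)
      t <- if (L2 > 0) ((X - a[1]) * v[1] + (Y - a[2]) * v[2]) / L2 else 0 * X
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((X - a[1] - t * v[1])^2 + (Y - a[2] - t * v[2])^2)
      mask <- mask | (d <= spec$width / 2)
    }
  }
  mask
}
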