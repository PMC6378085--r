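# Synthetic fluorescent-vessel phantoms.
#
# A phantom emulates a 2-D projection of the zebrafish trunk vasculature:
# two horizontal rails (dorsal aorta at the bottom, dorsal longitudinal
# anastomotic vessel at the top) spanned by pairs of adjacent near-vertical
# intersegmental vessels (ISVs). Each foreground ISV may carry a dimmer (or
# equally bright), slightly offset background partner -- the occluded
# contralateral vessel of the projection -- and may take an abnormal
# morphology: short (missing structure), branching, or adhesion (a bridge
# joining the two ISVs of a pair). Fluorescence intensity is modulated along
# each vessel by a low-frequency sinusoid plus a per-vessel gain, and the
# image receives additive Gaussian noise clipped to [0, 1]. Ground-truth
# masks come straight from the rasterized strokes, so they are exact.

#' Vessel specification
#'
#' @param kind one of `"normal"`, `"short"`, `"branching"`, `"adhesion"`,
#'   `"background"`.
#' @param centerline m x 2 matrix of (x, y) pixel coordinates, m >= 2.
#' @param width stroke width in pixels (> 0).
#' @param intensity_profile per-centerline-point brightness in `[0, 1]`.
#' @param role `"foreground"`, `"background"` or `"rail"` (rails are image
#'   context only and never enter the masks).
#' @return an object of class `vessel_spec`.
#' @export
vessel_spec <- function(kind, centerline, width, intensity_profile,
                        role = "foreground") {
  kinds <- c("normal", "short", "branching", "adhesion", "background")
  if (!kind %in% kinds) stop("kind must be one of: ", paste(kinds, collapse = ", "))
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2 || ncol(centerline) != 2) {
    stop("centerline must be an m x 2 matrix with m >= 2")
  }
  if (width <= 0) stop("width must be positive")
  if (any(intensity_profile < 0 | intensity_profile > 1)) {
    stop("intensity values must lie in [0, 1]")
  }
  if (length(intensity_profile) != nrow(centerline)) {
    stop("one intensity value per centerline point required")
  }
  structure(list(kind = kind, centerline = centerline, width = width,
                 intensity_profile = intensity_profile, role = role),
            class = "vessel_spec")
}

#' Phantom generator configuration
#'
#' @param image_size `(height, width)` in pixels.
#' @param n_isv_pairs number of ISV pairs (two adjacent foreground vessels
#'   each) to place; >= 0.
#' @param p_abnormal probability that a foreground ISV takes an abnormal
#'   morphology (short / branching / adhesion), in `[0, 1]`.
#' @param background_vessel_prob probability that a foreground ISV carries an
#'   occluded background partner vessel, in `[0, 1]`.
#' @param intensity_unevenness amplitude (>= 0) of the sinusoidal
#'   along-vessel brightness modulation; 0 gives flat profiles.
#' @param noise_sigma standard deviation (>= 0) of the additive Gaussian
#'   image noise (clipped to `[0, 1]`).
#' @param seed integer master seed; phantom geometry is a deterministic
#'   function of it.
#' @param anti_alias soft (distance-based) stroke edges in the rendered
#'   image; masks are always hard binary.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(192, 256), n_isv_pairs = 4,
                           p_abnormal = 0.15, background_vessel_prob = 0.7,
                           intensity_unevenness = 0.3, noise_sigma = 0.03,
                           seed = 1L, anti_alias = TRUE) {
  if (length(image_size) != 2 || any(image_size < 1)) {
    stop("image_size must be two positive integers (height, width)")
  }
  if (n_isv_pairs < 0) stop("n_isv_pairs must be >= 0")
  for (p in c(p_abnormal, background_vessel_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (intensity_unevenness < 0) stop("intensity_unevenness must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_isv_pairs = as.integer(n_isv_pairs),
                 p_abnormal = p_abnormal,
                 background_vessel_prob = background_vessel_prob,
                 intensity_unevenness = intensity_unevenness,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 anti_alias = isTRUE(anti_alias)),
            class = "phantom_config")
}

# layout constants (pixels): lateral room one pair needs, gap between pairs,
# spacing of the two ISVs within a pair, margins
PAIR_SPAN <- 34
PAIR_GAP <- 14
WITHIN_PAIR_DX <- 16
X_MARGIN <- 12
MIN_HEIGHT <- 48

phantom_min_size <- function(n_pairs) {
  c(MIN_HEIGHT,
    2 * X_MARGIN + n_pairs * PAIR_SPAN + max(0, n_pairs - 1) * PAIR_GAP)
}

# dense centerline of a near-vertical vessel between the two rails
isv_centerline <- function(x0, y_bottom, y_top, bow, wobble_phase) {
  ys <- seq(y_bottom, y_top, by = -2)
  if (ys[length(ys)] != y_top) ys <- c(ys, y_top)
  tt <- (ys - y_bottom) / (y_top - y_bottom)
  xs <- x0 + bow * sin(pi * tt + wobble_phase) * sin(pi * tt)
  cbind(xs, ys)
}

sin_profile <- function(n, gain, unevenness) {
  if (n == 1) return(gain)
  s <- seq(0, 1, length.out = n)
  freq <- runif(1, 1, 2.5)
  phase <- runif(1, 0, 2 * pi)
  pmin(pmax(gain * (1 + unevenness * sin(2 * pi * freq * s + phase)), 0.05), 1)
}

# build all vessel specs for one phantom (uses the current RNG stream);
# returns the specs plus the morphology of each trunk ISV (two per pair,
# branch and adhesion strokes excluded from the tally)
phantom_specs <- function(config) {
  H <- config$image_size[1]
  W <- config$image_size[2]
  y_top <- round(0.12 * H)
  y_bottom <- round(0.88 * H)
  specs <- list()
  # rails: DA (bottom) and DLAV (top), context only
  for (y in c(y_bottom, y_top)) {
    n <- max(2L, ceiling(W / 8))
    xs <- seq(1, W, length.out = n)
    specs[[length(specs) + 1L]] <- vessel_spec(
      "background", cbind(xs, y + runif(1, -1, 1)), width = 3.5,
      intensity_profile = sin_profile(n, runif(1, 0.65, 0.85),
                                      config$intensity_unevenness / 2),
      role = "rail")
  }
  trunk_kinds <- character(0)
  n_pairs <- config$n_isv_pairs
  if (n_pairs > 0) {
    usable <- W - 2 * X_MARGIN
    step <- usable / n_pairs
    for (k in seq_len(n_pairs)) {
      cx <- X_MARGIN + (k - 0.5) * step
      abnormal <- runif(2) < config$p_abnormal
      kinds <- ifelse(abnormal,
                      sample(c("short", "branching", "adhesion"), 2,
                             replace = TRUE),
                      "normal")
      trunk_kinds <- c(trunk_kinds, kinds)
      xs <- cx + c(-WITHIN_PAIR_DX / 2, WITHIN_PAIR_DX / 2) +
        runif(2, -2, 2)
      for (j in 1:2) {
        yb <- y_bottom
        yt <- y_top
        if (kinds[j] == "short") yt <- round(y_bottom - runif(1, 0.35, 0.6) *
                                               (y_bottom - y_top))
        cl <- isv_centerline(xs[j], yb, yt, bow = runif(1, -3, 3),
                             wobble_phase = runif(1, 0, pi))
        wd <- runif(1, 3, 4.5)
        gain <- runif(1, 0.6, 0.95)
        specs[[length(specs) + 1L]] <- vessel_spec(
          kinds[j], cl, wd,
          sin_profile(nrow(cl), gain, config$intensity_unevenness),
          role = "foreground")
        if (kinds[j] == "branching") {
          # a short branch leaving the trunk midway at an angle
          i0 <- max(2L, round(nrow(cl) * runif(1, 0.4, 0.6)))
          p0 <- cl[i0, ]
          ang <- runif(1, pi / 5, pi / 2.5) * sample(c(-1, 1), 1)
          len <- runif(1, 0.15, 0.3) * (y_bottom - y_top)
          tip <- p0 + len * c(sin(ang), -cos(ang))
          m <- 8L
          br <- cbind(seq(p0[1], tip[1], length.out = m),
                      seq(p0[2], tip[2], length.out = m))
          specs[[length(specs) + 1L]] <- vessel_spec(
            "branching", br, wd * 0.8,
            sin_profile(m, gain, config$intensity_unevenness),
            role = "foreground")
        }
        if (runif(1) < config$background_vessel_prob) {
          # occluded contralateral partner: offset, dimmer or equal
          off <- runif(1, 4, 9) * sample(c(-1, 1), 1)
          clb <- isv_centerline(xs[j] + off, y_bottom, y_top,
                                bow = runif(1, -3, 3),
                                wobble_phase = runif(1, 0, pi))
          specs[[length(specs) + 1L]] <- vessel_spec(
            "background", clb, wd * runif(1, 0.8, 1),
            sin_profile(nrow(clb), gain * runif(1, 0.5, 1),
                        config$intensity_unevenness),
            role = "background")
        }
      }
      if (any(kinds == "adhesion")) {
        # bridge joining the two ISVs of the pair partway up
        yb_ad <- y_bottom - runif(1, 0.3, 0.7) * (y_bottom - y_top)
        m <- 6L
        br <- cbind(seq(xs[1], xs[2], length.out = m),
                    yb_ad + runif(1, -2, 2) * seq(-1, 1, length.out = m)^2)
        specs[[length(specs) + 1L]] <- vessel_spec(
          "adhesion", br, runif(1, 2.5, 3.5),
          sin_profile(m, runif(1, 0.6, 0.9), config$intensity_unevenness),
          role = "foreground")
      }
    }
  }
  list(specs = specs, trunk_kinds = trunk_kinds)
}

# rasterize one spec onto (H, W): binary mask + intensity contribution
rasterize_spec <- function(spec, H, W, anti_alias = FALSE) {
  r <- stroke_distance_cpp(H, W, spec$centerline, spec$width / 2 + 1.5)
  inside <- r$dist <= spec$width / 2
  # intensity at each pixel follows the profile at the nearest centerline point
  npts <- nrow(spec$centerline)
  tt <- if (r$length > 0) pmin(pmax(r$arc / r$length, 0), 1) else r$arc * 0
  idx <- pmin(npts, pmax(1L, round(tt * (npts - 1)) + 1L))
  val <- matrix(spec$intensity_profile[idx], H, W)
  if (anti_alias) {
    alpha <- pmin(pmax(spec$width / 2 + 0.5 - r$dist, 0), 1)
  } else {
    alpha <- inside * 1
  }
  list(mask = inside, value = val * alpha, alpha = alpha)
}

#' Generate one synthetic vessel phantom
#'
#' Renders background partner vessels first, then the two rails, then the
#' foreground ISVs (painter's order, so foreground occludes background), adds
#' clipped Gaussian noise, and returns the image together with exact
#' foreground and background masks and the vessel specifications used.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom_sample`: `image` (matrix in `[0, 1]`),
#'   `fg_mask`, `bg_mask` (0/1 matrices; the foreground mask covers exactly
#'   the rasterized foreground strokes, rails excluded; the two masks may
#'   overlap where foreground occludes background), `specs` (list of
#'   [vessel_spec()]), `pair_fg_counts` (foreground pixels per ISV pair),
#'   `kinds` (morphology of each foreground ISV) and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$image_size[1]
  W <- config$image_size[2]
  mins <- phantom_min_size(config$n_isv_pairs)
  if (config$n_isv_pairs > 0 && (H < mins[1] || W < mins[2])) {
    stop("image too small for ", config$n_isv_pairs, " ISV pair(s): ",
         "minimum size is ", mins[1], "x", mins[2], " (height x width)")
  }
  with_local_seed(config$seed, {
    sp <- phantom_specs(config)
    specs <- sp$specs
    image <- matrix(0, H, W)
    fg_mask <- matrix(0, H, W)
    bg_mask <- matrix(0, H, W)
    order_roles <- c("background", "rail", "foreground")
    for (role in order_roles) {
      for (spec in specs) {
        if (spec$role != role) next
        r <- rasterize_spec(spec, H, W, anti_alias = config$anti_alias)
        paint <- r$alpha > 0
        image[paint] <- (1 - r$alpha[paint]) * image[paint] + r$value[paint]
        if (role == "foreground") fg_mask[r$mask] <- 1
        if (role == "background") bg_mask[r$mask] <- 1
      }
    }
    if (config$noise_sigma > 0) {
      image <- image + rnorm(H * W, 0, config$noise_sigma)
    }
    image <- matrix(pmin(pmax(image, 0), 1), H, W)
    # per-pair foreground pixel counts (pairs ordered left to right)
    n_pairs <- config$n_isv_pairs
    pair_counts <- integer(n_pairs)
    if (n_pairs > 0) {
      usable <- W - 2 * X_MARGIN
      step <- usable / n_pairs
      edges <- X_MARGIN + step * (0:n_pairs)
      edges[1] <- 0
      edges[n_pairs + 1] <- W + 1
      cols <- which(fg_mask == 1, arr.ind = TRUE)[, 2]
      pair_counts <- vapply(seq_len(n_pairs), function(k)
        sum(cols >= edges[k] & cols < edges[k + 1]), integer(1))
    }
    structure(list(image = image, fg_mask = fg_mask, bg_mask = bg_mask,
                   specs = specs, pair_fg_counts = pair_counts,
                   kinds = sp$trunk_kinds, config = config),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset
#'
#' `n` phantoms with per-sample seeds derived deterministically from the
#' master seed (`config$seed + index - 1`), plus a manifest tibble.
#'
#' @param n number of samples (>= 1).
#' @param config a [phantom_config()]; its `seed` is the master seed.
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (tibble: sample id, seed, comma-separated foreground morphologies,
#'   number of abnormal vessels, per-pair foreground pixel counts).
#' @export
generate_dataset <- function(n, config) {
  if (n < 1) stop("n must be >= 1")
  samples <- lapply(seq_len(n) - 1L, function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    generate_phantom(cfg)
  })
  manifest <- tibble::tibble(
    sample = seq_len(n),
    seed = config$seed + seq_len(n) - 1L,
    kinds = vapply(samples, function(s) paste(s$kinds, collapse = ","),
                   character(1)),
    n_abnormal = vapply(samples, function(s) sum(s$kinds != "normal"),
                        integer(1)),
    n_vessels = vapply(samples, function(s) length(s$kinds), integer(1)),
    pair_fg_counts = lapply(samples, function(s) s$pair_fg_counts)
  )
  list(samples = samples, manifest = manifest)
}

#' Write a phantom dataset to disk
#'
#' Images as 8-bit grayscale PNG under `images/`, foreground masks as 0/255
#' PNG under `masks/`, background masks under `bg_masks/`, and the manifest
#' as JSON.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  for (sub in c("images", "masks", "bg_masks")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    nm <- sprintf("sample_%04d.png", i)
    png::writePNG(s$image, file.path(dir, "images", nm))
    png::writePNG(s$fg_mask, file.path(dir, "masks", nm))
    png::writePNG(s$bg_mask, file.path(dir, "bg_masks", nm))
  }
  man <- dataset$manifest
  man$pair_fg_counts <- lapply(man$pair_fg_counts, as.integer)
  jsonlite::write_json(man, file.path(dir, "manifest.json"), dataframe = "rows")
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#' @param dir dataset directory.
#' @return list with `images`, `masks` (lists of matrices) and `manifest`.
#' @export
read_phantom_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  images <- lapply(files, function(f) png::readPNG(file.path(dir, "images", f)))
  masks <- lapply(files, function(f) {
    m <- png::readPNG(file.path(dir, "masks", f))
    (m > 0.5) * 1
  })
  list(images = images, masks = masks, manifest = tibble::as_tibble(man))
}
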