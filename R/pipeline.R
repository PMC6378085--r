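# Patch pipeline: adaptive pair cropping, zero-padding to square, x4
# mirror/flip augmentation, patch resizing and fold splitting.

new_patch <- function(image, mask, source = NA, box = NULL, tag = "orig") {
  structure(list(image = image, mask = mask,
                 provenance = list(source = source, box = box, tag = tag)),
            class = "patch_record")
}

#' Adaptive pair cropping
#'
#' Labels the connected foreground components of the mask (8-connectivity),
#' sorts them by centroid x and groups consecutive components in pairs so
#' that every crop contains one pair of adjacent ISVs (a trailing unpaired
#' component gets its own crop). Crop height is the pair's bounding-box
#' height expanded to at least `min_h` and clipped to `max_h` and the image
#' bounds; each crop's mask retains only the pair's own components.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param mask binary matrix.
#' @param min_h,max_h crop height bounds in pixels (defaults 120 and 160).
#' @param margin lateral margin around the pair's bounding box (pixels).
#' @param source identifier recorded in each crop's provenance.
#' @return list of `patch_record`s (empty when the mask is empty).
#' @export
crop_isv_regions <- function(image, mask, min_h = 120, max_h = 160,
                             margin = 6, source = NA) {
  mask <- check_binary(mask, "mask")
  if (sum(mask) == 0) return(list())
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  cx <- vapply(seq_len(n_comp), function(k)
    mean(which(lab == k, arr.ind = TRUE)[, 2]), numeric(1))
  ord <- order(cx)
  groups <- split(ord, ceiling(seq_along(ord) / 2))
  H <- nrow(mask)
  W <- ncol(mask)
  lapply(seq_along(groups), function(gi) {
    comps <- groups[[gi]]
    sel <- lab %in% comps
    dim(sel) <- dim(lab)
    idx <- which(sel, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    h <- min(max(r1 - r0 + 1 + 2 * margin, min_h), max_h, H)
    rc <- (r0 + r1) / 2
    top <- round(rc - h / 2 + 1)
    top <- min(max(top, 1), H - h + 1)
    left <- max(c0 - margin, 1)
    right <- min(c1 + margin, W)
    rows <- top:(top + h - 1)
    cols <- left:right
    m <- (sel & mask == 1) * 1
    new_patch(image[rows, cols, drop = FALSE],
              m[rows, cols, drop = FALSE],
              source = source,
              box = c(top = top, left = left, height = h,
                      width = length(cols)))
  })
}

#' Zero-pad a patch to a square
#'
#' Pads the shorter side with zeros (image and mask alike), content centered;
#' idempotent on already-square patches.
#'
#' @param patch a `patch_record`.
#' @return a square `patch_record`.
#' @export
pad_to_square <- function(patch) {
  h <- nrow(patch$image)
  w <- ncol(patch$image)
  if (h == w) return(patch)
  side <- max(h, w)
  pad <- function(m) {
    out <- matrix(0, side, side)
    r0 <- floor((side - h) / 2)
    c0 <- floor((side - w) / 2)
    out[r0 + seq_len(h), c0 + seq_len(w)] <- m
    out
  }
  new_patch(pad(patch$image), pad(patch$mask),
            source = patch$provenance$source, box = patch$provenance$box,
            tag = patch$provenance$tag)
}

#' Mirror/flip augmentation (x4)
#'
#' Returns the original patch plus its horizontal mirror (left-right), its
#' vertical flip (up-down) and the combination, with image and mask
#' transformed congruently. Mask pixel counts are preserved, so the
#' augmented set is exactly four times the input.
#'
#' @param patch a square `patch_record`.
#' @return list of 4 `patch_record`s tagged `orig`, `mirror`, `flip`,
#'   `mirror+flip`.
#' @export
augment_mirror_flip <- function(patch) {
  mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  mk <- function(f, tag) {
    new_patch(f(patch$image), f(patch$mask),
              source = patch$provenance$source, box = patch$provenance$box,
              tag = tag)
  }
  list(mk(identity, "orig"), mk(mirror, "mirror"), mk(flip, "flip"),
       mk(function(m) flip(mirror(m)), "mirror+flip"))
}

#' Resize a square patch
#'
#' Image resized bilinearly; mask resized by nearest neighbour and
#' re-binarized, so mask values stay in \{0, 1\}.
#'
#' @param patch a square `patch_record`.
#' @param side target side in pixels (default 128, the training patch size).
#' @return a `patch_record` of size `side x side`.
#' @export
resize_patch <- function(patch, side = 128) {
  h <- nrow(patch$image)
  w <- ncol(patch$image)
  if (h == side && w == side) return(patch)
  img <- bilinear_resize_cpp(patch$image, side, side)
  mask <- nearest_resize(patch$mask, side, side)
  new_patch(img, (mask > 0.5) * 1, source = patch$provenance$source,
            box = patch$provenance$box, tag = patch$provenance$tag)
}

# nearest-neighbour resize with half-pixel centre alignment
nearest_resize <- function(m, out_h, out_w) {
  H <- nrow(m)
  W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * H / out_h) + 1, 1), H)
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * W / out_w) + 1, 1), W)
  m[ri, ci, drop = FALSE]
}

#' Train/test/validation fold splits
#'
#' Five (by default) independently seeded re-splits at the 60/20/20 ratio;
#' within each fold the three sets are disjoint and jointly cover all ids.
#'
#' @param ids vector of sample identifiers (>= n_folds elements).
#' @param ratios train/test/validation proportions (must sum to 1).
#' @param n_folds number of cross-validation sessions (default 5).
#' @param seed integer; fold `k` shuffles with seed `seed + k`.
#' @return list of `fold_split` lists: `train`, `test`, `validation`, `fold`.
#' @export
split_folds <- function(ids, ratios = c(0.6, 0.2, 0.2), n_folds = 5,
                        seed = 1L) {
  n <- length(ids)
  if (n < n_folds) stop("need at least as many ids as folds")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  n_tr <- round(ratios[1] * n)
  n_te <- round(ratios[2] * n)
  n_va <- n - n_tr - n_te
  if (min(n_tr, n_te, n_va) < 1) stop("too few ids for the requested ratios")
  lapply(seq_len(n_folds), function(k) {
    perm <- with_local_seed(seed + k, sample(ids))
    structure(list(train = perm[seq_len(n_tr)],
                   test = perm[n_tr + seq_len(n_te)],
                   validation = perm[n_tr + n_te + seq_len(n_va)],
                   fold = k),
              class = "fold_split")
  })
}

#' Full patch preparation pipeline
#'
#' crop -> pad to square -> (optional) x4 augmentation -> resize. The
#' composition never produces mask values outside \{0, 1\}.
#'
#' @param image,mask a full frame and its binary foreground mask.
#' @param side output patch side (default 128).
#' @param augment apply [augment_mirror_flip()] (default TRUE).
#' @param ... passed to [crop_isv_regions()].
#' @return list of `patch_record`s.
#' @export
prepare_patches <- function(image, mask, side = 128, augment = TRUE, ...) {
  crops <- crop_isv_regions(image, mask, ...)
  out <- list()
  for (cr in crops) {
    sq <- pad_to_square(cr)
    ps <- if (augment) augment_mirror_flip(sq) else list(sq)
    for (p in ps) out[[length(out) + 1L]] <- resize_patch(p, side)
  }
  out
}

#' Write / read a patch set as paired PNG directories plus a manifest
#' @param patches list of `patch_record`s.
#' @param dir output directory.
#' @export
write_patch_set <- function(patches, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    nm <- sprintf("patch_%05d.png", i)
    png::writePNG(pmin(pmax(p$image, 0), 1), file.path(dir, "images", nm))
    png::writePNG(p$mask, file.path(dir, "masks", nm))
    tibble::tibble(file = nm, source = as.character(p$provenance$source),
                   tag = p$provenance$tag)
  })
  man <- do.call(rbind, rows)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  invisible(dir)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(seq_len(nrow(man)), function(i) {
    nm <- man$file[i]
    img <- png::readPNG(file.path(dir, "images", nm))
    msk <- (png::readPNG(file.path(dir, "masks", nm)) > 0.5) * 1
    new_patch(img, msk, source = man$source[i], tag = man$tag[i])
  })
}
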