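# Pixel-level evaluation: confusion counts, accuracy and Dice, PR/ROC/AUC
# threshold sweeps, per-image aggregation, paired t-tests and TP/FP/FN
# overlay rendering.

#' Binarize probability maps
#'
#' Per-pixel comparison of the two output channels: a pixel is ISV iff its
#' ISV probability strictly exceeds its non-ISV probability; ties go to
#' non-ISV.
#'
#' @param prob_maps array `(H, W, 2)` (ISV channel first).
#' @return binary matrix.
#' @export
binarize <- function(prob_maps) {
  d <- dim(prob_maps)
  if (length(d) != 3 || d[3] != 2) stop("expected (H, W, 2) probability maps")
  (prob_maps[, , 1] > prob_maps[, , 2]) * 1
}

#' Pixel confusion counts
#'
#' @param pred,gt congruent binary masks.
#' @return object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`;
#'   the four always sum to the number of pixels.
#' @export
confusion_counts <- function(pred, gt) {
  pred <- check_binary(pred, "pred")
  gt <- check_binary(gt, "gt")
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  structure(list(TP = sum(pred == 1 & gt == 1),
                 FP = sum(pred == 1 & gt == 0),
                 TN = sum(pred == 0 & gt == 0),
                 FN = sum(pred == 0 & gt == 1)),
            class = "confusion_counts")
}

#' Pixel accuracy (percent) and Dice coefficient
#'
#' `accuracy = 100 * (TP + TN) / (TP + TN + FP + FN)`;
#' `Dice = 2 TP / (2 TP + FN + FP)`, defined as 1 for the empty-vs-empty
#' case (no foreground in either mask).
#'
#' @param c a `confusion_counts`.
#' @return scalar.
#' @export
pixel_accuracy <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("empty region: no pixels to evaluate")
  100 * (c$TP + c$TN) / total
}

#' @rdname pixel_accuracy
#' @export
dice <- function(c) {
  denom <- 2 * c$TP + c$FN + c$FP
  if (denom == 0) {
    out <- 1
    attr(out, "empty_vs_empty") <- TRUE
    return(out)
  }
  2 * c$TP / denom
}

default_thresholds <- function(scores) {
  th <- seq(0, 1, length.out = 256)
  if (length(scores) <= 1e4) th <- c(th, unique(as.numeric(scores)))
  sort(unique(th))
}

#' Precision-recall and ROC threshold sweeps
#'
#' Sweeps a threshold over the ISV probability map (`pred = score >= t`).
#' PR points with no predicted positives are dropped (flagged via the
#' `n_dropped` attribute); for a ground truth that is all one class the ROC
#' is undefined and an error is raised.
#'
#' @param scores ISV probability matrix.
#' @param gt binary matrix.
#' @param thresholds optional sorted thresholds; the default grid is 256
#'   evenly spaced values plus every distinct score when the image has at
#'   most 10^4 pixels.
#' @return tibble of curve points (`threshold`, `precision`, `recall` /
#'   `threshold`, `fpr`, `tpr`).
#' @export
pr_curve <- function(scores, gt, thresholds = NULL) {
  gt <- check_binary(gt, "gt")
  if (is.null(thresholds)) thresholds <- default_thresholds(scores)
  s <- as.numeric(scores)
  g <- as.numeric(gt)
  npos <- sum(g)
  if (npos == 0) stop("ground truth has no positive pixels; PR undefined")
  rows <- lapply(thresholds, function(t) {
    p <- s >= t
    tp <- sum(p & g == 1)
    fp <- sum(p & g == 0)
    if (tp + fp == 0) return(NULL)
    tibble::tibble(threshold = t, precision = tp / (tp + fp),
                   recall = tp / npos)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  # conventional anchor: zero recall at perfect precision
  out <- rbind(out, tibble::tibble(threshold = Inf, precision = 1,
                                   recall = 0))
  attr(out, "n_dropped") <- dropped
  out
}

#' @rdname pr_curve
#' @export
roc_curve <- function(scores, gt, thresholds = NULL) {
  gt <- check_binary(gt, "gt")
  if (is.null(thresholds)) thresholds <- default_thresholds(scores)
  s <- as.numeric(scores)
  g <- as.numeric(gt)
  npos <- sum(g)
  nneg <- sum(1 - g)
  if (npos == 0 || nneg == 0) {
    stop("ground truth has a single class; ROC undefined")
  }
  rows <- lapply(thresholds, function(t) {
    p <- s >= t
    tibble::tibble(threshold = t, fpr = sum(p & g == 0) / nneg,
                   tpr = sum(p & g == 1) / npos)
  })
  out <- do.call(rbind, rows)
  # anchor the curve at its extremes
  out <- rbind(tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1), out,
               tibble::tibble(threshold = Inf, fpr = 0, tpr = 0))
  out
}

#' Trapezoidal area under a curve
#'
#' @param curve a [pr_curve()] or [roc_curve()] tibble (or any data frame
#'   whose first two metric columns are x and y).
#' @param x,y column names; defaults pick `fpr`/`tpr` for ROC tibbles and
#'   `recall`/`precision` for PR tibbles.
#' @return scalar area.
#' @export
auc <- function(curve, x = NULL, y = NULL) {
  if (is.null(x)) {
    if ("fpr" %in% names(curve)) {
      x <- "fpr"
      y <- "tpr"
    } else {
      x <- "recall"
      y <- "precision"
    }
  }
  xs <- curve[[x]]
  ys <- curve[[y]]
  # trapezoid over the step curve: sorting by (x, y) makes each vertical
  # segment contribute zero area, matching the rank-statistic AUC for ROC
  ord <- order(xs, ys)
  xs <- xs[ord]
  ys <- ys[ord]
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Aggregate per-image metrics
#'
#' Median, mean and sample standard deviation of a per-image metric vector
#' (a single image yields sd 0).
#'
#' @param values numeric vector (>= 1 value).
#' @return a `metrics_record` tibble: `n`, `median`, `mean`, `sd`.
#' @export
summarize_metrics <- function(values) {
  stopifnot(length(values) >= 1)
  tibble::tibble(n = length(values), median = median(values),
                 mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0)
}

#' Paired t-test between two per-image metric vectors
#'
#' Two-sided paired t-test on the per-image differences, flagged significant
#' at the 5% level. Zero-variance differences are handled explicitly: all
#' zero gives p = 1 (not significant); a non-zero constant difference is the
#' exact-t limit (p -> 0), flagged `degenerate`.
#'
#' @param metrics_a,metrics_b equal-length numeric vectors, n >= 2.
#' @return list: `p_value`, `t`, `df`, `significant` (p < 0.05),
#'   `degenerate`.
#' @export
paired_t_test <- function(metrics_a, metrics_b) {
  stopifnot(length(metrics_a) == length(metrics_b), length(metrics_a) >= 2)
  d <- metrics_a - metrics_b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(p_value = 1, t = 0, df = length(d) - 1,
                  significant = FALSE, degenerate = TRUE))
    }
    return(list(p_value = 0, t = sign(mean(d)) * Inf, df = length(d) - 1,
                significant = TRUE, degenerate = TRUE))
  }
  tt <- t.test(metrics_a, metrics_b, paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), significant = tt$p.value < 0.05,
       degenerate = FALSE)
}

#' TP/FP/FN overlay rendering
#'
#' Paints true positives red, false positives blue and false negatives
#' yellow over the grayscale base image; true negatives keep the base
#' intensity. The per-colour pixel tallies of the rendered overlay equal the
#' confusion counts exactly.
#'
#' @param pred,gt congruent binary masks.
#' @param base grayscale matrix in `[0, 1]`.
#' @return `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
render_overlay <- function(pred, gt, base) {
  pred <- check_binary(pred, "pred")
  gt <- check_binary(gt, "gt")
  if (!all(dim(pred) == dim(gt)) || !all(dim(pred) == dim(base))) {
    stop("pred, gt and base must be congruent")
  }
  out <- array(rep(base, 3), c(dim(base), 3))
  tp <- pred == 1 & gt == 1
  fp <- pred == 1 & gt == 0
  fn <- pred == 0 & gt == 1
  paint <- function(out, sel, rgb) {
    for (k in 1:3) {
      ch <- out[, , k]
      ch[sel] <- rgb[k]
      out[, , k] <- ch
    }
    out
  }
  out <- paint(out, tp, c(1, 0, 0))
  out <- paint(out, fp, c(0, 0, 1))
  out <- paint(out, fn, c(1, 1, 0))
  out
}

#' Evaluate predictions against ground truth
#'
#' Per-image accuracy and Dice (computed per image then aggregated, matching
#' median/mean/sd reporting over a dataset).
#'
#' @param preds,gts lists of congruent binary masks.
#' @return list with `per_image` (tibble: image, accuracy, dice) and
#'   `aggregate` (tibble with one row per metric).
#' @export
evaluate_masks <- function(preds, gts) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion_counts(preds[[i]], gts[[i]])
    tibble::tibble(image = i, accuracy = pixel_accuracy(cc),
                   dice = as.numeric(dice(cc)))
  })
  per_image <- do.call(rbind, rows)
  aggregate <- rbind(
    cbind(tibble::tibble(metric = "accuracy"),
          summarize_metrics(per_image$accuracy)),
    cbind(tibble::tibble(metric = "dice"), summarize_metrics(per_image$dice))
  )
  list(per_image = per_image, aggregate = aggregate)
}

#' Curve and boxplot figures
#'
#' @param curve a [pr_curve()] or [roc_curve()] tibble.
#' @return a ggplot object.
#' @export
plot_pr_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = recall, y = precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision")
}

#' @rdname plot_pr_curve
#' @export
plot_roc_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate")
}

#' @param per_image a long tibble with columns `method`, `metric`, `value`.
#' @rdname plot_pr_curve
#' @export
plot_metric_boxplot <- function(per_image) {
  ggplot2::ggplot(per_image,
                  ggplot2::aes(x = method, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
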