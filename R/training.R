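# Training protocol: Gaussian re-initialization, SGD with momentum and L2
# weight decay, learning-rate halving against the first-10-epoch baseline,
# relative-difference early stopping, per-epoch validation and
# best-validation checkpointing.

#' Training configuration
#'
#' @param lr0 initial learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 coefficient applied to convolution weights during
#'   the update (default `5e-4`).
#' @param max_epochs epoch cap (default 150).
#' @param rel_tol stopping tolerance on the relative loss difference between
#'   consecutive epochs (default `1e-4`).
#' @param halving_frac halve the learning rate when the epoch-to-epoch loss
#'   improvement is below this fraction of the first-10-epoch baseline
#'   (default 0.01).
#' @param baseline_epochs epochs whose mean loss forms the baseline
#'   (default 10).
#' @param batch_size minibatch size (default 4; the source protocol does not
#'   state one).
#' @param optimizer `"sgd"` (momentum SGD, the default protocol) or
#'   `"adam"` (useful on very small fixtures where few update steps are
#'   available).
#' @param arm loss arm: `"s+c"` (default), `"wce"`, `"c"`, `"s"`.
#' @param band_width,pos_weight loss-term settings.
#' @param seed seed controlling shuffling (and any other training
#'   randomness).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001, momentum = 0.9, weight_decay = 5e-4,
                         max_epochs = 150, rel_tol = 1e-4,
                         halving_frac = 0.01, baseline_epochs = 10,
                         batch_size = 4, arm = "s+c", band_width = 2,
                         pos_weight = 1, optimizer = c("sgd", "adam"),
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr0 > 0, momentum >= 0, weight_decay >= 0, max_epochs >= 0,
            rel_tol > 0, halving_frac > 0, batch_size >= 1)
  structure(list(lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), rel_tol = rel_tol,
                 halving_frac = halving_frac,
                 baseline_epochs = as.integer(baseline_epochs),
                 batch_size = as.integer(batch_size), arm = arm,
                 band_width = band_width, pos_weight = pos_weight,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' Training state
#'
#' Tracks the epoch counter, current learning rate, loss history, the frozen
#' first-10-epoch baseline driving learning-rate halving, and the stopping
#' flag/reason.
#'
#' @param lr0 initial learning rate.
#' @param config the `train_config` in force (defaults used when omitted).
#' @return an object of class `training_state`.
#' @export
training_state <- function(lr0 = 0.001, config = train_config(lr0 = lr0)) {
  structure(list(epoch = 0L, lr = lr0, loss_history = numeric(0),
                 baseline = NA_real_, stopped = FALSE, reason = NA_character_,
                 config = config),
            class = "training_state")
}

#' Learning-rate halving step
#'
#' Appends the epoch's mean loss to the history. During the first
#' `baseline_epochs` epochs the rate is left untouched (the baseline is
#' forming); the baseline is then frozen as the mean loss of those epochs,
#' and from the next epoch on the learning rate is halved whenever the
#' improvement over the previous epoch, `prev - current`, falls below
#' `halving_frac * baseline`.
#'
#' @param state a `training_state`.
#' @param epoch_loss mean training loss of the finished epoch.
#' @return the updated `training_state`.
#' @export
lr_schedule_step <- function(state, epoch_loss) {
  cfg <- state$config
  state$loss_history <- c(state$loss_history, epoch_loss)
  state$epoch <- state$epoch + 1L
  ne <- length(state$loss_history)
  if (ne == cfg$baseline_epochs) {
    state$baseline <- mean(state$loss_history)
  }
  if (ne > cfg$baseline_epochs && !is.na(state$baseline)) {
    improvement <- state$loss_history[ne - 1] - epoch_loss
    if (improvement < cfg$halving_frac * state$baseline) {
      state$lr <- state$lr / 2
    }
  }
  state
}

#' Stopping criterion
#'
#' Stops when the relative difference between consecutive epoch losses,
#' `|prev - current| / max(|prev|, eps)`, drops below `rel_tol`, or when the
#' epoch cap is reached.
#'
#' @param state a `training_state` with >= 1 recorded epochs.
#' @return list with `stop` (logical) and `reason` (`"max_epochs"`,
#'   `"converged"` or `NA`).
#' @export
stopping_criterion <- function(state) {
  cfg <- state$config
  ne <- length(state$loss_history)
  if (state$epoch >= cfg$max_epochs) {
    return(list(stop = TRUE, reason = "max_epochs"))
  }
  if (ne >= 2) {
    prev <- state$loss_history[ne - 1]
    cur <- state$loss_history[ne]
    rel <- abs(prev - cur) / max(abs(prev), 1e-12)
    if (rel < cfg$rel_tol) return(list(stop = TRUE, reason = "converged"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Re-initialize network weights
#'
#' Conv and transposed-conv weights are drawn from zero-mean Gaussians with
#' He fan-in scaling (`sd = sqrt(2 / fan_in)`); biases are zeroed; batch-norm
#' scales reset to 1/0 and running statistics to 0/1. Deterministic given the
#' seed.
#'
#' @param network an `isv_network`.
#' @param seed integer seed.
#' @return the re-initialized network.
#' @export
init_weights <- function(network, seed) {
  network$params <- with_local_seed(seed, {
    p <- network$params
    for (nm in names(p)) p[[nm]] <- init_param(dim(p[[nm]]) %||%
                                                 length(p[[nm]]), nm)
    p
  })
  for (nm in ls(network$state)) {
    network$state[[nm]] <- if (grepl("\\.rv$", nm))
      rep(1, length(network$state[[nm]]))
    else numeric(length(network$state[[nm]]))
  }
  network
}

# one optimizer update; weight decay (L2) only on conv/tconv kernels
optim_init <- function(params, optimizer) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  if (optimizer == "adam") list(m = zeros, v = zeros, t = 0L)
  else list(velocity = zeros)
}

optim_step <- function(params, grads, opt, lr, config) {
  wd <- config$weight_decay
  if (config$optimizer == "adam") {
    b1 <- 0.9
    b2 <- 0.999
    eps <- 1e-8
    opt$t <- opt$t + 1L
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      if (wd > 0 && grepl("\\.w$", nm)) g <- g + wd * params[[nm]]
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mh <- opt$m[[nm]] / (1 - b1^opt$t)
      vh <- opt$v[[nm]] / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - array(lr * mh / (sqrt(vh) + eps),
                                           dim(params[[nm]]) %||%
                                             length(params[[nm]]))
    }
  } else {
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      if (wd > 0 && grepl("\\.w$", nm)) g <- g + wd * params[[nm]]
      v <- config$momentum * opt$velocity[[nm]] - lr * as.numeric(g)
      opt$velocity[[nm]] <- v
      params[[nm]] <- params[[nm]] + array(v, dim(params[[nm]]) %||%
                                             length(params[[nm]]))
    }
  }
  list(params = params, opt = opt)
}

# stack a list of (H, W) patches into an (H, W, 1, N) batch
stack_patches <- function(patches, field) {
  H <- nrow(patches[[1]][[field]])
  W <- ncol(patches[[1]][[field]])
  arr <- array(0, c(H, W, 1L, length(patches)))
  for (i in seq_along(patches)) arr[, , 1, i] <- patches[[i]][[field]]
  arr
}

#' Re-estimate batch-norm population statistics
#'
#' Replaces the exponentially averaged batch-norm running statistics with the
#' statistics of one forward pass over a calibration batch (up to
#' `max_images` images in a single batch). Training optimizes the network
#' under within-batch statistics; after few, small batches the running
#' averages can sit far from the population values, degrading
#' evaluation-mode predictions. This one-pass re-estimation closes that gap.
#'
#' @param network an `isv_network`.
#' @param images list of image matrices (typically the training images).
#' @param max_images calibration batch cap (default 32).
#' @return the network with updated running statistics.
#' @export
calibrate_bn <- function(network, images, max_images = 32) {
  sel <- images[seq_len(min(length(images), max_images))]
  H <- nrow(sel[[1]])
  W <- ncol(sel[[1]])
  x <- array(0, c(H, W, 1L, length(sel)))
  for (i in seq_along(sel)) x[, , 1, i] <- sel[[i]]
  network$state$.bn_momentum <- 1
  on.exit(rm(".bn_momentum", envir = network$state))
  invisible(forward(network, x, training = TRUE))
  network
}

#' Train a network
#'
#' Per epoch: seeded shuffle, minibatch forward pass (training-mode batch
#' norm), combined objective, backpropagation through the tape, SGD update
#' with momentum and weight decay; then the learning-rate halving rule and
#' the stopping criterion. When a validation set is supplied its loss is
#' recorded each epoch and the weights with the lowest validation loss are
#' the ones returned (training loss is used otherwise). After training the
#' batch-norm running statistics are re-estimated over the training images
#' ([calibrate_bn()]) so evaluation-mode predictions match what the
#' optimizer saw. A non-finite loss aborts with a diagnostic naming the
#' epoch.
#'
#' @param network an `isv_network`.
#' @param patches list of `patch_record`s (or any lists with `image` and
#'   `mask` matrices).
#' @param config a [train_config()].
#' @param val_patches optional validation patches.
#' @param verbose print one line per epoch.
#' @return list with `network` (best checkpoint), `state`
#'   (`training_state`) and `log` (tibble: epoch, loss, val_loss, lr).
#' @export
train <- function(network, patches, config = train_config(),
                  val_patches = NULL, verbose = FALSE) {
  stopifnot(length(patches) >= 1)
  state <- training_state(config$lr0, config)
  if (config$max_epochs == 0L) {
    return(list(network = network, state = state,
                log = tibble::tibble(epoch = integer(0), loss = numeric(0),
                                     val_loss = numeric(0), lr = numeric(0))))
  }
  masks <- lapply(patches, function(p) check_binary(p$mask, "mask"))
  bands <- lapply(masks, compute_contour_bands, band_width = config$band_width)
  if (!is.null(val_patches)) {
    val_masks <- lapply(val_patches, function(p) check_binary(p$mask, "mask"))
    val_bands <- lapply(val_masks, compute_contour_bands,
                        band_width = config$band_width)
  }
  opt <- optim_init(network$params, config$optimizer)
  n <- length(patches)
  best <- list(loss = Inf, params = network$params,
               state = as.list(network$state))
  log_rows <- list()
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- with_local_seed(config$seed + epoch, sample(n))
    batch_starts <- seq(1, n, by = config$batch_size)
    epoch_losses <- numeric(0)
    for (b in batch_starts) {
      sel <- ord[b:min(b + config$batch_size - 1, n)]
      x <- stack_patches(patches[sel], "image")
      g <- ad_graph()
      fw <- network_forward_graph(g, network, x, training = TRUE)
      pred <- ad_value(g, fw$out)
      nb <- length(sel)
      dpred <- array(0, dim(pred))
      bl <- 0
      for (j in seq_len(nb)) {
        pj <- pred[, , , j]
        lb <- total_objective(pj, masks[[sel[j]]], bands[[sel[j]]],
                              arm = config$arm,
                              pos_weight = config$pos_weight,
                              weight_decay = config$weight_decay)
        if (!is.finite(lb$L)) {
          stop("training diverged at epoch ", epoch, " (arm '", config$arm,
               "'): non-finite loss")
        }
        bl <- bl + lb$L / nb
        dpred[, , , j] <- objective_gradient(pj, masks[[sel[j]]],
                                             bands[[sel[j]]],
                                             arm = config$arm,
                                             pos_weight = config$pos_weight) / nb
      }
      grads <- ad_backward(g, fw$out, dpred)
      upd <- optim_step(network$params, grads, opt, state$lr, config)
      network$params <- upd$params
      opt <- upd$opt
      epoch_losses <- c(epoch_losses, bl)
    }
    epoch_loss <- mean(epoch_losses)
    val_loss <- NA_real_
    if (!is.null(val_patches)) {
      val_loss <- mean(vapply(seq_along(val_patches), function(j) {
        pj <- forward(network, val_patches[[j]]$image)
        total_objective(pj, val_masks[[j]], val_bands[[j]],
                        arm = config$arm, pos_weight = config$pos_weight)$L
      }, numeric(1)))
    }
    sel_loss <- if (is.na(val_loss)) epoch_loss else val_loss
    if (sel_loss < best$loss) {
      best <- list(loss = sel_loss, params = network$params,
                   state = as.list(network$state))
    }
    state <- lr_schedule_step(state, epoch_loss)
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss,
                                        val_loss = val_loss, lr = state$lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  val %.5f  lr %.2e", epoch,
                      epoch_loss, val_loss, state$lr))
    }
    sc <- stopping_criterion(state)
    if (sc$stop) {
      state$stopped <- TRUE
      state$reason <- sc$reason
      break
    }
  }
  network$params <- best$params
  for (nm in names(best$state)) network$state[[nm]] <- best$state[[nm]]
  network <- calibrate_bn(network, lapply(patches, `[[`, "image"))
  list(network = network, state = state, log = do.call(rbind, log_rows))
}
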