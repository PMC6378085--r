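#' Network architecture configuration
#'
#' Describes a Dual ResUNet variant: a bridged pair of encoder--decoder
#' sub-networks built from full pre-activation residual units
#' (BN -> ReLU -> 3x3 conv, twice, plus an identity addition). The variant
#' name fixes the total residual-unit count, split equally across the two
#' sub-networks; each sub-network has `(units/2 - 1)/2` resolution levels on
#' each side of a bottleneck unit. `dual_unet_14` swaps the residual units for
#' plain convolutional units, and `single_resunet` is the unbridged
#' single-network sibling (7 units).
#'
#' @param variant one of `"dual_resunet_14"` (default), `"dual_resunet_10"`,
#'   `"dual_resunet_18"`, `"dual_unet_14"`, `"single_resunet"`.
#' @param base_channels feature channels at the first resolution level;
#'   channels double at each downsampling. Default 32; small values (e.g. 4)
#'   give CPU-sized networks.
#' @param in_channels input image channels (default 1, grayscale).
#' @param out_channels output probability maps (default 2: ISV and non-ISV).
#' @return an object of class `isv_network_config`.
#' @export
network_config <- function(variant = "dual_resunet_14", base_channels = 32,
                           in_channels = 1, out_channels = 2) {
  variants <- c(dual_resunet_10 = 10L, dual_resunet_14 = 14L,
                dual_resunet_18 = 18L, dual_unet_14 = 14L, single_resunet = 7L)
  if (!variant %in% names(variants)) {
    stop("unknown variant '", variant, "'; must be one of: ",
         paste(names(variants), collapse = ", "))
  }
  if (base_channels < 1) stop("base_channels must be >= 1")
  n_units <- unname(variants[variant])
  n_subnets <- if (variant == "single_resunet") 1L else 2L
  units_per_net <- n_units %/% n_subnets
  depth <- (units_per_net - 1L) %/% 2L # encoder levels per sub-network
  structure(list(variant = variant, base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_units = n_units, n_subnets = n_subnets,
                 units_per_net = units_per_net, depth = depth,
                 unit_type = if (variant == "dual_unet_14") "plain" else "res"),
            class = "isv_network_config")
}

# channel bookkeeping for one sub-network
subnet_channels <- function(config) {
  base <- config$base_channels
  E <- config$depth
  list(
    enc_in = vapply(seq_len(E), function(l)
      if (l == 1) config$in_channels
      else as.integer(base * 2^(l - 2)), integer(1)),
    enc_out = vapply(seq_len(E), function(l)
      as.integer(base * 2^(l - 1)), integer(1)),
    mid_in = as.integer(base * 2^(E - 1)),
    mid_out = as.integer(base * 2^E),
    dec = vapply(seq_len(E), function(l)
      as.integer(base * 2^(l - 1)), integer(1))
  )
}

unit_param_shapes <- function(name, cin, cout, type) {
  if (type == "res") {
    shapes <- list(c(cin), c(cin), c(3L, 3L, cin, cout), c(cout),
                   c(cout), c(cout), c(3L, 3L, cout, cout), c(cout))
    names(shapes) <- paste0(name, c(".bn1.gamma", ".bn1.beta", ".conv1.w",
                                    ".conv1.b", ".bn2.gamma", ".bn2.beta",
                                    ".conv2.w", ".conv2.b"))
    if (cin != cout) {
      shapes[[paste0(name, ".proj.w")]] <- c(1L, 1L, cin, cout)
      shapes[[paste0(name, ".proj.b")]] <- c(cout)
    }
  } else {
    shapes <- list(c(3L, 3L, cin, cout), c(cout), c(cout), c(cout),
                   c(3L, 3L, cout, cout), c(cout), c(cout), c(cout))
    names(shapes) <- paste0(name, c(".conv1.w", ".conv1.b", ".bn1.gamma",
                                    ".bn1.beta", ".conv2.w", ".conv2.b",
                                    ".bn2.gamma", ".bn2.beta"))
  }
  shapes
}

# full parameter-shape plan plus the ordered residual-unit registry
arch_plan <- function(config) {
  ch <- subnet_channels(config)
  E <- config$depth
  shapes <- list()
  registry <- list()
  for (s in seq_len(config$n_subnets)) {
    pre <- paste0("n", s)
    for (l in seq_len(E)) {
      if (s == 2L) {
        # bridge: decoder features of net 1 concatenated in, then a 1x1 conv
        # restores the channel count the encoder unit expects
        shapes[[paste0(pre, ".br", l, ".w")]] <-
          c(1L, 1L, ch$enc_in[l] + ch$dec[l], ch$enc_in[l])
        shapes[[paste0(pre, ".br", l, ".b")]] <- ch$enc_in[l]
      }
      nm <- paste0(pre, ".enc", l)
      shapes <- c(shapes, unit_param_shapes(nm, ch$enc_in[l], ch$enc_out[l],
                                            config$unit_type))
      registry[[length(registry) + 1L]] <-
        list(subnet = s, stage = "encoder", level = l,
             in_ch = ch$enc_in[l], out_ch = ch$enc_out[l])
    }
    nm <- paste0(pre, ".mid")
    shapes <- c(shapes, unit_param_shapes(nm, ch$mid_in, ch$mid_out,
                                          config$unit_type))
    registry[[length(registry) + 1L]] <-
      list(subnet = s, stage = "bottleneck", level = E + 1L,
           in_ch = ch$mid_in, out_ch = ch$mid_out)
    for (l in rev(seq_len(E))) {
      cin_up <- as.integer(config$base_channels * 2^l)
      cout_up <- as.integer(config$base_channels * 2^(l - 1))
      shapes[[paste0(pre, ".up", l, ".w")]] <- c(2L, 2L, cin_up, cout_up)
      shapes[[paste0(pre, ".up", l, ".b")]] <- cout_up
      shapes[[paste0(pre, ".upbn", l, ".gamma")]] <- cout_up
      shapes[[paste0(pre, ".upbn", l, ".beta")]] <- cout_up
      nm <- paste0(pre, ".dec", l)
      shapes <- c(shapes, unit_param_shapes(nm, ch$dec[l], ch$dec[l],
                                            config$unit_type))
      registry[[length(registry) + 1L]] <-
        list(subnet = s, stage = "decoder", level = l,
             in_ch = ch$dec[l], out_ch = ch$dec[l])
    }
  }
  shapes[["head.w"]] <- c(1L, 1L, config$base_channels, config$out_channels)
  shapes[["head.b"]] <- config$out_channels
  registry <- do.call(rbind, lapply(registry, function(r)
    tibble::as_tibble(r)))
  list(shapes = shapes, registry = registry)
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

init_param <- function(shape, name) {
  n <- prod(shape)
  if (grepl("\\.gamma$", name)) return(array(1, shape))
  if (grepl("\\.(beta|b)$", name)) return(array(0, shape))
  # conv / tconv weights: zero-mean Gaussian, He scaling by fan-in
  k <- length(shape)
  fan_in <- if (k == 4) shape[1] * shape[2] * shape[3] else shape[1]
  array(rnorm(n, 0, sqrt(2 / fan_in)), shape)
}

#' Build a Dual ResUNet
#'
#' Constructs the computation network described by a [network_config()]:
#' per sub-network, an encoder path (residual unit + 2x2/stride-2 max pooling,
#' channels doubling per level), a bottleneck unit, and a decoder path
#' (2x2/stride-2 transposed convolution halving channels, then BN and ReLU,
#' an element-wise-addition skip from the same-resolution encoder level, and a
#' residual unit). Each decoder level of the first sub-network is concatenated
#' channel-wise into the same-resolution encoder level of the second, followed
#' by a 1x1 convolution restoring the expected channel count. A final 1x1
#' convolution and element-wise sigmoid produce one probability map per output
#' channel (ISV, non-ISV).
#'
#' Weights are initialized from zero-mean Gaussians (He fan-in scaling);
#' use [init_weights()] to re-initialize with a different seed.
#'
#' @param config an [network_config()] object.
#' @param seed integer seed for the Gaussian weight initialization.
#' @return an object of class `isv_network` with elements `config`, `params`
#'   (named list of weight arrays), `state` (batch-norm running statistics)
#'   and `unit_registry` (a tibble with one row per residual unit).
#' @export
build_network <- function(config, seed = 0L) {
  stopifnot(inherits(config, "isv_network_config"))
  plan <- arch_plan(config)
  params <- with_local_seed(seed, {
    p <- vector("list", length(plan$shapes))
    names(p) <- names(plan$shapes)
    for (nm in names(plan$shapes)) p[[nm]] <- init_param(plan$shapes[[nm]], nm)
    p
  })
  state <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    if (grepl("\\.gamma$", nm)) {
      base <- sub("\\.gamma$", "", nm)
      state[[paste0(base, ".rm")]] <- numeric(length(params[[nm]]))
      state[[paste0(base, ".rv")]] <- rep(1, length(params[[nm]]))
    }
  }
  structure(list(config = config, params = params, state = state,
                 unit_registry = plan$registry),
            class = "isv_network")
}

#' Number of trainable parameters
#' @param network an `isv_network`.
#' @return integer count of scalar trainable parameters.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$params, length, numeric(1)))
}

#' Build a standalone residual unit
#'
#' A full pre-activation residual unit: `x + F(x)` with
#' `F = BN -> ReLU -> 3x3 conv -> BN -> ReLU -> 3x3 conv`, spatial size
#' preserved by zero padding, and a 1x1 projection on the identity path iff
#' the channel counts differ. `type = "plain"` gives the original U-Net unit
#' (conv -> BN -> ReLU, twice, no identity addition).
#'
#' @param in_ch,out_ch channel counts (>= 1).
#' @param type `"res"` (default) or `"plain"`.
#' @param seed seed for weight initialization.
#' @return an object of class `isv_unit`; run it with [unit_forward()].
#' @export
build_residual_unit <- function(in_ch, out_ch, type = "res", seed = 0L) {
  stopifnot(in_ch >= 1, out_ch >= 1)
  shapes <- unit_param_shapes("u", as.integer(in_ch), as.integer(out_ch), type)
  params <- with_local_seed(seed, {
    p <- vector("list", length(shapes))
    names(p) <- names(shapes)
    for (nm in names(shapes)) p[[nm]] <- init_param(shapes[[nm]], nm)
    p
  })
  state <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    if (grepl("\\.gamma$", nm)) {
      base <- sub("\\.gamma$", "", nm)
      state[[paste0(base, ".rm")]] <- numeric(length(params[[nm]]))
      state[[paste0(base, ".rv")]] <- rep(1, length(params[[nm]]))
    }
  }
  structure(list(in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
                 type = type, params = params, state = state),
            class = "isv_unit")
}

# shared unit body used by both the standalone unit and the full network
op_unit <- function(g, net, x, name, cin, cout, type, training) {
  if (type == "res") {
    h <- op_bn(g, net, x, paste0(name, ".bn1"), training)
    h <- op_relu(g, h)
    h <- op_conv(g, net, h, paste0(name, ".conv1"))
    h <- op_bn(g, net, h, paste0(name, ".bn2"), training)
    h <- op_relu(g, h)
    h <- op_conv(g, net, h, paste0(name, ".conv2"))
    idp <- if (cin == cout) x else op_conv(g, net, x, paste0(name, ".proj"))
    op_add(g, idp, h)
  } else {
    h <- op_conv(g, net, x, paste0(name, ".conv1"))
    h <- op_bn(g, net, h, paste0(name, ".bn1"), training)
    h <- op_relu(g, h)
    h <- op_conv(g, net, h, paste0(name, ".conv2"))
    h <- op_bn(g, net, h, paste0(name, ".bn2"), training)
    op_relu(g, h)
  }
}

#' Run a standalone unit
#' @param unit an `isv_unit` from [build_residual_unit()].
#' @param x input array `(H, W, in_ch, N)` (or `(H, W)` for a single-channel
#'   single image).
#' @param training logical; batch statistics (TRUE) vs running averages.
#' @return output array `(H, W, out_ch, N)`.
#' @export
unit_forward <- function(unit, x, training = FALSE) {
  x <- as_batch(x, unit$in_ch)
  g <- ad_graph()
  xid <- ad_node(g, x)
  out <- op_unit(g, unit, xid, "u", unit$in_ch, unit$out_ch, unit$type,
                 training)
  ad_value(g, out)
}

# coerce (H,W), (H,W,N) or (H,W,C,N) input to a (H,W,C,N) batch
as_batch <- function(x, in_channels) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("input must be at least a 2-d array")
  if (length(d) == 2) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3) {
    # interpret third dim as batch for single-channel networks
    x <- array(x, c(d[1], d[2], 1L, d[3]))
  }
  d <- dim(x)
  if (d[3] != in_channels) {
    stop("input has ", d[3], " channel(s) but the network expects ",
         in_channels)
  }
  x
}

# forward graph; returns output node id and net-1 decoder node ids
network_forward_graph <- function(g, net, x, training = FALSE) {
  cfg <- net$config
  E <- cfg$depth
  d <- dim(x)
  if (d[1] %% 2^E != 0 || d[2] %% 2^E != 0) {
    stop("input spatial size ", d[1], "x", d[2],
         " must be divisible by 2^depth = ", 2^E)
  }
  ch <- subnet_channels(cfg)
  xid <- ad_node(g, x)
  dec1 <- NULL
  out <- NULL
  for (s in seq_len(cfg$n_subnets)) {
    pre <- paste0("n", s)
    cur <- xid
    skips <- vector("list", E)
    for (l in seq_len(E)) {
      if (s == 2L) {
        cur <- op_concat(g, cur, dec1[[l]])
        cur <- op_conv(g, net, cur, paste0(pre, ".br", l))
      }
      cur <- op_unit(g, net, cur, paste0(pre, ".enc", l), ch$enc_in[l],
                     ch$enc_out[l], cfg$unit_type, training)
      skips[[l]] <- cur
      cur <- op_maxpool(g, cur)
    }
    cur <- op_unit(g, net, cur, paste0(pre, ".mid"), ch$mid_in, ch$mid_out,
                   cfg$unit_type, training)
    dec <- vector("list", E)
    for (l in rev(seq_len(E))) {
      cur <- op_tconv(g, net, cur, paste0(pre, ".up", l))
      cur <- op_bn(g, net, cur, paste0(pre, ".upbn", l), training)
      cur <- op_relu(g, cur)
      cur <- op_add(g, cur, skips[[l]])
      cur <- op_unit(g, net, cur, paste0(pre, ".dec", l), ch$dec[l],
                     ch$dec[l], cfg$unit_type, training)
      dec[[l]] <- cur
    }
    if (s == 1L && cfg$n_subnets == 2L) dec1 <- dec
    out <- cur
  }
  out <- op_conv(g, net, out, "head")
  out <- op_sigmoid(g, out)
  list(out = out, input = xid)
}

#' Forward pass
#'
#' Runs a batch of grayscale images through the network and returns per-pixel
#' probability maps (one per output channel: ISV, non-ISV). In evaluation mode
#' (default) batch normalization uses running averages, so outputs are
#' deterministic and independent across batch entries.
#'
#' @param network an `isv_network`.
#' @param batch input images: `(H, W)`, `(H, W, N)` or `(H, W, C, N)` array
#'   with values in `[0, 1]`; spatial size must be divisible by `2^depth`.
#' @param training logical; use batch statistics and update running averages.
#' @return probability maps `(H, W, out_channels, N)`; the batch dimension is
#'   dropped when a single `(H, W)` image is supplied.
#' @export
forward <- function(network, batch, training = FALSE) {
  single <- length(dim(batch)) == 2 || is.null(dim(batch))
  x <- as_batch(batch, network$config$in_channels)
  g <- ad_graph()
  res <- network_forward_graph(g, network, x, training)
  y <- ad_value(g, res$out)
  if (single) {
    dn <- dim(y)
    y <- array(y, dn[1:3])
  }
  y
}

#' @export
print.isv_network <- function(x, ...) {
  cat("Dual ResUNet network\n")
  cat("  variant:       ", x$config$variant, "\n")
  cat("  residual units:", nrow(x$unit_registry), "\n")
  cat("  base channels: ", x$config$base_channels, "\n")
  cat("  depth (levels):", x$config$depth, "\n")
  cat("  parameters:    ", n_parameters(x), "\n")
  invisible(x)
}

#' Fuse multi-resolution feature maps (optional auxiliary head)
#'
#' Bilinearly upsamples each feature map to the finest supplied resolution and
#' returns their weighted sum, `y(p) = sum_j w_j f_j(p)`.
#'
#' @param feature_maps list of 2-d matrices (coarse to fine, any order).
#' @param fusion_weights numeric vector, one weight per map.
#' @return a matrix at the finest input resolution.
#' @export
fuse_feature_maps <- function(feature_maps, fusion_weights) {
  if (length(feature_maps) == 0) stop("feature_maps must be non-empty")
  if (length(fusion_weights) != length(feature_maps)) {
    stop("need one fusion weight per feature map")
  }
  hs <- vapply(feature_maps, nrow, integer(1))
  ws <- vapply(feature_maps, ncol, integer(1))
  H <- max(hs)
  W <- max(ws)
  out <- matrix(0, H, W)
  for (j in seq_along(feature_maps)) {
    f <- feature_maps[[j]]
    if (nrow(f) != H || ncol(f) != W) f <- bilinear_resize_cpp(f, H, W)
    out <- out + fusion_weights[j] * f
  }
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture configuration, all weights and the
#' batch-norm running statistics, so `load_checkpoint()` restores a network
#' that reproduces the saved model's predictions exactly.
#'
#' @param network an `isv_network`.
#' @param path file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns an `isv_network`.
#' @export
save_checkpoint <- function(network, path) {
  saveRDS(list(config = unclass(network$config), params = network$params,
               state = as.list(network$state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(network_config,
                 obj$config[c("variant", "base_channels", "in_channels",
                              "out_channels")])
  net <- build_network(cfg)
  net$params <- obj$params
  for (nm in names(obj$state)) net$state[[nm]] <- obj$state[[nm]]
  net
}

#' Read / write a network configuration as YAML
#' @param config an `isv_network_config`.
#' @param path file path.
#' @export
write_network_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[c("variant", "base_channels",
                                     "in_channels", "out_channels")], path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  do.call(network_config, yaml::read_yaml(path))
}
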