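# Differentiable layer ops. Each takes the tape `g`, input node id(s) and,
# where parameterized, the network (for its parameter list / BN state) and a
# parameter name prefix. All return the id of the node holding the output.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

op_conv <- function(g, net, x, name) {
  wid <- ad_param(g, net$params, paste0(name, ".w"))
  bid <- ad_param(g, net$params, paste0(name, ".b"))
  xv <- ad_value(g, x)
  wv <- ad_value(g, wid)
  y <- conv2d_fwd(xv, wv, ad_value(g, bid))
  ad_node(g, y, c(x, wid, bid), function(d) {
    r <- conv2d_bwd(xv, wv, d)
    list(r$dx, r$dw, r$db)
  })
}

op_tconv <- function(g, net, x, name) {
  wid <- ad_param(g, net$params, paste0(name, ".w"))
  bid <- ad_param(g, net$params, paste0(name, ".b"))
  xv <- ad_value(g, x)
  wv <- ad_value(g, wid)
  y <- tconv2_fwd(xv, wv, ad_value(g, bid))
  ad_node(g, y, c(x, wid, bid), function(d) {
    r <- tconv2_bwd(xv, wv, d)
    list(r$dx, r$dw, r$db)
  })
}

op_bn <- function(g, net, x, name, training) {
  gid <- ad_param(g, net$params, paste0(name, ".gamma"))
  bid <- ad_param(g, net$params, paste0(name, ".beta"))
  xv <- ad_value(g, x)
  gamma <- ad_value(g, gid)
  beta <- ad_value(g, bid)
  st <- net$state
  rm_key <- paste0(name, ".rm")
  rv_key <- paste0(name, ".rv")
  if (training) {
    s <- bn_stats(xv)
    mu <- s$mean
    va <- s$var
    m <- s$m
    unbias <- if (m > 1) m / (m - 1) else 1
    mom <- st$.bn_momentum %||% BN_MOMENTUM
    st[[rm_key]] <- (1 - mom) * st[[rm_key]] + mom * mu
    st[[rv_key]] <- (1 - mom) * st[[rv_key]] + mom * va * unbias
    y <- bn_apply(xv, mu, va, gamma, beta, BN_EPS)
    ad_node(g, y, c(x, gid, bid), function(d) {
      r <- bn_bwd_train(xv, mu, va, gamma, BN_EPS, d)
      list(r$dx, r$dgamma, r$dbeta)
    })
  } else {
    mu <- st[[rm_key]]
    va <- st[[rv_key]]
    y <- bn_apply(xv, mu, va, gamma, beta, BN_EPS)
    ad_node(g, y, c(x, gid, bid), function(d) {
      r <- bn_bwd_eval(xv, mu, va, gamma, BN_EPS, d)
      list(r$dx, r$dgamma, r$dbeta)
    })
  }
}

op_relu <- function(g, x) {
  xv <- ad_value(g, x)
  y <- pmax(xv, 0)
  dim(y) <- dim(xv)
  ad_node(g, y, x, function(d) list(d * (xv > 0)))
}

op_sigmoid <- function(g, x) {
  xv <- ad_value(g, x)
  # clamp away from {0, 1}: float underflow at |logit| > ~37 would otherwise
  # round the output onto the boundary of the open sigmoid range
  y <- pmin(pmax(1 / (1 + exp(-xv)), 1e-12), 1 - 1e-12)
  dim(y) <- dim(xv)
  ad_node(g, y, x, function(d) list(d * y * (1 - y)))
}

op_add <- function(g, a, b) {
  y <- ad_value(g, a) + ad_value(g, b)
  ad_node(g, y, c(a, b), function(d) list(d, d))
}

op_maxpool <- function(g, x) {
  xv <- ad_value(g, x)
  r <- maxpool2_fwd(xv)
  in_dim <- dim(xv)
  ad_node(g, r$y, x, function(d) list(maxpool2_bwd(d, r$idx, in_dim)))
}

# channel-wise concatenation of two (H, W, C, N) tensors
op_concat <- function(g, a, b) {
  av <- ad_value(g, a)
  bv <- ad_value(g, b)
  da <- dim(av)
  db_ <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  y[, , seq_len(da[3]), ] <- av
  y[, , da[3] + seq_len(db_[3]), ] <- bv
  ad_node(g, y, c(a, b), function(d) {
    list(d[, , seq_len(da[3]), , drop = FALSE],
         d[, , da[3] + seq_len(db_[3]), , drop = FALSE])
  })
}
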