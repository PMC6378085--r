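# Minimal reverse-mode tape used to differentiate the network forward pass.
#
# Every layer call appends one node to the tape; a node holds the computed
# value, the ids of its parent nodes and a closure that maps the incoming
# gradient to per-parent gradients. Backward sweeps the tape in reverse
# creation order, which is a valid topological order by construction.

ad_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list() # parameter name -> node id
  g
}

ad_node <- function(g, value, parents = integer(0), bwd = NULL, pname = NULL) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(value = value, parents = as.integer(parents),
                        bwd = bwd, pname = pname)
  if (!is.null(pname)) g$params[[pname]] <- id
  id
}

ad_value <- function(g, id) g$nodes[[id]]$value

# leaf node for a named parameter (created once per forward pass)
ad_param <- function(g, params, pname) {
  id <- g$params[[pname]]
  if (is.null(id)) id <- ad_node(g, params[[pname]], pname = pname)
  id
}

# Backward pass from `out_id` seeded with gradient `seed` (same shape as the
# output value). Returns a named list of gradients for every parameter node
# reached by the sweep.
ad_backward <- function(g, out_id, seed) {
  n <- length(g$nodes)
  grads <- vector("list", n)
  grads[[out_id]] <- seed
  for (id in seq(n, 1L)) {
    nd <- g$nodes[[id]]
    gr <- grads[[id]]
    if (is.null(gr) || is.null(nd$bwd)) next
    pg <- nd$bwd(gr)
    for (k in seq_along(nd$parents)) {
      if (is.null(pg[[k]])) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL) # free memory without shifting list indices
  }
  out <- list()
  for (pname in names(g$params)) {
    pid <- g$params[[pname]]
    out[[pname]] <- grads[[pid]]
  }
  out
}
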