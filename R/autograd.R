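# Minimal reverse-mode automatic differentiation over H x W x C arrays.
# Nodes are environments; the graph is built during the forward pass and
# traversed once, in reverse topological order, by ag_backward(). All heavy
# kernels (convolution, bilinear resize) live in src/conv_ops.cpp; everything
# here is bookkeeping.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  .ag_counter$n <- .ag_counter$n + 1L
  e <- new.env(parent = emptyenv())
  e$id <- .ag_counter$n
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  class(e) <- "ag_node"
  e
}

ag_leaf <- function(value) ag_node(value)

# Reverse topological order by DFS (iterative; graphs here are shallow but
# wide, recursion depth is not an issue either way).
.ag_topo <- function(root) {
  order <- vector("list", 256L); no <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L)); ns <- 1L
  assign(as.character(root$id), TRUE, envir = seen)
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    if (fr$i < length(node$parents)) {
      stack[[ns]]$i <- fr$i + 1L
      p <- node$parents[[fr$i + 1L]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        ns <- ns + 1L
        stack[[ns]] <- list(node = p, i = 0L)
      }
    } else {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- node
      ns <- ns - 1L
    }
  }
  order[seq_len(no)]  # parents before children; reverse for backprop
}

# Seed the root gradient and propagate. Gradients accumulate on every node;
# leaves keep theirs for the optimizer to read.
ag_backward <- function(root, seed = 1) {
  topo <- .ag_topo(root)
  root$grad <- if (is.array(root$value) || length(root$value) > 1L) {
    g <- array(0, dim = dim(root$value) %||% length(root$value)); g[] <- seed; g
  } else seed
  for (k in rev(seq_along(topo))) {
    node <- topo[[k]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pg <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is.null(pg[[j]])) next
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
    node$grad <- NULL  # free interior gradients as we go
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as3d <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# --- differentiable ops -----------------------------------------------------

ag_conv <- function(x, w, b, stride = 1L, dilation = 1L, groups = 1L) {
  out <- .conv2d_fwd(x$value, w$value, b$value,
                     as.integer(stride), as.integer(dilation), as.integer(groups))
  ag_node(out, list(x, w, b), function(g) {
    r <- .conv2d_bwd(x$value, w$value, g,
                     as.integer(stride), as.integer(dilation), as.integer(groups))
    list(r$dx, r$dw, r$db)
  })
}

ag_relu <- function(x) {
  keep <- x$value > 0
  ag_node(x$value * keep, list(x), function(g) list(g * keep))
}

ag_bilinear <- function(x, oh, ow) {
  d <- dim(x$value)
  out <- .bilinear_resize_fwd(x$value, as.integer(oh), as.integer(ow))
  ag_node(out, list(x), function(g)
    list(.bilinear_resize_bwd(g, as.integer(d[1]), as.integer(d[2]))))
}

ag_concat <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  ch <- vapply(vals, function(v) dim(v)[3], integer(1))
  d1 <- dim(vals[[1]])
  out <- array(0, dim = c(d1[1], d1[2], sum(ch)))
  offs <- cumsum(c(0L, ch))
  for (j in seq_along(vals)) out[, , offs[j] + seq_len(ch[j])] <- vals[[j]]
  ag_node(out, nodes, function(g)
    lapply(seq_along(ch), function(j)
      g[, , offs[j] + seq_len(ch[j]), drop = FALSE]))
}

# Global average pool to 1 x 1 x C.
ag_gap <- function(x) {
  d <- dim(x$value)
  m <- apply(x$value, 3, mean)
  ag_node(array(m, dim = c(1L, 1L, d[3])), list(x), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) gx[, , c] <- g[1, 1, c] / (d[1] * d[2])
    list(gx)
  })
}

# Broadcast a 1 x 1 x C node to H x W x C.
ag_broadcast <- function(x, h, w) {
  d <- dim(x$value)
  out <- array(rep(x$value, each = h * w), dim = c(h, w, d[3]))
  ag_node(out, list(x), function(g)
    list(array(apply(g, 3, sum), dim = c(1L, 1L, d[3]))))
}

ag_pixel_shuffle <- function(x, r) {
  out <- pixel_shuffle(x$value, r)
  ag_node(out, list(x), function(g) list(pixel_unshuffle(g, r)))
}

# Pixel-wise softmax cross-entropy against an integer mask in {0, ..., K-1}.
# Returns a scalar node (mean over pixels); class_weights is length-K.
ag_softmax_ce <- function(scores, mask, class_weights = NULL) {
  d <- dim(scores$value)
  K <- d[3]
  n <- d[1] * d[2]
  sc <- matrix(scores$value, nrow = n, ncol = K)
  sc <- sc - apply(sc, 1, max)
  ex <- exp(sc)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(n), as.integer(mask) + 1L)
  wts <- if (is.null(class_weights)) rep(1, K) else class_weights
  wpix <- wts[as.integer(mask) + 1L]
  wsum <- sum(wpix)
  loss <- sum(-log(pmax(p[idx], 1e-12)) * wpix) / wsum
  ag_node(loss, list(scores), function(g) {
    onehot <- matrix(0, n, K)
    onehot[idx] <- 1
    dsc <- (p - onehot) * (wpix / wsum) * g
    list(array(dsc, dim = d))
  })
}
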