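# Minimal reverse-mode differentiation engine.
#
# A "tape" records nodes in creation order (which is a topological order of
# the forward graph); backward() walks it in reverse, calling each node's
# vector-Jacobian product and accumulating gradients on the parents. Nodes
# are environments so gradient accumulation mutates in place. When tape is
# NULL the ops run in plain inference mode and no closures are kept.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

tnode <- function(tape, value, parents = list(), vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (!is.null(tape)) {
    nd$parents <- parents
    nd$vjp <- vjp
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

leaf <- function(tape, value) tnode(tape, value)

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' @noRd
backward <- function(tape, loss_node, seed_grad = 1) {
  accumulate_grad(loss_node, seed_grad)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# ---- tensor ops on (C, X, Y, Z) arrays -------------------------------------

t_conv <- function(tape, x, w, b, stride = c(1L, 1L, 1L),
                   dilation = c(1L, 1L, 1L)) {
  wd <- dim(w$value)
  ks <- as.integer(wd[3:5])
  cout <- as.integer(wd[1])
  xv <- x$value
  y <- cpp_conv_forward(xv, dim(xv), w$value, cout, b$value, ks,
                        as.integer(stride), as.integer(dilation))
  vjp <- NULL
  if (!is.null(tape)) {
    wv <- w$value
    need_gx <- !is.null(x$vjp)  # the network input is a leaf: skip its grad
    vjp <- function(g) {
      r <- cpp_conv_backward(xv, dim(xv), wv, cout, ks, as.integer(stride),
                             as.integer(dilation), g, need_gx)
      list(r$gx, r$gw, r$gb)
    }
  }
  tnode(tape, y, list(x, w, b), vjp)
}

t_maxpool <- function(tape, x, pool = c(2L, 2L, 2L)) {
  xd <- dim(x$value)
  r <- cpp_maxpool_forward(x$value, xd, as.integer(pool))
  vjp <- NULL
  if (!is.null(tape)) {
    vjp <- function(g) list(cpp_maxpool_backward(g, r$argmax, xd))
  }
  tnode(tape, r$y, list(x), vjp)
}

t_upsample <- function(tape, x, oshape, method = c("linear", "nearest")) {
  method <- match.arg(method)
  xd <- dim(x$value)
  oshape <- as.integer(oshape)
  if (method == "linear") {
    y <- cpp_resample_linear(x$value, xd, oshape)
    vjp <- if (is.null(tape)) NULL else {
      function(g) list(cpp_resample_linear_grad(g, xd, oshape))
    }
  } else {
    y <- cpp_resample_nearest(x$value, xd, oshape)
    vjp <- if (is.null(tape)) NULL else {
      stop("nearest upsampling has no gradient path", call. = FALSE)
    }
  }
  tnode(tape, y, list(x), vjp)
}

t_leaky_relu <- function(tape, x, slope = 0.01) {
  xv <- x$value
  pos <- xv > 0
  y <- xv * (pos + slope * !pos)
  dim(y) <- dim(xv)
  vjp <- if (is.null(tape)) NULL else {
    function(g) list(g * (pos + slope * !pos))
  }
  tnode(tape, y, list(x), vjp)
}

t_relu <- function(tape, x) t_leaky_relu(tape, x, slope = 0)

t_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  vjp <- if (is.null(tape)) NULL else function(g) list(g * y * (1 - y))
  tnode(tape, y, list(x), vjp)
}

# Softmax over the channel (first) dimension.
t_softmax_channels <- function(tape, x) {
  xv <- x$value
  d <- dim(xv)
  m <- matrix(xv, nrow = d[1])
  m <- m - rep(apply(m, 2, max), each = d[1])
  e <- exp(m)
  p <- e / rep(colSums(e), each = d[1])
  y <- array(p, d)
  vjp <- if (is.null(tape)) NULL else {
    function(g) {
      gm <- matrix(g, nrow = d[1])
      dot <- colSums(gm * p)
      list(array(p * (gm - rep(dot, each = d[1])), d))
    }
  }
  tnode(tape, y, list(x), vjp)
}

t_add <- function(tape, a, b) {
  vjp <- if (is.null(tape)) NULL else function(g) list(g, g)
  tnode(tape, a$value + b$value, list(a, b), vjp)
}

# Concatenate along the channel (first) dimension.
t_concat_channels <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  dims <- lapply(vals, dim)
  cs <- vapply(dims, `[`, integer(1), 1L)
  sp <- dims[[1]][-1]
  mat <- do.call(rbind, lapply(vals, function(v) matrix(v, nrow = dim(v)[1])))
  y <- array(mat, c(sum(cs), sp))
  vjp <- if (is.null(tape)) NULL else {
    function(g) {
      gm <- matrix(g, nrow = sum(cs))
      off <- c(0L, cumsum(cs))
      lapply(seq_along(cs), function(i) {
        array(gm[(off[i] + 1L):off[i + 1L], , drop = FALSE], c(cs[i], sp))
      })
    }
  }
  tnode(tape, y, nodes, vjp)
}

# Global average pooling: (C, spatial) -> length-C vector.
t_gap <- function(tape, x) {
  d <- dim(x$value)
  nsp <- prod(d[-1])
  y <- rowMeans(matrix(x$value, nrow = d[1]))
  vjp <- if (is.null(tape)) NULL else {
    function(g) list(array(rep(g / nsp, nsp), d))
  }
  tnode(tape, y, list(x), vjp)
}

# Multiply channel k of x by scalar g[k] (g is a vector node of length C).
t_scale_channels <- function(tape, x, g) {
  d <- dim(x$value)
  gv <- g$value
  y <- x$value * gv  # first dim is channels: recycling broadcasts per channel
  vjp <- if (is.null(tape)) NULL else {
    xv <- x$value
    function(go) {
      list(go * gv, rowSums(matrix(go * xv, nrow = d[1])))
    }
  }
  tnode(tape, y, list(x, g), vjp)
}

# Batch normalization over spatial positions, per channel. In training mode
# uses the sample's own (population) statistics and updates running stats in
# `stats_env[[key]]`; in inference uses the stored running statistics.
t_batchnorm <- function(tape, x, gamma, beta, stats_env, key,
                        training = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[1]
  nsp <- prod(d[-1])
  xm <- matrix(x$value, nrow = C)
  st <- stats_env[[key]]
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
    stats_env[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                             var = (1 - momentum) * st$var + momentum * v)
  } else {
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    mu <- st$mean
    v <- st$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  y <- array(gamma$value * xhat + beta$value, d)
  vjp <- if (is.null(tape)) NULL else {
    function(g) {
      gm <- matrix(g, nrow = C)
      gxhat <- gm * gamma$value
      ggamma <- rowSums(gm * xhat)
      gbeta <- rowSums(gm)
      if (training) {
        # full backprop through the per-sample statistics
        gv <- rowSums(gxhat * (xm - mu)) * (-0.5) * istd^3
        gmu <- rowSums(gxhat) * (-istd)
        gx <- gxhat * istd + gv * 2 * (xm - mu) / nsp + gmu / nsp
      } else {
        gx <- gxhat * istd
      }
      list(array(gx, d), ggamma, gbeta)
    }
  }
  tnode(tape, y, list(x, gamma, beta), vjp)
}

t_sum <- function(tape, x) {
  d <- dim(x$value)
  vjp <- if (is.null(tape)) NULL else function(g) list(array(g, d))
  tnode(tape, sum(x$value), list(x), vjp)
}
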