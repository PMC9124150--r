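# Independent brute-force oracles shared across test files.

# Straight-line reference implementation of the CAM fusion equations,
# written as plain index loops, independent of the package's kernels.
cam_oracle <- function(x_l, x_h, params) {
  nd <- length(dim(x_l)) - 1L
  dl <- dim(x_l)
  c_h <- params$c_h
  # g: global average pool of x_h
  g <- apply(matrix(x_h, nrow = dim(x_h)[1]), 1, mean)
  # conv3 (same padding), then conv1, per output position
  conv_ref <- function(x, w, b) {
    dx <- dim(x)
    k <- dim(w)[-(1:2)]
    pad <- (k - 1) %/% 2
    out <- array(0, c(dim(w)[1], dx[-1]))
    sp <- expand.grid(lapply(dx[-1], seq_len))
    for (r in seq_len(nrow(sp))) {
      pos <- as.integer(sp[r, ])
      for (co in seq_len(dim(w)[1])) {
        acc <- b[co]
        off <- expand.grid(lapply(k, seq_len))
        for (q in seq_len(nrow(off))) {
          kp <- as.integer(off[q, ])
          ip <- pos - pad + kp - 1L
          if (all(ip >= 1L) && all(ip <= dx[-1])) {
            for (ci in seq_len(dx[1])) {
              wi <- do.call(`[`, c(list(w), list(co, ci), as.list(kp)))
              xi <- do.call(`[`, c(list(x), list(ci), as.list(ip)))
              acc <- acc + wi * xi
            }
          }
        }
        out <- do.call(`[<-`, c(list(out), list(co), as.list(pos),
                                list(value = acc)))
      }
    }
    out
  }
  x_lp <- conv_ref(x_l, params$conv3_w, params$conv3_b)
  x_c1 <- conv_ref(x_lp, params$conv1_w, params$conv1_b)
  x_gl <- x_c1 * g  # channel-first recycling = per-channel scalar gate
  # bilinear/trilinear upsampling of x_h, half-pixel centers
  up <- array(0, c(c_h, dl[-1]))
  axes <- lapply(seq_len(nd), function(a) {
    o <- seq_len(dl[a + 1])
    x <- (o - 0.5) * dim(x_h)[a + 1] / dl[a + 1] + 0.5
    x <- pmin(pmax(x, 1), dim(x_h)[a + 1])
    list(lo = floor(x), f = x - floor(x))
  })
  sp <- expand.grid(lapply(dl[-1], seq_len))
  for (r in seq_len(nrow(sp))) {
    pos <- as.integer(sp[r, ])
    for (co in seq_len(c_h)) {
      acc <- 0
      corners <- expand.grid(rep(list(0:1), nd))
      for (q in seq_len(nrow(corners))) {
        cr <- as.integer(corners[q, ])
        wgt <- 1
        ip <- integer(nd)
        for (a in seq_len(nd)) {
          lo <- axes[[a]]$lo[pos[a]]
          f <- axes[[a]]$f[pos[a]]
          ip[a] <- min(lo + cr[a], dim(x_h)[a + 1])
          wgt <- wgt * if (cr[a] == 0) (1 - f) else f
        }
        if (wgt > 0) {
          acc <- acc + wgt * do.call(`[`, c(list(x_h), list(co), as.list(ip)))
        }
      }
      up <- do.call(`[<-`, c(list(up), list(co), as.list(pos),
                             list(value = acc)))
    }
  }
  x_gl + up
}

count_oracle <- function(p, t) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (v in seq_along(p)) {
    if (p[v] == 1L && t[v] == 1L) tp <- tp + 1L
    else if (p[v] == 1L) fp <- fp + 1L
    else if (t[v] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

surface_oracle <- function(m) {
  d <- dim(m$data)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m$data[i, j, k] == 0L) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    surf <- FALSE
    for (r in 1:6) {
      q <- nb[r, ]
      if (any(q < 1) || any(q > d) || m$data[q[1], q[2], q[3]] == 0L) {
        surf <- TRUE
        break
      }
    }
    if (surf) pts <- rbind(pts, (c(i, j, k) - 1) * m$spacing)
  }
  pts
}

allpairs_dists <- function(a, b) {
  # n x m distance matrix via outer sums
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

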