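#' Channel attention module (CAM) feature fusion
#'
#' The CAM fuses a high-resolution, low-level feature map `x_l` with a
#' coarser, high-level map `x_h`. The high-level map is summarized by
#' global average pooling into one scalar per channel; the low-level map is
#' transformed by a same-padded 3x3(x3) convolution to the high-level
#' channel count, passed through a 1x1(x1) convolution, and each channel is
#' multiplied by the corresponding pooled scalar (the channel gate).
#' Finally the gated map is added to the bi/trilinearly upsampled
#' high-level map:
#'
#'   X_cam = conv1(conv3(X_L)) * g(X_H)  +  up(X_H)
#'
#' Feature maps are channel-first arrays: `(channels, x, y)` for 2D or
#' `(channels, x, y, z)` for 3D. No activation is applied to the pooled
#' gate vector by default (`gate_activation = "none"`); a sigmoid variant
#' is available.
#'
#' @param x_l low-level feature map (higher spatial resolution).
#' @param x_h high-level feature map (coarser resolution, `c_h` channels).
#' @param params a [cam_params()] parameter set.
#' @param gate_activation `"none"` (default) or `"sigmoid"`, applied to the
#'   pooled gate vector.
#' @return Fused feature map with `c_h` channels at `x_l`'s spatial shape.
#' @seealso [cam_params()], [global_avg_pool()], [upsample_to()],
#'   [low_level_transform()], [channel_gate()]
#' @examples
#' p <- cam_params(c_l = 2, c_h = 2, ndim = 2, init = "identity")
#' x_l <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
#' x_h <- array(1, c(2, 4, 4))
#' out <- cam_fuse(x_l, x_h, p)   # = 1 * x_l + 1 for identity kernels
#' @export
cam_fuse <- function(x_l, x_h, params, gate_activation = c("none", "sigmoid")) {
  gate_activation <- match.arg(gate_activation)
  nd <- check_feature_map(x_l)
  if (check_feature_map(x_h) != nd) {
    stop("x_l and x_h must have the same spatial dimensionality", call. = FALSE)
  }
  if (any(spatial_shape(x_h) > spatial_shape(x_l))) {
    stop("x_h spatial shape must not exceed x_l's on any axis", call. = FALSE)
  }
  g <- global_avg_pool(x_h)
  if (gate_activation == "sigmoid") g <- 1 / (1 + exp(-g))
  x_lp <- low_level_transform(x_l, params)
  x_gl <- channel_gate(x_lp, g, params)
  x_gl + upsample_to(x_h, spatial_shape(x_l))
}

#' CAM parameter set
#'
#' Creates the weights of the two convolutions inside the channel attention
#' module: `conv3`, a same-padded 3x3(x3) bank mapping `c_l` to `c_h`
#' channels, and `conv1`, a 1x1(x1) bank mapping `c_h` to `c_h`.
#'
#' @param c_l channel count of the low-level map.
#' @param c_h channel count of the high-level map (and of the output).
#' @param ndim spatial dimensionality, 2 or 3.
#' @param init `"random"` (He-scaled normal draws from the current RNG),
#'   `"identity"` (center-tap delta kernels, requires `c_l == c_h`), or
#'   `"zero"`.
#' @return A list with elements `conv3_w`, `conv3_b`, `conv1_w`, `conv1_b`
#'   and the channel counts, of class `"cam_params"`.
#' @export
cam_params <- function(c_l, c_h, ndim = 3,
                       init = c("random", "identity", "zero")) {
  init <- match.arg(init)
  stopifnot(c_l >= 1, c_h >= 1, ndim %in% c(2, 3))
  k3 <- if (ndim == 3) c(3L, 3L, 3L) else c(3L, 3L)
  k1 <- rep(1L, ndim)
  mk <- function(cout, cin, k) {
    n <- cout * cin * prod(k)
    w <- switch(init,
      random = stats::rnorm(n, sd = sqrt(2 / (cin * prod(k)))),
      zero = numeric(n),
      identity = {
        if (cout != cin) {
          stop("identity init requires matching channel counts", call. = FALSE)
        }
        a <- array(0, c(cout, cin, k))
        ctr <- as.list((k + 1L) %/% 2L)
        for (i in seq_len(cout)) {
          a <- do.call(`[<-`, c(list(a, i, i), ctr, list(value = 1)))
        }
        a
      })
    array(w, c(cout, cin, k))
  }
  structure(list(conv3_w = mk(c_h, c_l, k3), conv3_b = numeric(c_h),
                 conv1_w = mk(c_h, c_h, k1), conv1_b = numeric(c_h),
                 c_l = c_l, c_h = c_h, ndim = ndim),
            class = "cam_params")
}

#' Global average pooling of a feature map
#'
#' @param x channel-first feature map array (2D or 3D spatial).
#' @return Numeric vector with one spatial mean per channel.
#' @export
global_avg_pool <- function(x) {
  check_feature_map(x)
  if (prod(spatial_shape(x)) == 0) {
    stop("feature map has empty spatial extent", call. = FALSE)
  }
  rowMeans(matrix(x, nrow = dim(x)[1]))
}

#' Bi/trilinear upsampling of a feature map
#'
#' Interpolates a channel-first feature map to a larger spatial shape using
#' bilinear (2D) or trilinear (3D) interpolation with half-pixel-center
#' coordinate mapping. Downsampling is refused.
#'
#' @param x channel-first feature map.
#' @param target_shape integer spatial shape, same length as `x`'s spatial
#'   dimensionality, each entry >= the input extent.
#' @return Feature map at the target spatial shape.
#' @export
upsample_to <- function(x, target_shape) {
  nd <- check_feature_map(x)
  sp <- spatial_shape(x)
  if (length(target_shape) != nd) {
    stop("target_shape length must match spatial dimensionality", call. = FALSE)
  }
  if (any(target_shape < sp)) {
    stop("upsample_to cannot downsample: target below input extent",
         call. = FALSE)
  }
  x4 <- canonical4(x)
  o4 <- c(as.integer(target_shape), if (nd == 2) 1L)
  y <- cpp_resample_linear(x4, dim(x4), o4)
  uncanonical(y, nd)
}

#' Low-level transform of the CAM: same-padded 3x3(x3) convolution
#'
#' @inheritParams cam_fuse
#' @return Feature map with `c_h` channels at `x_l`'s spatial shape.
#' @export
low_level_transform <- function(x_l, params) {
  nd <- check_feature_map(x_l)
  if (dim(x_l)[1] != params$c_l) {
    stop("x_l channel count does not match conv3 input channels",
         call. = FALSE)
  }
  conv_plain(x_l, params$conv3_w, params$conv3_b, nd)
}

#' Channel gating of the CAM
#'
#' Applies the 1x1(x1) convolution to the transformed low-level map, then
#' multiplies channel k by the pooled gate scalar `g[k]`.
#'
#' @param x_lp transformed low-level map (`c_h` channels).
#' @param g per-channel gate vector of length `c_h`.
#' @inheritParams cam_fuse
#' @return Gated feature map, same shape as `x_lp`.
#' @export
channel_gate <- function(x_lp, g, params) {
  nd <- check_feature_map(x_lp)
  if (dim(x_lp)[1] != params$c_h || length(g) != params$c_h) {
    stop("channel counts of x_lp, g and conv1 must agree", call. = FALSE)
  }
  y <- conv_plain(x_lp, params$conv1_w, params$conv1_b, nd)
  y * as.numeric(g)  # channel-first: recycles one scalar per channel
}

# ---- internal helpers ------------------------------------------------------

check_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("feature maps are channel-first arrays with 2 or 3 spatial dims",
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("feature map contains non-finite values",
                               call. = FALSE)
  length(d) - 1L
}

spatial_shape <- function(x) dim(x)[-1]

# Lift a (C, X, Y) map to (C, X, Y, 1) so a single 3D kernel path serves 2D.
canonical4 <- function(x) {
  if (length(dim(x)) == 4L) x else array(x, c(dim(x), 1L))
}

uncanonical <- function(y, nd) {
  if (nd == 3L) y else array(y, dim(y)[1:3])
}

conv_plain <- function(x, w, b, nd) {
  x4 <- canonical4(x)
  wd <- dim(w)
  k <- c(wd[-(1:2)], if (nd == 2) 1L)
  w4 <- array(w, c(wd[1:2], k))
  y <- cpp_conv_forward(x4, dim(x4), w4, as.integer(wd[1]), b, as.integer(k),
                        c(1L, 1L, 1L), c(1L, 1L, 1L))
  uncanonical(y, nd)
}
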