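#' Network configuration
#'
#' Collects every architectural tunable of the three segmentation networks.
#' `depth` counts encoder levels including the deepest, so a network of
#' depth `d` downsamples `d - 1` times and requires every input extent to be
#' divisible by `2^(d-1)` with at least 2 voxels left at the deepest level.
#'
#' @param spatial_dims 2 or 3.
#' @param in_channels input channel count (CT volumes: 1).
#' @param n_classes output channels (1 for a sigmoid head, >= 2 for softmax).
#' @param depth encoder/decoder level count (SegChaNet default 4, V-Net 6).
#' @param base_channels channel width of the first encoder level.
#' @param channel_growth per-level width multiplier (default 2).
#' @param use_cam place a channel-attention fusion block on every
#'   encoder-to-decoder connection (SegChaNet only).
#' @param dilation_schedule dilation rates of the bottleneck stack
#'   (SegChaNet only); the default doubles from 1.
#' @param leaky_relu_slope negative-side slope of the leaky ReLU.
#' @param output_activation `"sigmoid"` or `"softmax"`.
#' @param deep_supervision upsample every decoder output to full resolution
#'   and concatenate before the prediction head (SegChaNet only).
#' @param cam_gate_activation activation on the pooled CAM gate vector.
#' @return A validated list of class `"network_config"`.
#' @export
network_config <- function(spatial_dims = 3, in_channels = 1, n_classes = 1,
                           depth = 4, base_channels = 8, channel_growth = 2,
                           use_cam = TRUE, dilation_schedule = c(1, 2, 4),
                           leaky_relu_slope = 0.01,
                           output_activation = c("sigmoid", "softmax"),
                           deep_supervision = TRUE,
                           cam_gate_activation = c("none", "sigmoid")) {
  output_activation <- match.arg(output_activation)
  cam_gate_activation <- match.arg(cam_gate_activation)
  stopifnot(spatial_dims %in% c(2, 3), in_channels >= 1, n_classes >= 1,
            depth >= 2, base_channels >= 1, channel_growth >= 1,
            leaky_relu_slope >= 0, all(dilation_schedule >= 1))
  structure(list(spatial_dims = as.integer(spatial_dims),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth, use_cam = isTRUE(use_cam),
                 dilation_schedule = as.integer(dilation_schedule),
                 leaky_relu_slope = leaky_relu_slope,
                 output_activation = output_activation,
                 deep_supervision = isTRUE(deep_supervision),
                 cam_gate_activation = cam_gate_activation),
            class = "network_config")
}

level_widths <- function(cfg) {
  as.integer(round(cfg$base_channels * cfg$channel_growth^(seq_len(cfg$depth) - 1)))
}

# Kernel/pool triples; 2D networks run through the same 3D kernels with a
# singleton third axis.
net_k3 <- function(cfg) if (cfg$spatial_dims == 3) c(3L, 3L, 3L) else c(3L, 3L, 1L)
net_k1 <- function(cfg) c(1L, 1L, 1L)
net_pool <- function(cfg) if (cfg$spatial_dims == 3) c(2L, 2L, 2L) else c(2L, 2L, 1L)

init_conv <- function(params, name, cout, cin, k) {
  params[[paste0(name, ".w")]] <-
    array(stats::rnorm(cout * cin * prod(k), sd = sqrt(2 / (cin * prod(k)))),
          c(cout, cin, k))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_bn <- function(params, name, C) {
  params[[paste0(name, ".gamma")]] <- rep(1, C)
  params[[paste0(name, ".beta")]] <- numeric(C)
  params
}

new_network <- function(arch, cfg, params) {
  structure(list(arch = arch, config = cfg, params = params,
                 bn_stats = new.env(parent = emptyenv())),
            class = c(arch, "seg_network"))
}

#' Total number of trainable parameters
#' @param net a network built by [build_unet()], [build_vnet()] or
#'   [build_segchanet()].
#' @return Integer parameter count (a pure function of the configuration).
#' @export
parameter_count <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' Deep-copy a network (parameters and normalization statistics)
#' @param net a `seg_network`.
#' @return An independent copy safe to train without mutating `net`.
#' @export
clone_network <- function(net) {
  out <- net
  out$bn_stats <- list2env(as.list(net$bn_stats), parent = emptyenv())
  out
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<%s> %dD, depth %d, base %d channels%s\n", x$arch,
              cfg$spatial_dims, cfg$depth, cfg$base_channels,
              if (identical(x$arch, "segchanet")) {
                sprintf(", CAM %s", if (cfg$use_cam) "on" else "off")
              } else ""))
  cat(sprintf("  parameters: %d; head: %s (%d class%s)\n", parameter_count(x),
              cfg$output_activation, cfg$n_classes,
              if (cfg$n_classes > 1) "es" else ""))
  invisible(x)
}

# ---- builders --------------------------------------------------------------

#' Build a U-Net
#'
#' Classic encoder-decoder: each level applies two same-padded 3x3(x3)
#' convolutions with ReLU, levels are joined by 2x max pooling on the way
#' down and linear upsampling plus skip concatenation on the way up, channel
#' width doubles per level, and a 1x1(x1) convolution with sigmoid produces
#' the binary probability map.
#'
#' @param cfg a [network_config()]; `use_cam`, `dilation_schedule` and
#'   `deep_supervision` are ignored for this architecture.
#' @return A `seg_network` with freshly initialized weights (He-scaled
#'   draws from the current RNG; seed beforehand for reproducibility).
#' @export
build_unet <- function(cfg = network_config(output_activation = "sigmoid",
                                            use_cam = FALSE)) {
  w <- level_widths(cfg)
  k3 <- net_k3(cfg); k1 <- net_k1(cfg)
  p <- list()
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    p <- init_conv(p, sprintf("enc%d.c1", i), w[i], cin, k3)
    p <- init_conv(p, sprintf("enc%d.c2", i), w[i], w[i], k3)
    cin <- w[i]
  }
  for (i in seq.int(cfg$depth - 1L, 1L)) {
    p <- init_conv(p, sprintf("dec%d.c1", i), w[i], w[i] + w[i + 1], k3)
    p <- init_conv(p, sprintf("dec%d.c2", i), w[i], w[i], k3)
  }
  p <- init_conv(p, "head", cfg$n_classes, w[1], k1)
  if (cfg$output_activation == "sigmoid") {
    p[["head.b"]][] <- stats::qlogis(0.01)  # rare-foreground prior init
  }
  new_network("unet", cfg, p)
}

#' Build a V-Net
#'
#' Volumetric encoder-decoder with residual stages: every stage adds a
#' channel-preserving two-convolution branch back onto its input,
#' downsampling uses stride-2 convolutions instead of pooling, decoder
#' levels use linear upsampling with additive encoder skips, and the head
#' is a 1x1x1 convolution with a per-voxel softmax over `n_classes`.
#'
#' @param cfg a [network_config()] with `spatial_dims = 3`,
#'   `n_classes >= 2` and `output_activation = "softmax"`.
#' @return A `seg_network`.
#' @export
build_vnet <- function(cfg = network_config(depth = 6, n_classes = 2,
                                            output_activation = "softmax",
                                            use_cam = FALSE)) {
  if (cfg$spatial_dims != 3) stop("V-Net is volumetric: spatial_dims must be 3",
                                  call. = FALSE)
  if (cfg$n_classes < 2 || cfg$output_activation != "softmax") {
    stop("V-Net uses a softmax head over >= 2 classes", call. = FALSE)
  }
  w <- level_widths(cfg)
  k3 <- net_k3(cfg); k1 <- net_k1(cfg)
  p <- list()
  p <- init_conv(p, "stem", w[1], cfg$in_channels, k3)
  for (i in seq_len(cfg$depth)) {
    p <- init_conv(p, sprintf("enc%d.res.c1", i), w[i], w[i], k3)
    p <- init_conv(p, sprintf("enc%d.res.c2", i), w[i], w[i], k3)
    if (i < cfg$depth) p <- init_conv(p, sprintf("down%d", i), w[i + 1], w[i], k3)
  }
  for (i in seq.int(cfg$depth - 1L, 1L)) {
    p <- init_conv(p, sprintf("up%d", i), w[i], w[i + 1], k3)
    p <- init_conv(p, sprintf("dec%d.res.c1", i), w[i], w[i], k3)
    p <- init_conv(p, sprintf("dec%d.res.c2", i), w[i], w[i], k3)
  }
  p <- init_conv(p, "head", cfg$n_classes, w[1], k1)
  new_network("vnet", cfg, p)
}

#' Build a SegChaNet
#'
#' Encoder-decoder for volumetric tumor segmentation. Each encoder level
#' applies two same-padded 3x3(x3) convolutions, each followed by batch
#' normalization and a leaky ReLU; levels are joined by 2x max pooling. At
#' the deepest level a stack of dilated convolutions (rates from
#' `dilation_schedule`, doubling by default) aggregates multiscale context.
#' Each decoder level upsamples 2x; its encoder skip either passes through
#' the channel-attention fusion block ([cam_fuse()], `use_cam = TRUE`) or is
#' concatenated plainly. With `deep_supervision` every decoder output is
#' upsampled to full resolution and concatenated before the 1x1(x1)
#' sigmoid head.
#'
#' @param cfg a [network_config()].
#' @return A `seg_network`.
#' @export
build_segchanet <- function(cfg = network_config()) {
  w <- level_widths(cfg)
  k3 <- net_k3(cfg); k1 <- net_k1(cfg)
  D <- cfg$depth
  p <- list()
  cin <- cfg$in_channels
  for (i in seq_len(D)) {
    p <- init_conv(p, sprintf("enc%d.c1", i), w[i], cin, k3)
    p <- init_bn(p, sprintf("enc%d.b1", i), w[i])
    p <- init_conv(p, sprintf("enc%d.c2", i), w[i], w[i], k3)
    p <- init_bn(p, sprintf("enc%d.b2", i), w[i])
    cin <- w[i]
  }
  for (j in seq_along(cfg$dilation_schedule)) {
    p <- init_conv(p, sprintf("dil%d", j), w[D], w[D], k3)
    p <- init_bn(p, sprintf("dilb%d", j), w[D])
  }
  for (i in seq.int(D - 1L, 1L)) {
    if (cfg$use_cam) {
      p <- init_conv(p, sprintf("cam%d.conv3", i), w[i + 1], w[i], k3)
      p <- init_conv(p, sprintf("cam%d.conv1", i), w[i + 1], w[i + 1], k1)
      cin_dec <- w[i + 1]
    } else {
      cin_dec <- w[i] + w[i + 1]
    }
    p <- init_conv(p, sprintf("dec%d.c1", i), w[i], cin_dec, k3)
    p <- init_bn(p, sprintf("dec%d.b1", i), w[i])
    p <- init_conv(p, sprintf("dec%d.c2", i), w[i], w[i], k3)
    p <- init_bn(p, sprintf("dec%d.b2", i), w[i])
  }
  head_in <- if (cfg$deep_supervision) sum(w[seq_len(D - 1L)]) else w[1]
  p <- init_conv(p, "head", cfg$n_classes, head_in, k1)
  if (cfg$output_activation == "sigmoid") {
    # start near a small foreground prior: tumor voxels are rare, and a
    # 0.5 initialization wastes early steps relearning the background rate
    p[["head.b"]][] <- stats::qlogis(0.01)
  }
  new_network("segchanet", cfg, p)
}

# ---- forward passes --------------------------------------------------------

param_nodes <- function(tape, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- leaf(tape, params[[nm]])
  out
}

# Canonicalize an input to a 4D (C, X, Y, Z) array.
as_input_array <- function(x, cfg) {
  if (inherits(x, "ct_volume")) x <- x$data
  d <- dim(x)
  nd <- cfg$spatial_dims
  if (length(d) == nd) {
    x <- array(x, c(1L, d))
    d <- dim(x)
  }
  if (length(d) != nd + 1L || d[1] != cfg$in_channels) {
    stop("input must be a (channels, spatial...) array matching the config",
         call. = FALSE)
  }
  if (nd == 2) x <- array(x, c(d, 1L))
  x
}

check_divisible <- function(shape, depth, nd) {
  f <- 2L^(depth - 1L)
  sp <- shape[seq_len(nd)]
  if (any(sp %% f != 0L) || any(sp %/% f < 2L)) {
    stop(sprintf(
      "input extent %s not compatible with depth %d (needs divisibility by %d and >= %d)",
      paste(sp, collapse = "x"), depth, f, 2L * f), call. = FALSE)
  }
}

conv_block <- function(tape, x, P, pre, bn, stats, training, slope, k) {
  for (j in 1:2) {
    x <- t_conv(tape, x, P[[sprintf("%s.c%d.w", pre, j)]],
                P[[sprintf("%s.c%d.b", pre, j)]])
    if (bn) {
      x <- t_batchnorm(tape, x, P[[sprintf("%s.b%d.gamma", pre, j)]],
                       P[[sprintf("%s.b%d.beta", pre, j)]], stats,
                       sprintf("%s.b%d", pre, j), training = training)
      x <- t_leaky_relu(tape, x, slope)
    } else {
      x <- t_relu(tape, x)
    }
  }
  x
}

segchanet_forward <- function(net, x, tape = NULL, training = FALSE,
                              P = NULL, acts = NULL) {
  cfg <- net$config
  D <- cfg$depth
  if (is.null(P)) P <- param_nodes(tape, net$params)
  pool <- net_pool(cfg)
  # receptive field of the dilated stack must fit the deepest map
  deepest <- dim(x$value)[2:(1 + cfg$spatial_dims)] %/% 2L^(D - 1L)
  rf <- 1L + sum(2L * cfg$dilation_schedule)
  if (rf > min(deepest)) {
    stop(sprintf(
      "dilated-stack receptive field (%d) exceeds the deepest map extent (%d)",
      rf, min(deepest)), call. = FALSE)
  }
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    if (i > 1L) x <- t_maxpool(tape, x, pool)
    x <- conv_block(tape, x, P, sprintf("enc%d", i), TRUE, net$bn_stats,
                    training, cfg$leaky_relu_slope, net_k3(cfg))
    skips[[i]] <- x
    if (!is.null(acts)) acts[[sprintf("enc%d", i)]] <- x
  }
  for (j in seq_along(cfg$dilation_schedule)) {
    r <- cfg$dilation_schedule[j]
    dil <- if (cfg$spatial_dims == 3) c(r, r, r) else c(r, r, 1L)
    x <- t_conv(tape, x, P[[sprintf("dil%d.w", j)]], P[[sprintf("dil%d.b", j)]],
                dilation = dil)
    x <- t_batchnorm(tape, x, P[[sprintf("dilb%d.gamma", j)]],
                     P[[sprintf("dilb%d.beta", j)]], net$bn_stats,
                     sprintf("dilb%d", j), training = training)
    x <- t_leaky_relu(tape, x, cfg$leaky_relu_slope)
  }
  if (!is.null(acts)) acts[["bottleneck"]] <- x
  decs <- list()
  for (i in seq.int(D - 1L, 1L)) {
    skip <- skips[[i]]
    target <- dim(skip$value)[-1]
    if (cfg$use_cam) {
      # channel-attention fusion: gate the transformed skip by the pooled
      # high-level descriptor, then add the upsampled high-level map
      g <- t_gap(tape, x)
      if (cfg$cam_gate_activation == "sigmoid") g <- t_sigmoid(tape, g)
      lp <- t_conv(tape, skip, P[[sprintf("cam%d.conv3.w", i)]],
                   P[[sprintf("cam%d.conv3.b", i)]])
      lp <- t_conv(tape, lp, P[[sprintf("cam%d.conv1.w", i)]],
                   P[[sprintf("cam%d.conv1.b", i)]])
      gl <- t_scale_channels(tape, lp, g)
      x <- t_add(tape, gl, t_upsample(tape, x, target))
    } else {
      x <- t_concat_channels(tape, list(skip, t_upsample(tape, x, target)))
    }
    x <- conv_block(tape, x, P, sprintf("dec%d", i), TRUE, net$bn_stats,
                    training, cfg$leaky_relu_slope, net_k3(cfg))
    decs[[length(decs) + 1L]] <- x
    if (!is.null(acts)) acts[[sprintf("dec%d", i)]] <- x
  }
  if (cfg$deep_supervision) {
    full <- dim(decs[[length(decs)]]$value)[-1]
    ups <- lapply(decs, function(d) {
      if (all(dim(d$value)[-1] == full)) d else t_upsample(tape, d, full)
    })
    x <- t_concat_channels(tape, ups)
  }
  x <- t_conv(tape, x, P[["head.w"]], P[["head.b"]])
  out <- if (cfg$output_activation == "sigmoid") t_sigmoid(tape, x) else
    t_softmax_channels(tape, x)
  if (!is.null(acts)) acts[["head"]] <- out
  out
}

unet_forward <- function(net, x, tape = NULL, training = FALSE, P = NULL,
                         acts = NULL) {
  cfg <- net$config
  D <- cfg$depth
  if (is.null(P)) P <- param_nodes(tape, net$params)
  pool <- net_pool(cfg)
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    if (i > 1L) x <- t_maxpool(tape, x, pool)
    x <- conv_block(tape, x, P, sprintf("enc%d", i), FALSE, NULL, training,
                    0, net_k3(cfg))
    skips[[i]] <- x
    if (!is.null(acts)) acts[[sprintf("enc%d", i)]] <- x
  }
  for (i in seq.int(D - 1L, 1L)) {
    target <- dim(skips[[i]]$value)[-1]
    x <- t_concat_channels(tape, list(skips[[i]], t_upsample(tape, x, target)))
    x <- conv_block(tape, x, P, sprintf("dec%d", i), FALSE, NULL, training,
                    0, net_k3(cfg))
    if (!is.null(acts)) acts[[sprintf("dec%d", i)]] <- x
  }
  x <- t_conv(tape, x, P[["head.w"]], P[["head.b"]])
  out <- if (cfg$output_activation == "sigmoid") t_sigmoid(tape, x) else
    t_softmax_channels(tape, x)
  if (!is.null(acts)) acts[["head"]] <- out
  out
}

# One V-Net residual stage: x + conv(relu(conv(x))), channel preserving.
vnet_res_stage <- function(tape, x, P, pre) {
  br <- t_conv(tape, x, P[[paste0(pre, ".res.c1.w")]],
               P[[paste0(pre, ".res.c1.b")]])
  br <- t_relu(tape, br)
  br <- t_conv(tape, br, P[[paste0(pre, ".res.c2.w")]],
               P[[paste0(pre, ".res.c2.b")]])
  t_add(tape, x, br)
}

vnet_forward <- function(net, x, tape = NULL, training = FALSE, P = NULL,
                         acts = NULL) {
  cfg <- net$config
  D <- cfg$depth
  if (is.null(P)) P <- param_nodes(tape, net$params)
  x <- t_relu(tape, t_conv(tape, x, P[["stem.w"]], P[["stem.b"]]))
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    x <- vnet_res_stage(tape, x, P, sprintf("enc%d", i))
    x <- t_relu(tape, x)
    skips[[i]] <- x
    if (!is.null(acts)) acts[[sprintf("enc%d", i)]] <- x
    if (i < D) {
      x <- t_conv(tape, x, P[[sprintf("down%d.w", i)]],
                  P[[sprintf("down%d.b", i)]], stride = c(2L, 2L, 2L))
      x <- t_relu(tape, x)
    }
  }
  for (i in seq.int(D - 1L, 1L)) {
    target <- dim(skips[[i]]$value)[-1]
    x <- t_upsample(tape, x, target)
    x <- t_relu(tape, t_conv(tape, x, P[[sprintf("up%d.w", i)]],
                             P[[sprintf("up%d.b", i)]]))
    x <- t_add(tape, x, skips[[i]])  # additive encoder skip
    x <- vnet_res_stage(tape, x, P, sprintf("dec%d", i))
    x <- t_relu(tape, x)
    if (!is.null(acts)) acts[[sprintf("dec%d", i)]] <- x
  }
  x <- t_conv(tape, x, P[["head.w"]], P[["head.b"]])
  out <- t_softmax_channels(tape, x)
  if (!is.null(acts)) acts[["head"]] <- out
  out
}

net_forward <- function(net, xnode, tape = NULL, training = FALSE, P = NULL,
                        acts = NULL) {
  switch(net$arch,
         segchanet = segchanet_forward(net, xnode, tape, training, P, acts),
         unet = unet_forward(net, xnode, tape, training, P, acts),
         vnet = vnet_forward(net, xnode, tape, training, P, acts),
         stop("unknown architecture", call. = FALSE))
}

#' Run inference
#'
#' Deterministic forward pass in inference mode (batch-normalization layers
#' use their stored running statistics).
#'
#' @param net a `seg_network`.
#' @param x a preprocessed [ct_volume()], a `(channels, spatial...)` array,
#'   a bare spatial array (a single channel is assumed), or a list of such
#'   inputs (a batch).
#' @return A probability array of shape `(n_classes, spatial...)`, or a
#'   list of them for a batch. Sigmoid heads give values in \[0, 1\];
#'   softmax heads sum to 1 per voxel over classes.
#' @export
forward <- function(net, x) {
  stopifnot(inherits(net, "seg_network"))
  if (is.list(x) && !inherits(x, "ct_volume")) {
    return(lapply(x, function(xi) forward(net, xi)))
  }
  cfg <- net$config
  xa <- as_input_array(x, cfg)
  check_divisible(dim(xa)[-1], cfg$depth, cfg$spatial_dims)
  out <- net_forward(net, leaf(NULL, xa), tape = NULL, training = FALSE)$value
  if (cfg$spatial_dims == 2) out <- array(out, dim(out)[1:3])
  out
}

#' Binarize a probability map
#'
#' A voxel is foreground iff its probability is strictly greater than the
#' threshold (ties go to background, fixed for reproducibility).
#'
#' @param prob probability array in \[0, 1\] (a leading singleton channel
#'   dimension is dropped).
#' @param threshold decision threshold in \[0, 1\] (default 0.5).
#' @param spacing optional voxel spacing for the returned mask geometry.
#' @return A [label_mask()] with labels \{0, 1\}.
#' @export
predict_mask <- function(prob, threshold = 0.5, spacing = c(1, 1, 1)) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (min(prob) < 0 || max(prob) > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  d <- dim(prob)
  if (!is.null(d) && length(d) == 4L && d[1] == 1L) {
    prob <- array(prob, d[-1])
  }
  label_mask(array(as.integer(prob > threshold), dim(prob)),
             spacing = spacing)
}
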