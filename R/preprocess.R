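#' Preprocessing configuration
#'
#' Tunables of the CT preprocessing chain: the Hounsfield-unit window
#' (default \[-1000, 400\], which spans air to soft tissue and discards
#' dense bone), the cubic target grid (default 128^3), interpolation
#' schemes, and the augmentation switches with the rotation bound in
#' degrees (default 10).
#'
#' @param hu_low,hu_high HU window bounds, `hu_low < hu_high`.
#' @param target_shape voxel triple, each >= 8.
#' @param image_interpolation only `"linear"` is meaningful for images.
#' @param mask_interpolation only `"nearest"` is meaningful for masks.
#' @param augment_flip_lr allow left-right mirroring during augmentation.
#' @param augment_intensity_invert allow intensity negation (white-to-black
#'   inversion) of the normalized volume.
#' @param max_rotation_deg bound of the uniform in-plane rotation draw.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(hu_low = -1000, hu_high = 400,
                              target_shape = c(128, 128, 128),
                              image_interpolation = "linear",
                              mask_interpolation = "nearest",
                              augment_flip_lr = TRUE,
                              augment_intensity_invert = TRUE,
                              max_rotation_deg = 10) {
  stopifnot(hu_low < hu_high, length(target_shape) == 3,
            all(target_shape >= 8), max_rotation_deg >= 0,
            identical(image_interpolation, "linear"),
            identical(mask_interpolation, "nearest"))
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 target_shape = as.integer(target_shape),
                 image_interpolation = image_interpolation,
                 mask_interpolation = mask_interpolation,
                 augment_flip_lr = isTRUE(augment_flip_lr),
                 augment_intensity_invert = isTRUE(augment_intensity_invert),
                 max_rotation_deg = max_rotation_deg),
            class = "preprocess_config")
}

#' Truncate Hounsfield units to a window
#'
#' Clamps every voxel into `[hu_low, hu_high]`; values already inside the
#' window are untouched, so the operation is idempotent.
#'
#' @param vol a [ct_volume()].
#' @param cfg a [preprocess_config()].
#' @return The clipped [ct_volume()].
#' @export
clip_hu <- function(vol, cfg = preprocess_config()) {
  vol$data <- pmin(pmax(vol$data, cfg$hu_low), cfg$hu_high)
  vol
}

#' Z-score normalization
#'
#' Rescales a scan to zero mean and unit variance using its own mean and
#' population standard deviation. Constant volumes cannot be z-scored and
#' raise an error.
#'
#' @param vol a [ct_volume()].
#' @return The normalized [ct_volume()].
#' @export
normalize_zscore <- function(vol) {
  mu <- mean(vol$data)
  sigma <- sqrt(mean((vol$data - mu)^2))  # population sd
  if (sigma <= 0) {
    stop("degenerate input: constant volume has zero variance", call. = FALSE)
  }
  vol$data <- (vol$data - mu) / sigma
  vol
}

#' Resample a volume or mask to a target grid
#'
#' Images use linear interpolation; masks use nearest-neighbor (which can
#' never introduce a label outside the input vocabulary). Spacing is
#' rescaled by the shape ratio so the physical extent is preserved.
#'
#' @param x a [ct_volume()] or [label_mask()].
#' @param target_shape voxel triple.
#' @param interpolation `"linear"` (images) or `"nearest"` (masks);
#'   defaults to the appropriate scheme for the input type.
#' @return Object of the same type at the target shape.
#' @export
resample <- function(x, target_shape, interpolation = NULL) {
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  if (inherits(x, "label_mask")) {
    if (!is.null(interpolation) && interpolation != "nearest") {
      stop("masks must be resampled with nearest-neighbor interpolation",
           call. = FALSE)
    }
    d <- dim(x$data)
    arr <- array(as.numeric(x$data), c(1L, d))
    y <- cpp_resample_nearest(arr, dim(arr), target_shape)
    x$data <- array(as.integer(y), target_shape)
  } else if (inherits(x, "ct_volume")) {
    if (is.null(interpolation)) interpolation <- "linear"
    d <- dim(x$data)
    arr <- array(x$data, c(1L, d))
    y <- if (interpolation == "linear") {
      cpp_resample_linear(arr, dim(arr), target_shape)
    } else {
      cpp_resample_nearest(arr, dim(arr), target_shape)
    }
    x$data <- array(y, target_shape)
  } else {
    stop("resample expects a ct_volume or label_mask", call. = FALSE)
  }
  x$spacing <- x$spacing * (d / target_shape)
  x
}

#' Full preprocessing chain for one case
#'
#' Applies HU truncation, z-score normalization and resampling, in that
#' order (normalization statistics are computed after clipping), to the
#' volume, and nearest-neighbor resampling to the paired mask.
#'
#' @param vol a [ct_volume()].
#' @param mask a [label_mask()] sharing `vol`'s geometry.
#' @param cfg a [preprocess_config()].
#' @return `list(volume, mask)` at `cfg$target_shape`.
#' @export
preprocess_case <- function(vol, mask, cfg = preprocess_config()) {
  v <- resample(normalize_zscore(clip_hu(vol, cfg)), cfg$target_shape)
  m <- resample(mask, cfg$target_shape)
  list(volume = v, mask = m)
}

# ---- augmentation ----------------------------------------------------------

#' Apply a fixed augmentation transform
#'
#' The deterministic core of [augment()]: a left-right mirror, an in-plane
#' (axial) rotation, and an optional intensity negation. The mask receives
#' the identical spatial transform with nearest-neighbor interpolation and
#' is never intensity-inverted. Rotation padding uses `pad_value`
#' (defaulting to the volume minimum, i.e. clipped air after
#' normalization).
#'
#' @param vol a [ct_volume()].
#' @param mask a [label_mask()] with the same geometry.
#' @param transform list with elements `flip` (logical), `invert`
#'   (logical) and `angle` (degrees).
#' @param pad_value intensity used outside the rotated field of view.
#' @return `list(volume, mask)`.
#' @export
apply_augmentation <- function(vol, mask, transform, pad_value = NULL) {
  if (!same_geometry(vol, mask)) {
    stop("volume and mask geometry mismatch", call. = FALSE)
  }
  if (is.null(pad_value)) pad_value <- min(vol$data)
  v <- vol$data
  m <- mask$data
  if (isTRUE(transform$flip)) {
    v <- v[dim(v)[1]:1, , , drop = FALSE]
    m <- m[dim(m)[1]:1, , , drop = FALSE]
  }
  if (abs(transform$angle) > 1e-12) {
    v <- rotate_axial(v, transform$angle, "linear", pad_value)
    m <- rotate_axial(m, transform$angle, "nearest", 0)
  }
  if (isTRUE(transform$invert)) v <- -v
  vol$data <- v
  mask$data <- array(as.integer(m), dim(m))
  list(volume = vol, mask = mask)
}

#' Randomized augmentation of a training case
#'
#' Draws one transform per call from the seeded generator: a left-right
#' flip (probability 1/2 when enabled), an intensity inversion
#' (probability 1/2 when enabled, volume only), and an in-plane rotation
#' angle uniform in `[-max_rotation_deg, +max_rotation_deg]`. The same
#' seed always produces the same output pair.
#'
#' @inheritParams apply_augmentation
#' @param cfg a [preprocess_config()].
#' @param seed integer seed.
#' @return `list(volume, mask, transform)`.
#' @export
augment <- function(vol, mask, cfg = preprocess_config(), seed = 1L) {
  tr <- with_seed(seed, sample_transform(cfg))
  out <- apply_augmentation(vol, mask, tr)
  out$transform <- tr
  out
}

sample_transform <- function(cfg) {
  list(flip = cfg$augment_flip_lr && stats::runif(1) < 0.5,
       invert = cfg$augment_intensity_invert && stats::runif(1) < 0.5,
       angle = if (cfg$max_rotation_deg > 0) {
         stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg)
       } else 0)
}

# Rotate every axial (x-y) slice about the slice center by `angle` degrees.
rotate_axial <- function(arr, angle, method = c("linear", "nearest"),
                         pad = 0) {
  method <- match.arg(method)
  d <- dim(arr)
  nx <- d[1]; ny <- d[2]
  th <- angle * pi / 180
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  di <- ij$i - cx; dj <- ij$j - cy
  # inverse mapping: source coordinate for each output voxel
  u <- cx + cos(th) * di + sin(th) * dj
  v <- cy - sin(th) * di + cos(th) * dj
  out <- array(pad, d)
  if (method == "nearest") {
    ui <- round(u); vi <- round(v)
    ok <- ui >= 1 & ui <= nx & vi >= 1 & vi <= ny
    src <- cbind(ui[ok], vi[ok])
    for (z in seq_len(d[3])) {
      sl <- matrix(pad, nx, ny)
      sl[cbind(ij$i[ok], ij$j[ok])] <- arr[, , z][src]
      out[, , z] <- sl
    }
  } else {
    u0 <- floor(u); v0 <- floor(v)
    fu <- u - u0; fv <- v - v0
    ok <- u0 >= 1 & u0 + 1 <= nx & v0 >= 1 & v0 + 1 <= ny
    i0 <- u0[ok]; j0 <- v0[ok]; a <- fu[ok]; b <- fv[ok]
    oi <- ij$i[ok]; oj <- ij$j[ok]
    for (z in seq_len(d[3])) {
      sl <- arr[, , z]
      val <- (1 - a) * (1 - b) * sl[cbind(i0, j0)] +
             a * (1 - b) * sl[cbind(i0 + 1, j0)] +
             (1 - a) * b * sl[cbind(i0, j0 + 1)] +
             a * b * sl[cbind(i0 + 1, j0 + 1)]
      slo <- matrix(pad, nx, ny)
      slo[cbind(oi, oj)] <- val
      out[, , z] <- slo
    }
  }
  out
}
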