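test_that("U-Net contract: shape, range and channel doubling", {
  set.seed(81)
  cfg <- network_config(depth = 3, base_channels = 8, use_cam = FALSE,
                        deep_supervision = FALSE)
  net <- build_unet(cfg)
  expect_equal(segchanet:::level_widths(cfg), c(8L, 16L, 32L))
  x <- array(rnorm(32^3), c(1, 32, 32, 32))
  out <- forward(net, x)
  expect_equal(dim(out), c(1L, 32L, 32L, 32L))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_error(forward(net, array(0, c(1, 6, 6, 6))), "not compatible")
})

test_that("U-Net parameter count matches a hand-summed formula", {
  set.seed(82)
  cfg <- network_config(depth = 2, base_channels = 4, use_cam = FALSE)
  net <- build_unet(cfg)
  k <- 27  # 3x3x3 kernels
  # encoder: (1->4, 4->4), (4->8, 8->8); decoder: (12->4, 4->4); head 4->1
  want <- (k * 1 * 4 + 4) + (k * 4 * 4 + 4) +
          (k * 4 * 8 + 8) + (k * 8 * 8 + 8) +
          (k * 12 * 4 + 4) + (k * 4 * 4 + 4) +
          (1 * 4 * 1 + 1)
  expect_equal(parameter_count(net), want)
})

test_that("V-Net contract: softmax normalization and residual identity", {
  set.seed(83)
  cfg <- network_config(depth = 3, base_channels = 4, n_classes = 2,
                        output_activation = "softmax", use_cam = FALSE)
  net <- build_vnet(cfg)
  x <- array(rnorm(16^3), c(1, 16, 16, 16))
  out <- forward(net, x)
  expect_equal(dim(out), c(2L, 16L, 16L, 16L))
  sums <- apply(out, c(2, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # zero-initialized head: uniform 0.5/0.5 per voxel
  net0 <- net
  net0$params$head.w[] <- 0
  net0$params$head.b[] <- 0
  out0 <- forward(net0, x)
  expect_true(all(abs(out0 - 0.5) < 1e-12))
  # zeroed residual branch makes a stage the identity
  xs <- segchanet:::leaf(NULL, array(rnorm(4 * 8^3), c(4, 8, 8, 8)))
  pz <- net$params
  for (nm in grep("^enc1\\.res", names(pz), value = TRUE)) pz[[nm]][] <- 0
  P <- segchanet:::param_nodes(NULL, pz)
  st <- segchanet:::vnet_res_stage(NULL, xs, P, "enc1")
  expect_identical(st$value, xs$value)
  expect_error(build_vnet(network_config(spatial_dims = 2, n_classes = 2,
                                         output_activation = "softmax")),
               "volumetric")
})

test_that("SegChaNet contract and CAM parameter monotonicity", {
  set.seed(84)
  x <- array(rnorm(32^3), c(1, 32, 32, 32))
  net_cam <- build_segchanet(reduced_segchanet_config(use_cam = TRUE))
  net_plain <- build_segchanet(reduced_segchanet_config(use_cam = FALSE))
  out <- forward(net_cam, x)
  expect_equal(dim(out), c(1L, 32L, 32L, 32L))
  expect_true(min(out) >= 0 && max(out) <= 1)
  expect_equal(dim(forward(net_plain, x)), dim(out))
  expect_gt(parameter_count(net_cam), parameter_count(net_plain))
  # deepest-map guard for the dilated stack
  wide <- build_segchanet(network_config(depth = 3, base_channels = 2,
                                         dilation_schedule = c(1, 2, 4)))
  expect_error(forward(wide, x), "receptive field")
})

test_that("dilated stack receptive field matches an impulse probe", {
  set.seed(85)
  # single dilated conv layers with rates 1, 2, 4 chained on one channel:
  # closed-form receptive field is 1 + sum(2 * rate)
  rates <- c(1L, 2L, 4L)
  n <- 33L
  x <- array(0, c(1, n, n, 1))
  x[1, 17, 17, 1] <- 1
  w <- array(1, c(1, 1, 3, 3, 1))
  b <- 0
  y <- x
  for (r in rates) {
    y <- segchanet:::cpp_conv_forward(y, dim(y), w, 1L, b, c(3L, 3L, 1L),
                                      c(1L, 1L, 1L), c(r, r, 1L))
  }
  nz <- which(y[1, , , 1] != 0, arr.ind = TRUE)
  observed <- max(nz[, 1]) - min(nz[, 1]) + 1L
  expect_equal(observed, 1 + sum(2 * rates))
})

test_that("forward passes are deterministic and batch-invariant", {
  set.seed(86)
  net <- build_segchanet(network_config(depth = 2, base_channels = 4,
                                        dilation_schedule = c(1)))
  x <- array(rnorm(16^3), c(1, 16, 16, 16))
  expect_identical(forward(net, x), forward(net, x))
  batch <- forward(net, list(x, x))
  expect_identical(batch[[1]], batch[[2]])
})

test_that("output spatial shape equals input shape across random configs", {
  set.seed(87)
  for (i in 1:12) {
    depth <- sample(2:3, 1)
    base <- sample(2:4, 1)
    arch <- sample(c("unet", "vnet", "segchanet"), 1)
    ext <- 2^(depth - 1) * sample(3:4, 1)
    x <- array(rnorm(ext^3), c(1, ext, ext, ext))
    net <- switch(arch,
      unet = build_unet(network_config(depth = depth, base_channels = base,
                                       use_cam = FALSE)),
      vnet = build_vnet(network_config(depth = depth, base_channels = base,
                                       n_classes = 2,
                                       output_activation = "softmax",
                                       use_cam = FALSE)),
      segchanet = build_segchanet(network_config(depth = depth,
                                                 base_channels = base,
                                                 dilation_schedule = c(1))))
    out <- forward(net, x)
    expect_equal(dim(out)[-1], dim(x)[-1])
    if (net$config$output_activation == "sigmoid") {
      expect_true(min(out) >= 0 && max(out) <= 1)
    }
  }
})

test_that("parameter count grows with base channels", {
  set.seed(88)
  p <- vapply(c(2, 4, 8), function(b) {
    parameter_count(build_segchanet(network_config(depth = 2,
                                                   base_channels = b,
                                                   dilation_schedule = c(1))))
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("mask prediction thresholds strictly", {
  p <- array(0.7, c(4, 4, 4))
  expect_true(all(predict_mask(p, 0.5)$data == 1L))
  p5 <- array(0.5, c(4, 4, 4))
  expect_true(all(predict_mask(p5, 0.5)$data == 0L))
  expect_error(predict_mask(p, 1.5), "threshold")
  expect_error(predict_mask(array(2, c(2, 2, 2)), 0.5), "probabilities")
  set.seed(89)
  pr <- array(stats::runif(64), c(4, 4, 4))
  got <- predict_mask(pr, 0.3)$data
  want <- array(0L, dim(pr))
  for (v in seq_along(pr)) want[v] <- if (pr[v] > 0.3) 1L else 0L
  expect_identical(got, want)
})
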