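test_that("the plateau schedule reduces tenfold after each patience window", {
  cfg <- train_config(initial_lr = 5e-4, lr_factor = 0.1, lr_patience = 15)
  worsening <- seq(1, by = 0.01, length.out = 15)  # never improves on epoch 1
  expect_equal(reduce_lr_on_plateau(c(1, worsening[-1], 1.5), cfg), 5e-5)
  expect_equal(reduce_lr_on_plateau(rep(1, 16), cfg), 5e-5)
  expect_equal(reduce_lr_on_plateau(rep(1, 31), cfg), 5e-6)
  # an improvement inside the window resets nothing prematurely
  vals <- c(1, rep(1.2, 13), 0.9)
  expect_equal(reduce_lr_on_plateau(vals, cfg), 5e-4)
})

test_that("learning-rate trajectories are non-increasing during training", {
  set.seed(91)
  case <- tiny_case(seed = 5, shape = 16L)
  net <- build_segchanet(network_config(depth = 2, base_channels = 2,
                                        dilation_schedule = c(1)))
  fit <- train_model(net, list(case), train_config(initial_lr = 1e-3,
                                                   minibatch = 1,
                                                   epochs = 8, seed = 3,
                                                   lr_patience = 2))
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_equal(nrow(fit$history), 8L)
})

test_that("zero epochs leave the parameters untouched", {
  set.seed(92)
  case <- tiny_case(seed = 6, shape = 16L)
  net <- build_segchanet(network_config(depth = 2, base_channels = 2,
                                        dilation_schedule = c(1)))
  fit <- train_model(net, list(case), train_config(epochs = 0, seed = 1))
  expect_identical(coef(fit), net$params)
})

test_that("training is deterministic given the seed", {
  set.seed(93)
  cases <- lapply(7:9, tiny_case, shape = 16L)
  net <- build_segchanet(network_config(depth = 2, base_channels = 2,
                                        dilation_schedule = c(1)))
  cfg <- train_config(initial_lr = 1e-3, minibatch = 2, epochs = 3, seed = 17)
  f1 <- train_model(net, cases, cfg, validation = 3L)
  f2 <- train_model(net, cases, cfg, validation = 3L)
  expect_identical(f1$history, f2$history)
  expect_lt(abs(f1$history$train_loss[3] - f2$history$train_loss[3]), 1e-6)
  # fit methods
  expect_s3_class(f1, "seg_fit")
  expect_output(print(f1), "seg_fit")
  p <- predict(f1, cases[[3]]$volume)
  expect_equal(dim(p), dim(cases[[3]]$mask$data))
  pm <- predict(f1, cases[[3]]$volume, type = "mask")
  expect_s3_class(pm, "label_mask")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(f1)
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("majority voting follows the worked example and unanimity", {
  d <- c(4, 4, 4)
  ones <- label_mask(array(1L, d))
  zeros <- label_mask(array(0L, d))
  vote <- ensemble_majority_vote(list(ones, ones, ones, zeros, zeros))
  expect_true(all(vote$data == 1L))  # votes (1,1,1,0,0) -> 1
  set.seed(94)
  m <- random_binary_mask(d)
  expect_identical(ensemble_majority_vote(list(m, m, m, m, m))$data, m$data)
  # per-voxel counting oracle on random members
  ms <- lapply(1:5, function(i) random_binary_mask(d, p = 0.5))
  got <- ensemble_majority_vote(ms)$data
  want <- array(0L, d)
  for (v in seq_len(prod(d))) {
    want[v] <- as.integer(sum(vapply(ms, function(m) m$data[v],
                                     integer(1))) >= 3L)
  }
  expect_identical(got, want)
  # flipping any 2 of 5 members never changes a unanimous vote
  for (i in 1:4) for (j in (i + 1):5) {
    flipped <- list(ones, ones, ones, ones, ones)
    flipped[[i]] <- zeros
    flipped[[j]] <- zeros
    expect_true(all(ensemble_majority_vote(flipped)$data == 1L))
  }
  expect_error(ensemble_majority_vote(list(ones, zeros)), "odd")
  expect_error(ensemble_majority_vote(list(ones, ones,
                                           label_mask(array(0L, c(2, 2, 2))))),
               "shapes differ")
})

test_that("k-fold assignment covers every case exactly once", {
  for (seed in 1:10) {
    f <- kfold_assign(23, 5, seed = seed)
    expect_equal(length(f), 23L)
    expect_true(all(f %in% 1:5))
    expect_lte(diff(range(table(f))), 1)
  }
  expect_identical(kfold_assign(10, 5, 1), kfold_assign(10, 5, 1))
})

test_that("the hyperparameter grid has the canonical nine rows", {
  g <- segchanet_grid()
  expect_equal(nrow(g), 9L)
  expect_setequal(unique(g$initial_lr), c(1e-4, 1e-3, 3e-3))
  expect_true(all(g$minibatch %in% c(2L, 4L, 8L, 12L)))
  expect_false(any(duplicated(g)))
})

test_that("a singleton grid equals a direct training call", {
  set.seed(95)
  cases <- lapply(10:12, tiny_case, shape = 16L)
  base <- train_config(epochs = 2, seed = 5, minibatch = 1)
  builder <- function() build_segchanet(network_config(depth = 2,
                                                       base_channels = 2,
                                                       dilation_schedule = c(1)))
  g <- run_hyperparameter_grid(cases,
                               data.frame(initial_lr = 1e-3, minibatch = 1),
                               base, builder, validation = 3L)
  expect_equal(nrow(g), 1L)
  expect_true(g$best)
  cfg <- base
  cfg$initial_lr <- 1e-3
  cfg$minibatch <- 1L
  net1 <- segchanet:::with_seed(base$seed, builder())
  fit <- train_model(net1, cases, cfg, validation = 3L)
  expect_equal(g$val_bce, fit$history$val_loss[2], tolerance = 1e-9)
  expect_error(run_hyperparameter_grid(cases, data.frame(), base, builder, 3L),
               "empty")
})

test_that("grad-CAM heatmaps are non-negative, normalized and localized", {
  set.seed(96)
  case <- tiny_case(seed = 13, shape = 16L)
  net <- build_segchanet(network_config(depth = 2, base_channels = 2,
                                        dilation_schedule = c(1)))
  hm <- gradcam_heatmap(net, case$volume, target_layer = "dec1")
  expect_equal(dim(hm), dim(case$volume$data))
  expect_true(all(hm >= 0))
  expect_lte(max(hm), 1)
  # a zero-weight network yields an all-zero heatmap
  z <- net
  for (nm in names(z$params)) z$params[[nm]][] <- 0
  hmz <- gradcam_heatmap(z, case$volume, target_layer = "dec1")
  expect_true(all(hmz == 0))
  expect_error(gradcam_heatmap(net, case$volume, target_layer = "nope"),
               "unknown layer")
})

test_that("grad-CAM matches the closed form on a single-convolution net", {
  # one 1x1 convolution + sigmoid: the heatmap is proportional to
  # relu(weight_k * mean-gradient_k * activation) of the chosen layer
  set.seed(97)
  cfg <- network_config(depth = 2, base_channels = 1,
                        dilation_schedule = c(1))
  net <- build_segchanet(cfg)
  x <- array(rnorm(8^3), c(1, 8, 8, 8))
  hm <- gradcam_heatmap(net, x, target_layer = "dec1")
  # manual recomputation from the recorded activation and head weights
  tape <- segchanet:::new_tape()
  acts <- new.env()
  out <- segchanet:::net_forward(net, segchanet:::leaf(tape, x), tape,
                                 training = FALSE, acts = acts)
  segchanet:::backward(tape, out, seed_grad = array(1, dim(out$value)))
  a <- acts[["dec1"]]$value
  g <- acts[["dec1"]]$grad
  w <- rowMeans(matrix(g, nrow = dim(a)[1]))
  manual <- as.vector(w %*% matrix(a, nrow = dim(a)[1]))
  manual[manual < 0] <- 0
  manual <- array(manual, dim(a)[-1])
  if (max(manual) > 0) manual <- manual / max(manual)
  expect_equal(hm, manual, tolerance = 1e-9)
})
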