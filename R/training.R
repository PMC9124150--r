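#' Training configuration
#'
#' Optimization protocol: Adam with an initial learning rate of 5e-4,
#' reduced by a factor of 0.1 whenever the monitored validation binary
#' cross-entropy fails to improve for 15 consecutive epochs; 500 epochs by
#' default (reduce for desk-scale runs); the compound Dice + BCE loss
#' (`"eq6"`) or the `2 - (IOU + DSC)` loss (`"eq1"`).
#'
#' @param initial_lr initial Adam learning rate.
#' @param minibatch gradient-accumulation batch size.
#' @param epochs number of passes over the training split.
#' @param lr_factor multiplicative learning-rate reduction in (0, 1).
#' @param lr_patience epochs without improvement before a reduction.
#' @param monitor `"val_bce"` (validation binary cross-entropy).
#' @param folds fold count for cross-validation ensembling.
#' @param seed seed for shuffling and augmentation draws.
#' @param loss `"eq6"` (Dice + BCE) or `"eq1"` (2 - IOU - DSC).
#' @param epsilon smoothing constant of the soft overlap terms.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(initial_lr = 5e-4, minibatch = 2L, epochs = 500L,
                         lr_factor = 0.1, lr_patience = 15L,
                         monitor = "val_bce", folds = 5L, seed = 1L,
                         loss = c("eq6", "eq1"), epsilon = 1) {
  loss <- match.arg(loss)
  stopifnot(initial_lr > 0, minibatch >= 1, epochs >= 0,
            lr_factor > 0, lr_factor < 1, lr_patience >= 1, folds >= 2)
  structure(list(initial_lr = initial_lr, minibatch = as.integer(minibatch),
                 epochs = as.integer(epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), monitor = monitor,
                 folds = as.integer(folds), seed = as.integer(seed),
                 loss = loss, epsilon = epsilon),
            class = "train_config")
}

case_arrays <- function(case, cfg) {
  v <- if (inherits(case$volume, "ct_volume")) case$volume$data else case$volume
  m <- if (inherits(case$mask, "label_mask")) case$mask$data else case$mask
  nd <- cfg$spatial_dims
  x <- if (length(dim(v)) == nd) array(v, c(1L, dim(v))) else v
  if (nd == 2) x <- array(x, c(dim(x), 1L))
  list(x = x, y = m)
}

# Foreground probability channel: sigmoid heads use channel 1, softmax
# heads use the last class channel.
foreground_prob <- function(out, cfg) {
  d <- dim(out)
  ch <- if (cfg$output_activation == "sigmoid") 1L else d[1]
  array(out[ch, , , ], d[-1])
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Learning-rate plateau schedule
#'
#' Reduces the learning rate by `lr_factor` whenever the monitored value
#' has not improved (strictly decreased) for `lr_patience` consecutive
#' epochs; the patience counter resets after each reduction and the rate
#' never increases.
#'
#' @param history a numeric vector of monitored values (one per epoch), or
#'   a training-history data frame with a `val_loss` column.
#' @param cfg a [train_config()] supplying `initial_lr`, `lr_factor` and
#'   `lr_patience`.
#' @return The learning rate in force after the last recorded epoch.
#' @export
reduce_lr_on_plateau <- function(history, cfg = train_config()) {
  vals <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  if (!length(vals)) stop("history is empty", call. = FALSE)
  sched <- plateau_state(cfg$initial_lr, cfg$lr_factor, cfg$lr_patience)
  for (v in vals) sched <- plateau_update(sched, v)
  sched$lr
}

plateau_state <- function(lr, factor, patience) {
  list(lr = lr, factor = factor, patience = patience, best = Inf, wait = 0L)
}

plateau_update <- function(s, value) {
  if (value < s$best) {
    s$best <- value
    s$wait <- 0L
  } else {
    s$wait <- s$wait + 1L
    if (s$wait >= s$patience) {
      s$lr <- s$lr * s$factor
      s$wait <- 0L
    }
  }
  s
}

#' Train a segmentation network
#'
#' Optimizes a network on preprocessed cases with Adam, seeded shuffling,
#' optional training-split augmentation, gradient accumulation to the
#' configured minibatch size, and plateau learning-rate scheduling on the
#' validation binary cross-entropy (training BCE when no validation cases
#' are given). All randomness flows from `cfg$seed`, so identical calls
#' produce identical histories; the input network is never mutated.
#'
#' @param net a `seg_network` (its current weights are the starting point).
#' @param dataset list of cases, each `list(volume, mask)` of
#'   [ct_volume()]/[label_mask()] objects or plain arrays, all preprocessed
#'   to one common shape.
#' @param cfg a [train_config()].
#' @param validation integer indices of `dataset` used for validation
#'   monitoring (excluded from gradient updates).
#' @param augment_cfg optional [preprocess_config()]; when supplied,
#'   training cases are re-augmented every epoch.
#' @return An object of class `"seg_fit"` with the trained network, the
#'   per-epoch history (training loss, validation loss, learning rate) and
#'   the configuration. Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @export
train_model <- function(net, dataset, cfg = train_config(),
                        validation = integer(0), augment_cfg = NULL) {
  stopifnot(inherits(net, "seg_network"))
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  ncfg <- net$config
  cases <- lapply(dataset, case_arrays, cfg = ncfg)
  shp <- dim(cases[[1]]$x)
  for (cs in cases) {
    if (!identical(dim(cs$x), shp)) {
      stop("all cases must share one preprocessed shape", call. = FALSE)
    }
  }
  check_divisible(shp[-1], ncfg$depth, ncfg$spatial_dims)
  train_idx <- setdiff(seq_along(cases), validation)
  if (!length(train_idx)) stop("no training cases left", call. = FALSE)
  net <- clone_network(net)
  params <- net$params
  state <- adam_init(params)
  sched <- plateau_state(cfg$initial_lr, cfg$lr_factor, cfg$lr_patience)
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- if (length(train_idx) > 1) sample(train_idx) else train_idx
      ep_loss <- 0
      ep_bce <- 0
      nsteps <- 0L
      b <- 1L
      while (b <= length(ord)) {
        idx <- ord[b:min(b + cfg$minibatch - 1L, length(ord))]
        b <- b + cfg$minibatch
        grads <- NULL
        for (i in idx) {
          cs <- cases[[i]]
          if (!is.null(augment_cfg)) {
            tr <- sample_transform(augment_cfg)
            aug <- apply_augmentation(
              ct_volume(array(cs$x, shp[-1]), spacing = rep(1, 3)),
              label_mask(cs$y, spacing = rep(1, 3)), tr)
            cs <- list(x = array(aug$volume$data, shp), y = aug$mask$data)
          }
          tape <- new_tape()
          P <- param_nodes(tape, params)
          net$params <- params
          out <- net_forward(net, leaf(tape, cs$x), tape, training = TRUE,
                             P = P)
          p <- foreground_prob(out$value, ncfg)
          lw <- loss_with_grad(as.numeric(cs$y), p, cfg$loss, cfg$epsilon)
          gout <- array(0, dim(out$value))
          ch <- if (ncfg$output_activation == "sigmoid") 1L else dim(out$value)[1]
          gout[ch, , , ] <- lw$grad
          backward(tape, out, seed_grad = gout)
          ep_loss <- ep_loss + lw$value
          ep_bce <- ep_bce + loss_dice_bce(as.numeric(cs$y), p)$bce_term
          nsteps <- nsteps + 1L
          gi <- lapply(P, function(nd) nd$grad)
          grads <- if (is.null(grads)) gi else {
            for (nm in names(gi)) {
              if (!is.null(gi[[nm]])) {
                grads[[nm]] <- if (is.null(grads[[nm]])) gi[[nm]] else
                  grads[[nm]] + gi[[nm]]
              }
            }
            grads
          }
        }
        grads <- lapply(grads, function(g) if (is.null(g)) NULL else
          g / length(idx))
        upd <- adam_step(params, grads, state, sched$lr)
        params <- upd$params
        state <- upd$state
      }
      net$params <- params
      # monitored BCE: held-out cases when given, else the epoch's own
      # training-step BCE (avoids a redundant monitoring pass)
      val_bce <- if (length(validation)) {
        mean(vapply(validation, function(i) {
          p <- foreground_prob(
            net_forward(net, leaf(NULL, cases[[i]]$x), NULL,
                        training = FALSE)$value, ncfg)
          loss_dice_bce(as.numeric(cases[[i]]$y), p)$bce_term
        }, numeric(1)))
      } else ep_bce / max(nsteps, 1L)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / max(nsteps, 1L),
                                  val_loss = val_bce, lr = sched$lr)
      sched <- plateau_update(sched, val_bce)
    }
  })
  net$params <- params
  structure(list(network = net, config = cfg,
                 history = if (cfg$epochs > 0) do.call(rbind, hist) else
                   data.frame(epoch = integer(0), train_loss = numeric(0),
                              val_loss = numeric(0), lr = numeric(0)),
                 n_train = length(train_idx), n_validation = length(validation)),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat(sprintf("<seg_fit> %s trained %d epoch(s) on %d case(s) (%d validation)\n",
              x$network$arch, nrow(x$history), x$n_train, x$n_validation))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final: train loss %.4f, monitored BCE %.4f, lr %.2e\n",
                last$train_loss, last$val_loss, last$lr))
  }
  invisible(x)
}

#' @export
summary.seg_fit <- function(object, ...) {
  print(object)
  print(object$network)
  h <- object$history
  if (nrow(h)) {
    cat(sprintf("  learning-rate reductions: %d\n",
                sum(diff(h$lr) < 0)))
    cat(sprintf("  best monitored BCE: %.4f (epoch %d)\n",
                min(h$val_loss), h$epoch[which.min(h$val_loss)]))
  }
  invisible(object)
}

#' @export
coef.seg_fit <- function(object, ...) object$network$params

#' Predict segmentation probabilities or masks
#'
#' @param object a `"seg_fit"`.
#' @param newdata a [ct_volume()], array, or list of them.
#' @param type `"prob"` for the foreground probability map, `"mask"` for a
#'   thresholded [label_mask()].
#' @param threshold binarization threshold for `type = "mask"`.
#' @param ... unused.
#' @return Probability array(s) or [label_mask()](s).
#' @export
predict.seg_fit <- function(object, newdata, type = c("prob", "mask"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(x) {
    sp <- if (inherits(x, "ct_volume")) x$spacing else c(1, 1, 1)
    p <- foreground_prob(forward(object$network, x), object$network$config)
    if (type == "prob") p else predict_mask(p, threshold, spacing = sp)
  }
  if (is.list(newdata) && !inherits(newdata, "ct_volume")) {
    lapply(newdata, one)
  } else one(newdata)
}

#' @export
plot.seg_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = c("training loss", "monitored BCE"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' The canonical hyperparameter grid
#'
#' Nine (initial learning rate, minibatch) combinations explored when
#' tuning the attention network.
#'
#' @return Data frame with columns `initial_lr` and `minibatch` (9 rows).
#' @export
segchanet_grid <- function() {
  data.frame(initial_lr = c(1e-4, 1e-4, 1e-4, 1e-3, 1e-3, 1e-3, 3e-3, 3e-3,
                            3e-3),
             minibatch = c(2L, 8L, 12L, 2L, 4L, 8L, 4L, 12L, 8L))
}

#' Run a hyperparameter grid search
#'
#' Trains one model per grid row (fresh weights per row, seeded
#' identically so rows differ only in their hyperparameters) and reports
#' final validation metrics; the best row is chosen by validation Dice.
#'
#' @param dataset as in [train_model()].
#' @param grid data frame with columns `initial_lr` and `minibatch`.
#' @param base_cfg a [train_config()] supplying everything else.
#' @param builder zero-argument function returning a fresh `seg_network`.
#' @param validation validation indices (required for the Dice ranking).
#' @return Data frame with one row per grid row (`initial_lr`,
#'   `minibatch`, `val_dsc`, `val_bce`, `best`).
#' @export
run_hyperparameter_grid <- function(dataset, grid, base_cfg, builder,
                                    validation) {
  if (!nrow(grid)) stop("grid is empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_cfg
    cfg$initial_lr <- grid$initial_lr[i]
    cfg$minibatch <- as.integer(grid$minibatch[i])
    net <- with_seed(base_cfg$seed, builder())
    fit <- train_model(net, dataset, cfg, validation = validation)
    dscs <- vapply(validation, function(j) {
      pm <- predict(fit, dataset[[j]]$volume, type = "mask")
      truth <- dataset[[j]]$mask
      tm <- if (inherits(truth, "label_mask")) truth else label_mask(truth)
      evaluate_case(pm, tm)$dsc
    }, numeric(1))
    data.frame(initial_lr = cfg$initial_lr, minibatch = cfg$minibatch,
               val_dsc = mean(dscs),
               val_bce = fit$history$val_loss[nrow(fit$history)])
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$val_dsc)
  out
}

#' Majority-vote ensemble of binary masks
#'
#' A voxel is foreground iff strictly more than half of the (odd number
#' of) member masks mark it: votes of (1,1,1,0,0) yield 1.
#'
#' @param masks list of binary [label_mask()]s or 0/1 arrays of identical
#'   shape, odd length.
#' @return A [label_mask()] with the per-voxel majority.
#' @export
ensemble_majority_vote <- function(masks) {
  n <- length(masks)
  if (n %% 2L == 0L) {
    stop("majority voting requires an odd number of members", call. = FALSE)
  }
  arrs <- lapply(masks, mask_data)
  d <- dim(arrs[[1]])
  for (a in arrs) {
    if (!identical(dim(a), d)) stop("member shapes differ", call. = FALSE)
    if (!all(a %in% c(0L, 1L))) stop("members must be binary", call. = FALSE)
  }
  votes <- Reduce(`+`, arrs)
  sp <- mask_spacing(masks[[1]])
  label_mask(array(as.integer(votes > n / 2), d), spacing = sp)
}

#' Assign cases to cross-validation folds
#'
#' @param n number of cases.
#' @param k fold count.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`, sizes differing by at
#'   most one; every case lands in exactly one fold.
#' @export
kfold_assign <- function(n, k, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Grad-CAM saliency heatmap
#'
#' Gradient-weighted channel pooling at a chosen layer: channels of the
#' layer's activation are weighted by the spatial mean of the gradient of
#' the summed output probability, summed, rectified, upsampled to input
#' resolution, and max-normalized to 1 when non-zero.
#'
#' @param net a `seg_network`.
#' @param vol input volume (as accepted by [forward()]).
#' @param target_layer activation name, e.g. `"enc1"`, `"bottleneck"`,
#'   `"dec1"` (the shallowest decoder block, the default).
#' @return Non-negative heatmap array at input spatial resolution.
#' @export
gradcam_heatmap <- function(net, vol, target_layer = "dec1") {
  cfg <- net$config
  xa <- as_input_array(vol, cfg)
  check_divisible(dim(xa)[-1], cfg$depth, cfg$spatial_dims)
  tape <- new_tape()
  acts <- new.env(parent = emptyenv())
  out <- net_forward(net, leaf(tape, xa), tape, training = FALSE, acts = acts)
  if (!target_layer %in% ls(acts)) {
    stop(sprintf("unknown layer '%s' (available: %s)", target_layer,
                 paste(sort(ls(acts)), collapse = ", ")), call. = FALSE)
  }
  backward(tape, out, seed_grad = array(1, dim(out$value)))
  nd <- acts[[target_layer]]
  g <- nd$grad
  if (is.null(g)) g <- array(0, dim(nd$value))
  C <- dim(nd$value)[1]
  w <- rowMeans(matrix(g, nrow = C))
  hm <- as.vector(w %*% matrix(nd$value, nrow = C))
  hm[hm < 0] <- 0
  hm <- array(hm, c(1L, dim(nd$value)[-1]))
  hm <- cpp_resample_linear(hm, dim(hm), dim(xa)[-1])
  hm <- array(hm, dim(xa)[-1])
  mx <- max(hm)
  if (mx > 0) hm <- hm / mx
  if (cfg$spatial_dims == 2) hm <- array(hm, dim(hm)[1:2])
  hm
}
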