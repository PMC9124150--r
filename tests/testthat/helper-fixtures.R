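# Shared fixtures, built in code.

random_volume <- function(shape = c(16, 16, 16), spacing = c(1, 1, 1),
                          lo = -1200, hi = 600) {
  ct_volume(array(stats::runif(prod(shape), lo, hi), shape),
            spacing = spacing)
}

random_binary_mask <- function(shape = c(8, 8, 8), p = 0.3,
                               spacing = c(1, 1, 1)) {
  label_mask(array(as.integer(stats::runif(prod(shape)) < p), shape),
             spacing = spacing)
}

# A small phantom preprocessed to a cube, ready for the reduced networks.
tiny_case <- function(seed = 1, shape = 32L) {
  ph <- generate_phantom(
    phantom_spec(shape = rep(shape, 3), spacing = rep(96 / shape, 3),
                 nodule_diameter_mm = c(8, 25), nodules_per_case = c(1, 2)),
    seed = seed)
  preprocess_case(ph$volume, ph$mask,
                  preprocess_config(target_shape = rep(shape, 3)))
}

reduced_segchanet_config <- function(use_cam = TRUE) {
  network_config(depth = 3, base_channels = 8, use_cam = use_cam,
                 dilation_schedule = c(1, 2))
}
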