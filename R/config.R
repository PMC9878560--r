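# YAML run configuration.
#
# A config file mirrors the module surfaces:
#
#   network:
#     input_size: 256
#     preset: hardnet68          # or "tiny"
#     decoder_channels: [256, 128, 64]
#   backbone:                    # optional, overrides the preset
#     stem: [32, 64]
#     multiplier: 1.7
#     stages:                    # n_layers, growth k, transition t, downsample
#       - {layers: 8, k: 14, t: 128, down: true}
#       - ...
#   aspp:      {dilations: [3, 6, 12, 18]}
#   attention: {reduction: 8}
#   loss:      {alpha: 0.25, gamma: 2, smooth: 1, w_dice: 1, w_focal: 1}
#   train:     {batch_size: 4, max_epochs: 300, patience: 50,
#               learning_rate: 1.0e-4, seed: 1}
#   data:      {size: 256, seed: 1,
#               augment: {crop: [160, 160], rotation: 30, blur: [3, 3],
#                         variants: 20},
#               split: {fractions: [0.8, 0.1, 0.1]}}

#' Read a run configuration
#'
#' @param path Path to a YAML file (see the package configuration layout in
#'   the source of this function's file or the methods vignette).
#' @return The parsed configuration list, class `polypseg_config`.
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "polypseg_config")
}

#' Build specs from a configuration
#'
#' `config_network_spec()`, `config_loss()`, `config_train()`,
#' `config_augment()` and `config_split()` turn the corresponding YAML
#' blocks into the package's spec objects, falling back to the canonical
#' defaults for anything omitted.
#'
#' @param cfg A list from [read_config()].
#' @return The corresponding spec object.
#' @export
config_network_spec <- function(cfg) {
  nw <- cfg$network %||% list()
  enc <- if (!is.null(cfg$backbone)) {
    bb <- cfg$backbone
    m <- bb$multiplier %||% 1.7
    stages <- lapply(bb$stages, function(s) {
      hdb_spec(s$layers, s$k, s$t, multiplier = m,
               downsample = isTRUE(s$down))
    })
    encoder_spec(stem_channels = unlist(bb$stem %||% c(32L, 64L)),
                 stages = stages)
  } else if (identical(nw$preset, "tiny")) {
    encoder_spec_tiny()
  } else {
    encoder_spec_hardnet68()
  }
  aspp <- dense_aspp_spec(
    dilation_rates = unlist((cfg$aspp %||% list())$dilations %||%
                              c(3L, 6L, 12L, 18L))
  )
  dec <- unlist(nw$decoder_channels %||%
                  if (identical(nw$preset, "tiny")) c(48L, 32L, 24L)
                  else c(256L, 128L, 64L))
  network_spec(
    input_size = nw$input_size %||%
      if (identical(nw$preset, "tiny")) 96L else 256L,
    encoder = enc, aspp = aspp, decoder_channels = dec,
    reduction = (cfg$attention %||% list())$reduction %||% 8L
  )
}

#' @rdname config_network_spec
#' @export
config_loss <- function(cfg) {
  l <- cfg$loss %||% list()
  loss_config(alpha = l$alpha %||% 0.25, gamma = l$gamma %||% 2,
              smooth = l$smooth %||% 1, w_dice = l$w_dice %||% 1,
              w_focal = l$w_focal %||% 1)
}

#' @rdname config_network_spec
#' @export
config_train <- function(cfg) {
  t <- cfg$train %||% list()
  train_config(batch_size = t$batch_size %||% 4L,
               max_epochs = t$max_epochs %||% 300L,
               patience = t$patience %||% 50L,
               learning_rate = t$learning_rate %||% 1e-4,
               seed = t$seed %||% 1L,
               max_steps = t$max_steps %||% Inf)
}

#' @rdname config_network_spec
#' @export
config_augment <- function(cfg) {
  a <- (cfg$data %||% list())$augment %||% list()
  augment_spec(crop_size = unlist(a$crop %||% c(160L, 160L)),
               rotation_max_deg = a$rotation %||% 30,
               blur_kernel = unlist(a$blur %||% c(3L, 3L)),
               blur_sigma = a$blur_sigma,
               variants_per_image = a$variants %||% 20L,
               seed = (cfg$data %||% list())$seed %||% 1L)
}

#' @rdname config_network_spec
#' @export
config_split <- function(cfg) {
  s <- (cfg$data %||% list())$split %||% list()
  split_spec(fractions = unlist(s$fractions %||% c(0.8, 0.1, 0.1)),
             seed = (cfg$data %||% list())$seed %||% 1L)
}
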