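#' Network specification
#'
#' The full segmentation model: HarDNet encoder, DenseASPP bridge on the
#' stride-32 map, and three decoder stages.  Each decoder stage bilinearly
#' upsamples the stream 2x, matches the encoder skip (strides 16, 8, 4) to
#' the stream width with a 1x1 conv, multiplies the two elementwise, applies
#' an SCA module and a 3x3 conv to the next stream width.  A 1x1 conv plus
#' sigmoid head produces the probability map, bilinearly upsampled to the
#' input size.
#'
#' @param input_size Side length of the (square) input in pixels; must be
#'   divisible by 32.  Canonical 256.
#' @param encoder An [encoder_spec()]; canonical [encoder_spec_hardnet68()].
#' @param aspp A [dense_aspp_spec()].
#' @param decoder_channels Stream widths after each of the three decoder
#'   stages' 3x3 convs.
#' @param reduction Channel-attention bottleneck reduction inside SCA.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_size = 256L,
                         encoder = encoder_spec_hardnet68(),
                         aspp = dense_aspp_spec(),
                         decoder_channels = c(256L, 128L, 64L),
                         reduction = 8L) {
  if (input_size %% 32L != 0L) {
    stop("input_size must be divisible by 32", call. = FALSE)
  }
  if (length(decoder_channels) != 3L) {
    stop("exactly three decoder stages are expected", call. = FALSE)
  }
  structure(
    list(input_size = as.integer(input_size), encoder = encoder,
         aspp = aspp, decoder_channels = as.integer(decoder_channels),
         decoder_stages = 3L, out_channels = 1L,
         reduction = as.integer(reduction)),
    class = "network_spec"
  )
}

#' @rdname network_spec
#' @export
network_spec_tiny <- function(input_size = 96L) {
  network_spec(input_size = input_size, encoder = encoder_spec_tiny(),
               decoder_channels = c(48L, 32L, 24L))
}

#' Build the segmentation network
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization (Kaiming uniform).
#' @return A model of class `polyp_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  set.seed(seed)
  enc <- build_encoder(spec$encoder)
  stage_specs <- spec$encoder$stages
  tapped <- vapply(spec$encoder$taps, function(i) {
    stage_specs[[i]]$transition_channels
  }, numeric(1)) # channels at strides 4, 8, 16, 32
  c32 <- tapped[4]
  aspp <- build_dense_aspp(spec$aspp, c32)
  stream <- aspp$out_channels
  skip_c <- rev(tapped[1:3]) # strides 16, 8, 4
  stages <- vector("list", 3L)
  for (i in 1:3) {
    skip_conv <- conv_layer(skip_c[i], stream, k = 1L,
                            name = sprintf("dec%d.skip", i))
    att <- new_sca(stream, reduction = spec$reduction)
    post <- conv_layer(stream, spec$decoder_channels[i], k = 3L,
                       name = sprintf("dec%d.post", i))
    stages[[i]] <- list(skip_conv = skip_conv, sca = att, post = post)
    stream <- spec$decoder_channels[i]
  }
  head <- conv_layer(stream, 1L, k = 1L, bias = TRUE, bn = FALSE,
                     act = "none", name = "head")
  structure(
    list(spec = spec, encoder = enc, aspp = aspp, stages = stages,
         head = head),
    class = c("polyp_network", "list")
  )
}

# Forward pass returning the probability-map tape node (H, W, 1, N).
network_forward <- function(model, x, training = FALSE) {
  pyr <- encoder_forward(model$encoder, x, training)
  h <- dense_aspp_node(model$aspp, pyr[["32"]], training)
  skips <- list(pyr[["16"]], pyr[["8"]], pyr[["4"]])
  for (i in 1:3) {
    st <- model$stages[[i]]
    d <- dim(h$v)
    h <- tg_resize(h, 2L * d[1], 2L * d[2])
    sk <- conv_forward(st$skip_conv, skips[[i]], training)
    h <- tg_mul(h, sk)
    h <- sca_node(st$sca, h, training)
    h <- conv_forward(st$post, h, training)
  }
  logits <- conv_forward(model$head, h, training)
  prob <- tg_sigmoid(logits)
  din <- dim(x$v)
  tg_resize(prob, din[1], din[2])
}

#' Predict polyp probability maps
#'
#' Runs the network in inference mode.  Output entries lie strictly in
#' `(0, 1)` and the map has the same spatial size as the input.
#'
#' @param model A [build_network()] model.
#' @param images `(H, W, 3)` array or `(H, W, 3, N)` batch, values in
#'   `[0, 1]`, `H` and `W` divisible by 32.
#' @return `(H, W)` matrix for a single image, `(H, W, N)` array for a
#'   batch.
#' @export
predict_probs <- function(model, images) {
  x <- as_batch(images, channels = 3L)
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("image height and width must be divisible by 32", call. = FALSE)
  }
  out <- network_forward(model, tg_leaf(x), training = FALSE)$v
  if (length(dim(images)) == 3L) {
    matrix(out, d[1], d[2])
  } else {
    array(out, c(d[1], d[2], d[4]))
  }
}

#' Threshold a probability map into a binary mask
#'
#' @param prob Numeric array of probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`; a pixel is foreground
#'   iff its probability is `>= threshold`.
#' @return Integer array of 0/1 with the same shape.
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  m <- (prob >= threshold) + 0L
  dim(m) <- dim(prob)
  m
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable weight tensor (conv kernels,
#' biases, batch-norm scale/shift).  Batch-norm running statistics are not
#' trainable and are excluded.
#'
#' @param model Any module tree built by this package.
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  n_params(collect_params(model))
}

#' @export
print.polyp_network <- function(x, ...) {
  cat("<polyp_network>\n")
  cat(sprintf("  input size : %dx%d\n", x$spec$input_size,
              x$spec$input_size))
  cat(sprintf("  encoder    : %d HDB stages, stem (%s)\n",
              length(x$spec$encoder$stages),
              paste(x$spec$encoder$stem_channels, collapse = ", ")))
  cat(sprintf("  bridge     : DenseASPP dilations (%s) -> %d ch\n",
              paste(x$spec$aspp$dilation_rates, collapse = ", "),
              x$aspp$out_channels))
  cat(sprintf("  decoder    : 3 SCA stages -> widths (%s)\n",
              paste(x$spec$decoder_channels, collapse = ", ")))
  cat(sprintf("  parameters : %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Model summary as a one-row tibble
#'
#' @param x A `polyp_network`.
#' @param ... Unused.
#' @return A tibble with the parameter count and architecture summary.
#' @export
glance.polyp_network <- function(x, ...) {
  tibble::tibble(
    parameters = count_parameters(x),
    input_size = x$spec$input_size,
    decoder_stages = x$spec$decoder_stages,
    aspp_dilations = paste(x$spec$aspp$dilation_rates, collapse = "/"),
    encoder_stages = length(x$spec$encoder$stages)
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the `network_spec` together with
#' every weight tensor and batch-norm running statistic.
#'
#' @param model A `polyp_network`.
#' @param path File path.
#' @return `load_checkpoint()` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, weights = snapshot_weights(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$spec, seed = 1L)
  restore_weights(model, ck$weights)
  model
}

#' @importFrom generics glance
#' @export
generics::glance
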