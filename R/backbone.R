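#' Skip-connection targets of a harmonic dense block layer
#'
#' In a harmonic dense block (HDB), layer `k` receives input from layer
#' `k - 2^n` for every integer `n >= 0` such that `2^n` divides `k` and
#' `k - 2^n >= 0` (index 0 denotes the block input).  This sparsifies
#' DenseNet's all-to-all connectivity while keeping a logarithmic number of
#' skip paths per layer.
#'
#' @param layer_index Positive integer, 1-based layer position in the block.
#' @return Integer vector of source layer indices, in decreasing order.
#' @examples
#' link_targets(1) # 0
#' link_targets(4) # 3 2 0
#' link_targets(6) # 5 4
#' @export
link_targets <- function(layer_index) {
  if (length(layer_index) != 1L || is.na(layer_index) || layer_index < 1 ||
      layer_index != round(layer_index)) {
    stop("layer_index must be a positive integer", call. = FALSE)
  }
  k <- as.integer(layer_index)
  out <- integer(0)
  n <- 0L
  repeat {
    p <- as.integer(2^n)
    if (k %% p != 0L) break
    tgt <- k - p
    if (tgt < 0L) break
    out <- c(out, tgt)
    n <- n + 1L
  }
  out
}

#' Channel width of a harmonic dense block layer
#'
#' Layers whose index is divisible by a high power of two are "key" layers
#' and are widened: the width is `k * m^n` where `n` is the 2-adic valuation
#' of the layer index (the largest power of two dividing it), `k` the growth
#' rate and `m` the multiplier.  The product is rounded to the nearest even
#' integer (minimum 2) so that downstream concatenations stay well formed.
#'
#' @param layer_index Positive integer layer position.
#' @param growth_rate Base channel width `k` (>= 1).
#' @param multiplier Key-layer widening factor `m` (>= 1).
#' @return Positive even integer channel count.
#' @examples
#' layer_width(1, 14, 1.7) # 14
#' layer_width(2, 14, 1.7) # 24
#' layer_width(4, 14, 1.7) # 40
#' @export
layer_width <- function(layer_index, growth_rate, multiplier) {
  if (layer_index < 1 || layer_index != round(layer_index)) {
    stop("layer_index must be a positive integer", call. = FALSE)
  }
  if (growth_rate < 1) stop("growth_rate must be >= 1", call. = FALSE)
  if (multiplier < 1) stop("multiplier must be >= 1", call. = FALSE)
  k <- as.integer(layer_index)
  n <- 0L
  while (k %% 2L == 0L) {
    k <- k %/% 2L
    n <- n + 1L
  }
  w <- growth_rate * multiplier^n
  max(2L, 2L * (floor(floor(w + 1) / 2)))
}

#' Specification of one harmonic dense block
#'
#' @param n_layers Number of 3x3 conv layers in the block (>= 1).
#' @param growth_rate Base width `k` per layer.
#' @param transition_channels Output width `t` of the block's 1x1 transition.
#' @param multiplier Key-layer compression/widening factor `m`.
#' @param downsample Whether the stage halves spatial resolution on entry
#'   (2x2 max pooling).
#' @return An object of class `hdb_spec`.
#' @export
hdb_spec <- function(n_layers, growth_rate, transition_channels,
                     multiplier = 1.7, downsample = FALSE) {
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (growth_rate < 1) stop("growth_rate must be >= 1", call. = FALSE)
  if (multiplier < 1) stop("multiplier must be >= 1.0", call. = FALSE)
  if (transition_channels < growth_rate) {
    stop("transition_channels must be >= growth_rate", call. = FALSE)
  }
  structure(
    list(n_layers = as.integer(n_layers),
         growth_rate = as.integer(growth_rate),
         transition_channels = as.integer(transition_channels),
         multiplier = multiplier,
         downsample = isTRUE(downsample)),
    class = "hdb_spec"
  )
}

#' Encoder specification
#'
#' Five harmonic dense blocks after a two-conv stem.  The canonical preset
#' ([encoder_spec_hardnet68()]) follows the HarDNet68 stage plan: stem widths
#' (32, 64) and stages (8, k=14, t=128), (16, 16, 256), (16, 20, 320),
#' (16, 40, 640), (4, 160, 1024) with multiplier m = 1.7.  The feature
#' pyramid is tapped after stages 1, 3, 4 and 5, i.e. at strides 4, 8, 16
#' and 32 (the two middle blocks both run at stride 8; the deeper of the two
#' feeds the decoder skip).
#'
#' @param stem_channels Length-2 integer vector of stem conv widths.
#' @param stages List of [hdb_spec()] objects.
#' @param taps Indices of the stages whose outputs form the pyramid, in
#'   stride order 4, 8, 16, 32.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(stem_channels = c(32L, 64L), stages,
                         taps = c(1L, 3L, 4L, 5L)) {
  stopifnot(length(stem_channels) == 2L, length(stages) >= 1L)
  for (s in stages) stopifnot(inherits(s, "hdb_spec"))
  structure(
    list(stem_channels = as.integer(stem_channels), stages = stages,
         taps = as.integer(taps)),
    class = "encoder_spec"
  )
}

#' @rdname encoder_spec
#' @export
encoder_spec_hardnet68 <- function() {
  encoder_spec(
    stem_channels = c(32L, 64L),
    stages = list(
      hdb_spec(8, 14, 128, downsample = TRUE),
      hdb_spec(16, 16, 256, downsample = TRUE),
      hdb_spec(16, 20, 320, downsample = FALSE),
      hdb_spec(16, 40, 640, downsample = TRUE),
      hdb_spec(4, 160, 1024, downsample = TRUE)
    )
  )
}

# A small-width encoder with the same five-stage topology, for CPU-scale
# experiments and examples.
#' @rdname encoder_spec
#' @export
encoder_spec_tiny <- function() {
  encoder_spec(
    stem_channels = c(8L, 16L),
    stages = list(
      hdb_spec(4, 8, 32, downsample = TRUE),
      hdb_spec(4, 8, 40, downsample = TRUE),
      hdb_spec(4, 10, 48, downsample = FALSE),
      hdb_spec(4, 12, 64, downsample = TRUE),
      hdb_spec(4, 14, 96, downsample = TRUE)
    )
  )
}

#' Build one harmonic dense block
#'
#' Layer `l` consumes the channel-concatenation of the outputs of
#' [link_targets()]`(l)` (index 0 being the block input).  The block output
#' concatenates the final layer with every odd-indexed layer, then a 1x1
#' transition maps it to `transition_channels`.
#'
#' @param spec An [hdb_spec()].
#' @param in_channels Channels of the block input (> 0).
#' @return A block descriptor (class `hdb_block`) usable with
#'   `hdb_forward()`; its `out_channels` field equals
#'   `spec$transition_channels`.
#' @export
build_hdb <- function(spec, in_channels) {
  if (in_channels <= 0) {
    stop("in_channels must be positive", call. = FALSE)
  }
  n <- spec$n_layers
  widths <- vapply(seq_len(n), layer_width, numeric(1),
                   growth_rate = spec$growth_rate,
                   multiplier = spec$multiplier)
  widths0 <- c(in_channels, widths) # widths0[l + 1] = width of layer l
  links <- lapply(seq_len(n), link_targets)
  layers <- vector("list", n)
  for (l in seq_len(n)) {
    cin <- sum(widths0[links[[l]] + 1L])
    layers[[l]] <- conv_layer(cin, widths[l], k = 3L,
                              name = sprintf("hdb.l%d", l))
  }
  keep <- sort(unique(c(which(seq_len(n) %% 2L == 1L), n)))
  concat_channels <- sum(widths[keep])
  transition <- conv_layer(concat_channels, spec$transition_channels, k = 1L,
                           name = "hdb.trans")
  structure(
    list(spec = spec, layers = layers, transition = transition,
         links = links, keep = keep, widths = widths,
         in_channels = as.integer(in_channels),
         out_channels = spec$transition_channels),
    class = c("hdb_block", "list")
  )
}

# Forward pass through an HDB. `x` is a tape node (H, W, C, N).
hdb_forward <- function(block, x, training = FALSE) {
  n <- length(block$layers)
  outs <- vector("list", n + 1L)
  outs[[1L]] <- x # layer 0 = block input
  for (l in seq_len(n)) {
    srcs <- rev(block$links[[l]]) # ascending layer order
    xin <- tg_concat(outs[srcs + 1L])
    outs[[l + 1L]] <- conv_forward(block$layers[[l]], xin, training)
  }
  cat_out <- tg_concat(outs[block$keep + 1L])
  conv_forward(block$transition, cat_out, training)
}

#' Build the harmonic dense encoder
#'
#' Stem: 3x3 conv stride 2 then 3x3 conv stride 1 (each conv -> batch norm ->
#' ReLU), followed by the five HDB stages; stages flagged `downsample` are
#' entered through a 2x2 max pool.
#'
#' @param spec An [encoder_spec()].
#' @return An encoder descriptor (class `polyp_encoder`).
#' @export
build_encoder <- function(spec) {
  stem1 <- conv_layer(3L, spec$stem_channels[1], k = 3L, stride = 2L,
                      name = "stem1")
  stem2 <- conv_layer(spec$stem_channels[1], spec$stem_channels[2], k = 3L,
                      name = "stem2")
  blocks <- vector("list", length(spec$stages))
  cin <- spec$stem_channels[2]
  for (i in seq_along(spec$stages)) {
    blocks[[i]] <- build_hdb(spec$stages[[i]], cin)
    cin <- blocks[[i]]$out_channels
  }
  structure(
    list(spec = spec, stem1 = stem1, stem2 = stem2, blocks = blocks),
    class = c("polyp_encoder", "list")
  )
}

# Internal forward returning tape nodes for the tapped stages.
encoder_forward <- function(enc, x, training = FALSE) {
  h <- conv_forward(enc$stem1, x, training)
  h <- conv_forward(enc$stem2, h, training)
  taps <- enc$spec$taps
  maps <- vector("list", length(taps))
  names(maps) <- as.character(c(4L, 8L, 16L, 32L)[seq_along(taps)])
  for (i in seq_along(enc$blocks)) {
    if (enc$blocks[[i]]$spec$downsample) h <- tg_maxpool2(h)
    h <- hdb_forward(enc$blocks[[i]], h, training)
    hit <- which(taps == i)
    if (length(hit)) maps[[hit]] <- h
  }
  maps
}

#' Encode an image into a multi-scale feature pyramid
#'
#' @param encoder A [build_encoder()] result.
#' @param image Numeric array `(H, W, 3)` (or a batch `(H, W, 3, N)`) with
#'   values in `[0, 1]`; `H` and `W` must be divisible by 32.
#' @return A `feature_pyramid`: a list `maps` keyed by stride
#'   ("4", "8", "16", "32"), each an `(H/stride, W/stride, C)` array (with a
#'   trailing batch dimension if the input was a batch).  For the canonical
#'   encoder the channel counts are 128, 320, 640 and 1024.
#' @export
encode <- function(encoder, image) {
  x <- as_batch(image, channels = 3L)
  d <- dim(x)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("image height and width must be divisible by 32", call. = FALSE)
  }
  nodes <- encoder_forward(encoder, tg_leaf(x), training = FALSE)
  single <- length(dim(image)) == 3L
  maps <- lapply(nodes, function(nd) {
    v <- nd$v
    if (single) array(v, dim(v)[1:3]) else v
  })
  structure(list(maps = maps), class = "feature_pyramid")
}

# Coerce (H, W, C) or (H, W, C, N) input to a 4-D batch.
as_batch <- function(x, channels = NULL) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L, 4L))) {
    stop("expected an array with 2-4 dimensions", call. = FALSE)
  }
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (!is.null(channels) && dim(x)[3] != channels) {
    stop(sprintf("expected %d channel(s), got %d", channels, dim(x)[3]),
         call. = FALSE)
  }
  x
}
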