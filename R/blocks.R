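#' DenseASPP specification
#'
#' A densely connected atrous spatial pyramid: branch `i` (dilation `d_i`)
#' consumes the concatenation of the block input and all previous branch
#' outputs, and the final 1x1 projection fuses the input together with every
#' branch.  Each branch is a 1x1 reduction followed by a 3x3 dilated conv
#' (both conv -> batch norm -> ReLU, zero padding scaled by the dilation).
#'
#' Widths default to fractions of the bridge input `C`: reduction `C/8`,
#' branch growth `C/4`, projection output `C/2` — the scheme that keeps the
#' whole network at the intended parameter budget.
#'
#' @param dilation_rates Strictly increasing dilations; canonical
#'   `c(3, 6, 12, 18)`.
#' @param reduce_channels 1x1 reduction width per branch, or `NULL` for
#'   `C/8`; `0` drops the reduction layer.
#' @param branch_channels Dilated-conv output width per branch, or `NULL`
#'   for `C/4`.
#' @param out_channels Projection width, or `NULL` for `C/2`.
#' @return An object of class `dense_aspp_spec`.
#' @export
dense_aspp_spec <- function(dilation_rates = c(3L, 6L, 12L, 18L),
                            reduce_channels = NULL,
                            branch_channels = NULL,
                            out_channels = NULL) {
  if (length(dilation_rates) < 1L) {
    stop("dilation_rates must be non-empty", call. = FALSE)
  }
  if (any(dilation_rates < 1) ||
      (length(dilation_rates) > 1L && any(diff(dilation_rates) <= 0))) {
    stop("dilation_rates must be >= 1 and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(dilation_rates = as.integer(dilation_rates),
         reduce_channels = reduce_channels,
         branch_channels = branch_channels,
         out_channels = out_channels),
    class = "dense_aspp_spec"
  )
}

#' Build the DenseASPP bridge
#'
#' @param spec A [dense_aspp_spec()].
#' @param in_channels Channels `C` of the bridge input.
#' @return A module descriptor (class `dense_aspp`) with an `out_channels`
#'   field.
#' @export
build_dense_aspp <- function(spec, in_channels) {
  if (in_channels <= 0) stop("in_channels must be positive", call. = FALSE)
  C <- as.integer(in_channels)
  red <- spec$reduce_channels %||% max(2L, C %/% 8L)
  g <- spec$branch_channels %||% max(2L, C %/% 4L)
  outc <- spec$out_channels %||% max(2L, C %/% 2L)
  nb <- length(spec$dilation_rates)
  branches <- vector("list", nb)
  for (i in seq_len(nb)) {
    cin_i <- C + (i - 1L) * g
    d <- spec$dilation_rates[i]
    reduce <- if (red > 0L) {
      conv_layer(cin_i, red, k = 1L, name = sprintf("aspp.b%d.reduce", i))
    } else NULL
    dilated <- conv_layer(if (red > 0L) red else cin_i, g, k = 3L, dil = d,
                          name = sprintf("aspp.b%d.dil%d", i, d))
    branches[[i]] <- list(reduce = reduce, dilated = dilated)
  }
  project <- conv_layer(C + nb * g, outc, k = 1L, name = "aspp.project")
  structure(
    list(spec = spec, branches = branches, project = project,
         in_channels = C, branch_channels = g,
         out_channels = as.integer(outc)),
    class = c("dense_aspp", "list")
  )
}

dense_aspp_node <- function(mod, x, training = FALSE) {
  feats <- list(x)
  for (br in mod$branches) {
    h <- tg_concat(feats)
    if (!is.null(br$reduce)) h <- conv_forward(br$reduce, h, training)
    h <- conv_forward(br$dilated, h, training)
    feats <- c(feats, list(h))
  }
  conv_forward(mod$project, tg_concat(feats), training)
}

#' Apply the DenseASPP bridge to a feature map
#'
#' @param mod A [build_dense_aspp()] module.
#' @param x Numeric array `(H, W, C)` or batch `(H, W, C, N)`.
#' @return Array of the same spatial size with `mod$out_channels` channels.
#' @export
dense_aspp <- function(mod, x) {
  single <- length(dim(x)) == 3L
  out <- dense_aspp_node(mod, tg_leaf(as_batch(x)), training = FALSE)$v
  if (single) array(out, dim(out)[1:3]) else out
}

## ---- spatial attention -----------------------------------------------------

#' Spatial attention module
#'
#' Per-pixel reweighting: the feature map is pooled across channels with a
#' maximum and a mean, the two maps are concatenated, a 1x1 convolution plus
#' sigmoid yields a weight map in `(0, 1)` of shape `(H, W, 1)`, and the
#' input is multiplied by it (broadcast over channels).
#'
#' @param zero_init Start the 1x1 conv at zero (weights become exactly 0.5
#'   everywhere); useful for testing.
#' @return Module of class `spatial_attention` for [spatial_attention()].
#' @export
new_spatial_attention <- function(zero_init = FALSE) {
  conv <- conv_layer(2L, 1L, k = 1L, bias = TRUE, bn = FALSE, act = "none",
                     name = "satt.conv")
  if (zero_init) conv$W$value[] <- 0
  structure(list(conv = conv), class = c("spatial_attention", "list"))
}

spatial_attention_node <- function(mod, x, training = FALSE) {
  xm <- tg_chan_max(x)
  xa <- tg_chan_mean(x)
  w <- tg_sigmoid(conv_forward(mod$conv, tg_concat(list(xm, xa)), training))
  list(weights = w, out = tg_scale_spatial(x, w))
}

#' Apply spatial attention
#'
#' @param mod A [new_spatial_attention()] module.
#' @param x Numeric array `(H, W, C)` (or batch).
#' @return List with `weights` (`(H, W, 1)`, entries in `(0, 1)`) and `out`
#'   (same shape as `x`).
#' @export
spatial_attention <- function(mod, x) {
  single <- length(dim(x)) == 3L
  r <- spatial_attention_node(mod, tg_leaf(as_batch(x)))
  strip <- function(v) if (single) array(v, dim(v)[1:3]) else v
  list(weights = strip(r$weights$v), out = strip(r$out$v))
}

## ---- channel attention -----------------------------------------------------

#' Channel attention module
#'
#' Per-channel reweighting: global max- and average-pooled channel vectors
#' each pass through the same shared three-layer 1x1 bottleneck
#' `C -> C/8 -> C/8 -> C` (a linear chain, as specified), the two results
#' are concatenated and a 1x1 transform maps `2C -> C`; a sigmoid gives the
#' weight vector `(1, 1, C)` that rescales the input across space.
#'
#' The bottleneck width is `ceiling(C / reduction)` so degenerate small-`C`
#' inputs remain usable; the canonical reduction is 8.
#'
#' @param channels Input channel count `C`.
#' @param reduction Bottleneck reduction factor (default 8).
#' @param zero_init Zero all transforms (weights become exactly 0.5).
#' @return Module of class `channel_attention` for [channel_attention()].
#' @export
new_channel_attention <- function(channels, reduction = 8L,
                                  zero_init = FALSE) {
  C <- as.integer(channels)
  if (C < 1L) stop("channels must be positive", call. = FALSE)
  cr <- max(1L, as.integer(ceiling(C / reduction)))
  fc1 <- conv_layer(C, cr, k = 1L, bias = TRUE, bn = FALSE, act = "none",
                    name = "catt.fc1")
  fc2 <- conv_layer(cr, cr, k = 1L, bias = TRUE, bn = FALSE, act = "none",
                    name = "catt.fc2")
  fc3 <- conv_layer(cr, C, k = 1L, bias = TRUE, bn = FALSE, act = "none",
                    name = "catt.fc3")
  wf <- conv_layer(2L * C, C, k = 1L, bias = TRUE, bn = FALSE, act = "none",
                   name = "catt.wf")
  if (zero_init) {
    for (ly in list(fc1, fc2, fc3, wf)) ly$W$value[] <- 0
  }
  structure(list(fc1 = fc1, fc2 = fc2, fc3 = fc3, wf = wf,
                 channels = C, bottleneck = cr),
            class = c("channel_attention", "list"))
}

channel_attention_node <- function(mod, x, training = FALSE) {
  bottleneck <- function(v) {
    conv_forward(mod$fc3,
                 conv_forward(mod$fc2,
                              conv_forward(mod$fc1, v, training), training),
                 training)
  }
  x1 <- bottleneck(tg_gpool_max(x))
  x2 <- bottleneck(tg_gpool_avg(x))
  w <- tg_sigmoid(conv_forward(mod$wf, tg_concat(list(x1, x2)), training))
  list(weights = w, out = tg_scale_channel(x, w))
}

#' Apply channel attention
#'
#' @param mod A [new_channel_attention()] module.
#' @param x Numeric array `(H, W, C)` (or batch).
#' @return List with `weights` (`(1, 1, C)`, entries in `(0, 1)`) and `out`
#'   (same shape as `x`).
#' @export
channel_attention <- function(mod, x) {
  single <- length(dim(x)) == 3L
  r <- channel_attention_node(mod, tg_leaf(as_batch(x)))
  strip <- function(v) if (single) array(v, dim(v)[1:3]) else v
  list(weights = strip(r$weights$v), out = strip(r$out$v))
}

## ---- combined spatial-channel attention ------------------------------------

#' Spatial-channel attention (SCA) module
#'
#' Runs the spatial and channel attention branches on the same input,
#' concatenates the two attended tensors (`2C` channels) and fuses them back
#' to `C` channels with a 1x1 conv -> batch norm -> ReLU.
#'
#' @param channels Input channel count `C`.
#' @param reduction Channel-attention bottleneck reduction (default 8).
#' @return Module of class `sca_module` for [sca()].
#' @export
new_sca <- function(channels, reduction = 8L) {
  C <- as.integer(channels)
  structure(
    list(spatial = new_spatial_attention(),
         channel = new_channel_attention(C, reduction),
         fusion = conv_layer(2L * C, C, k = 1L, name = "sca.fuse"),
         channels = C),
    class = c("sca_module", "list")
  )
}

sca_node <- function(mod, x, training = FALSE) {
  s <- spatial_attention_node(mod$spatial, x, training)
  c <- channel_attention_node(mod$channel, x, training)
  conv_forward(mod$fusion, tg_concat(list(s$out, c$out)), training)
}

#' Apply the SCA module
#'
#' @param mod A [new_sca()] module.
#' @param x Numeric array `(H, W, C)` (or batch).
#' @return Array with the same shape as `x`.
#' @export
sca <- function(mod, x) {
  single <- length(dim(x)) == 3L
  out <- sca_node(mod, tg_leaf(as_batch(x)), training = FALSE)$v
  if (single) array(out, dim(out)[1:3]) else out
}
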