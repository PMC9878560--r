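# Parameters, composite conv layers and the Adam optimizer.

new_param <- function(value, name = "", trainable = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim(value) %||% length(value))
  p$name <- name
  p$trainable <- trainable
  p$m <- NULL
  p$v <- NULL
  class(p) <- "tg_param"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kaiming-uniform fan-in initialization (the conventional scheme for
# ReLU-activated conv stacks); draws from R's active RNG stream.
kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

# Conv -> [BatchNorm] -> [activation].  `pad` defaults to "same" padding for
# odd kernels (scaled by dilation).
conv_layer <- function(cin, cout, k = 3L, stride = 1L, dil = 1L,
                       pad = NULL, bias = !bn, bn = TRUE,
                       act = c("relu", "sigmoid", "none"),
                       name = "conv") {
  act <- match.arg(act)
  if (cin <= 0 || cout <= 0) {
    stop("conv_layer: channel counts must be positive", call. = FALSE)
  }
  if (is.null(pad)) pad <- (k %/% 2L) * dil
  ly <- new.env(parent = emptyenv())
  ly$W <- new_param(kaiming_uniform(c(k, k, cin, cout), k * k * cin),
                    name = paste0(name, ".W"))
  ly$b <- if (bias) {
    new_param(array(0, cout), name = paste0(name, ".b"))
  } else NULL
  ly$bn <- bn
  if (bn) {
    ly$gamma <- new_param(array(1, cout), name = paste0(name, ".gamma"))
    ly$beta <- new_param(array(0, cout), name = paste0(name, ".beta"))
    ly$running_mean <- numeric(cout)
    ly$running_var <- rep(1, cout)
    ly$momentum <- 0.1
    ly$eps <- 1e-5
  }
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad); ly$dil <- as.integer(dil)
  ly$act <- act
  ly$cin <- as.integer(cin); ly$cout <- as.integer(cout)
  ly$name <- name
  class(ly) <- "conv_layer"
  ly
}

conv_forward <- function(ly, x, training = FALSE) {
  y <- tg_conv2d(x, ly$W, ly$b, stride = ly$stride, pad = ly$pad,
                 dil = ly$dil)
  if (ly$bn) y <- tg_batchnorm(y, ly, training)
  switch(ly$act,
    relu = tg_relu(y),
    sigmoid = tg_sigmoid(y),
    none = y
  )
}

# Recursively gather every tg_param in a module tree (lists of lists of
# conv_layer environments, in construction order).
collect_params <- function(x) {
  if (inherits(x, "tg_param")) return(list(x))
  if (inherits(x, "conv_layer")) {
    out <- list(x$W)
    if (!is.null(x$b)) out <- c(out, list(x$b))
    if (isTRUE(x$bn)) out <- c(out, list(x$gamma, x$beta))
    return(out)
  }
  if (is.list(x)) {
    return(do.call(c, c(lapply(x, collect_params), list(list()))))
  }
  list()
}

n_params <- function(params) {
  sum(vapply(params, function(p) if (p$trainable) length(p$value) else 0L,
             numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# One Adam update over a parameter list; `state` carries the step counter.
adam_step <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (p in params) {
    if (!p$trainable) next
    if (is.null(p$m)) {
      p$m <- array(0, dim(p$value) %||% length(p$value))
      p$v <- p$m
    }
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

# Snapshot / restore parameter values and batch-norm running statistics, used
# to keep the best-validation checkpoint during training.
snapshot_weights <- function(model) {
  params <- lapply(collect_params(model), function(p) p$value)
  bns <- lapply(collect_bn_layers(model), function(ly) {
    list(mean = ly$running_mean, var = ly$running_var)
  })
  list(params = params, bn = bns)
}

restore_weights <- function(model, snap) {
  params <- collect_params(model)
  stopifnot(length(params) == length(snap$params))
  for (i in seq_along(params)) params[[i]]$value <- snap$params[[i]]
  bls <- collect_bn_layers(model)
  for (i in seq_along(bls)) {
    bls[[i]]$running_mean <- snap$bn[[i]]$mean
    bls[[i]]$running_var <- snap$bn[[i]]$var
  }
  invisible(model)
}

collect_bn_layers <- function(x) {
  if (inherits(x, "conv_layer")) {
    return(if (isTRUE(x$bn)) list(x) else list())
  }
  if (is.list(x)) {
    return(do.call(c, c(lapply(x, collect_bn_layers), list(list()))))
  }
  list()
}
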