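# Finite-difference validation of the reverse-mode tape.  Each op's analytic
# gradient is compared against central differences on small random tensors.

ns <- asNamespace("polypseg")

numgrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# analytic gradient of sum(w * op(x)) wrt x, via a parameter leaf
tape_grad <- function(op, x, wmask) {
  p <- ns$new_param(x)
  ns$tg_start_tape()
  out <- op(ns$tg_param_node(p))
  s <- ns$tg_node(sum(wmask * out$v), parents = out$id,
                  backfn = function(g) list(g * wmask))
  ns$tg_backward(s)
  ns$tg_stop_tape()
  p$grad
}

check_op <- function(op, d, tol = 1e-6) {
  x <- array(rnorm(prod(d)), d)
  out0 <- op(ns$tg_leaf(x))
  wmask <- array(rnorm(length(out0$v)), dim(out0$v))
  ana <- tape_grad(op, x, wmask)
  num <- numgrad(function(xx) sum(wmask * op(ns$tg_leaf(xx))$v), x)
  expect_equal(ana, num, tolerance = tol, ignore_attr = TRUE)
}

test_that("elementwise and pooling ops backpropagate exactly", {
  set.seed(81)
  check_op(ns$tg_relu, c(3, 4, 2, 2))
  check_op(ns$tg_sigmoid, c(3, 4, 2, 2))
  check_op(ns$tg_chan_max, c(3, 4, 5, 2))
  check_op(ns$tg_chan_mean, c(3, 4, 5, 2))
  check_op(ns$tg_gpool_max, c(3, 4, 5, 2))
  check_op(ns$tg_gpool_avg, c(3, 4, 5, 2))
  check_op(ns$tg_maxpool2, c(4, 6, 3, 2))
})

test_that("bilinear resampling backpropagates exactly both ways", {
  set.seed(82)
  check_op(function(x) ns$tg_resize(x, 6, 8), c(3, 4, 2, 2))
  check_op(function(x) ns$tg_resize(x, 2, 3), c(4, 6, 2, 2))
})

test_that("convolution gradients match finite differences for x, W and b", {
  set.seed(83)
  for (cfgs in list(list(k = 3, stride = 1, dil = 1),
                    list(k = 3, stride = 2, dil = 2),
                    list(k = 1, stride = 1, dil = 1))) {
    ly <- ns$conv_layer(3, 4, k = cfgs$k, stride = cfgs$stride,
                        dil = cfgs$dil, bias = TRUE, bn = FALSE,
                        act = "none")
    x <- array(rnorm(9 * 11 * 3 * 2), c(9, 11, 3, 2))
    run <- function(xx, Wv, bv) {
      oldW <- ly$W$value; oldb <- ly$b$value
      ly$W$value <- Wv; ly$b$value <- bv
      on.exit({ ly$W$value <- oldW; ly$b$value <- oldb })
      sum(wm * ns$conv_forward(ly, ns$tg_leaf(xx))$v)
    }
    out0 <- ns$conv_forward(ly, ns$tg_leaf(x))
    wm <- array(rnorm(length(out0$v)), dim(out0$v))
    px <- ns$new_param(x)
    ns$tg_start_tape()
    out <- ns$conv_forward(ly, ns$tg_param_node(px))
    s <- ns$tg_node(sum(wm * out$v), parents = out$id,
                    backfn = function(g) list(g * wm))
    ns$tg_backward(s)
    ns$tg_stop_tape()
    expect_equal(px$grad, numgrad(function(xx) run(xx, ly$W$value,
                                                   ly$b$value), x),
                 tolerance = 1e-6)
    expect_equal(ly$W$grad, numgrad(function(W) run(x, W, ly$b$value),
                                    ly$W$value),
                 tolerance = 1e-6)
    expect_equal(as.vector(ly$b$grad),
                 as.vector(numgrad(function(b) run(x, ly$W$value, b),
                                   ly$b$value)),
                 tolerance = 1e-6)
  }
})

test_that("batch normalization backpropagates through batch statistics", {
  set.seed(84)
  ly <- ns$conv_layer(3, 3, k = 1, bn = TRUE, act = "none")
  ly$W$value <- array(0, dim(ly$W$value))
  for (i in 1:3) ly$W$value[1, 1, i, i] <- 1 # identity 1x1 conv
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  run <- function(xx) {
    rm0 <- ly$running_mean; rv0 <- ly$running_var
    out <- ns$tg_batchnorm(ns$tg_conv2d(ns$tg_leaf(xx), ly$W), ly,
                           training = TRUE)
    ly$running_mean <- rm0; ly$running_var <- rv0
    sum(wm * out$v)
  }
  out0 <- ns$tg_batchnorm(ns$tg_conv2d(ns$tg_leaf(x), ly$W), ly, TRUE)
  wm <- array(rnorm(length(out0$v)), dim(out0$v))
  px <- ns$new_param(x)
  ns$tg_start_tape()
  out <- ns$tg_batchnorm(ns$tg_conv2d(ns$tg_param_node(px), ly$W), ly,
                         training = TRUE)
  s <- ns$tg_node(sum(wm * out$v), parents = out$id,
                  backfn = function(g) list(g * wm))
  ns$tg_backward(s)
  ns$tg_stop_tape()
  expect_equal(px$grad, numgrad(run, x), tolerance = 1e-5)
})

test_that("a full attention module backpropagates as one composite", {
  set.seed(85)
  mod <- ns$new_sca(8)
  # well-separated distinct inputs: the module contains max selections whose
  # argmax must not flip under the finite-difference perturbation
  d <- c(4, 4, 8, 2)
  x <- array((sample(prod(d)) / prod(d) - 0.5) * 4, d)
  op <- function(xx) ns$sca_node(mod, xx, training = FALSE)
  out0 <- op(ns$tg_leaf(x))
  wm <- array(rnorm(length(out0$v)), dim(out0$v))
  ana <- tape_grad(op, x, wm)
  num <- numgrad(function(xx) sum(wm * op(ns$tg_leaf(xx))$v), x)
  expect_equal(ana, num, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("shared parameters accumulate gradients from every use", {
  set.seed(86)
  # the channel-attention bottleneck runs twice (max- and avg-pooled paths);
  # its weight gradient must be the sum of both contributions
  att <- ns$new_channel_attention(8)
  x <- array(rnorm(5 * 5 * 8), c(5, 5, 8, 1))
  run_w <- function(Wv) {
    old <- att$fc1$W$value
    att$fc1$W$value <- Wv
    on.exit(att$fc1$W$value <- old)
    r <- ns$channel_attention_node(att, ns$tg_leaf(x))
    sum(wm * r$out$v)
  }
  r0 <- ns$channel_attention_node(att, ns$tg_leaf(x))
  wm <- array(rnorm(length(r0$out$v)), dim(r0$out$v))
  ns$zero_grads(list(att$fc1$W))
  ns$tg_start_tape()
  r <- ns$channel_attention_node(att, ns$tg_leaf(x))
  s <- ns$tg_node(sum(wm * r$out$v), parents = r$out$id,
                  backfn = function(g) list(g * wm))
  ns$tg_backward(s)
  ns$tg_stop_tape()
  expect_equal(att$fc1$W$grad, numgrad(run_w, att$fc1$W$value),
               tolerance = 1e-6)
})

test_that("ops run value-only when no tape is active", {
  set.seed(87)
  x <- array(rnorm(24), c(2, 3, 4, 1))
  expect_false(ns$tg_recording())
  y <- ns$tg_relu(ns$tg_leaf(x))
  expect_true(is.na(y$id))
  expect_equal(y$v, pmax(x, 0), ignore_attr = TRUE)
})
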