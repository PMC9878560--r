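test_that("dense_aspp wires branches densely and preserves spatial size", {
  mod <- build_dense_aspp(dense_aspp_spec(), in_channels = 64)
  g <- mod$branch_channels
  expect_equal(g, 16) # C/4
  # branch i consumes the input plus all previous branch outputs
  for (i in 1:4) {
    expect_equal(mod$branches[[i]]$reduce$cin, 64 + (i - 1) * g)
  }
  expect_equal(mod$project$cin, 64 + 4 * g)
  x <- array(rnorm(24 * 20 * 64), c(24, 20, 64))
  y <- dense_aspp(mod, x)
  expect_equal(dim(y), c(24, 20, mod$out_channels))
  expect_error(dense_aspp_spec(dilation_rates = integer(0)), "non-empty")
  expect_error(dense_aspp_spec(dilation_rates = c(6, 3)), "increasing")
})

test_that("a single-branch dilation-1 pyramid degenerates to a plain conv bridge", {
  spec <- dense_aspp_spec(dilation_rates = 1L, reduce_channels = 0L,
                          branch_channels = 8L, out_channels = 8L)
  mod <- build_dense_aspp(spec, in_channels = 4)
  expect_length(mod$branches, 1L)
  expect_null(mod$branches[[1]]$reduce)
  expect_equal(mod$branches[[1]]$dilated$k, 3L)
  expect_equal(mod$branches[[1]]$dilated$dil, 1L)
  y <- dense_aspp(mod, array(rnorm(10 * 10 * 4), c(10, 10, 4)))
  expect_equal(dim(y), c(10, 10, 8))
})

test_that("constant input maps to a constant output away from padding edges", {
  # zero padding perturbs a border of width dilation; interiors stay flat
  mod <- build_dense_aspp(dense_aspp_spec(dilation_rates = c(1L, 2L)),
                          in_channels = 8)
  x <- array(0.7, c(20, 20, 8))
  y <- dense_aspp(mod, x)
  inner <- y[8:13, 8:13, , drop = FALSE]
  for (c in seq_len(dim(inner)[3])) {
    expect_lt(diff(range(inner[, , c])), 1e-10)
  }
})

test_that("spatial attention computes sigmoid-bounded per-pixel weights", {
  set.seed(5)
  att <- new_spatial_attention()
  x <- array(rnorm(12 * 10 * 6), c(12, 10, 6))
  r <- spatial_attention(att, x)
  expect_equal(dim(r$weights), c(12, 10, 1))
  expect_equal(dim(r$out), dim(x))
  expect_true(all(r$weights > 0 & r$weights < 1))
  # sigmoid weights < 1 shrink every entry
  expect_true(all(abs(r$out) <= abs(x)))
  # constant input -> constant weight map
  rc <- spatial_attention(att, array(0.3, c(6, 6, 4)))
  expect_lt(diff(range(rc$weights)), 1e-12)
})

test_that("zero-initialized spatial attention halves its input", {
  att <- new_spatial_attention(zero_init = TRUE)
  x <- array(0, c(5, 5, 3))
  x[3, 3, 2] <- 4 # single hot pixel
  r <- spatial_attention(att, x)
  expect_equal(as.vector(r$weights), rep(0.5, 25))
  expect_equal(r$out, 0.5 * x)
})

test_that("spatial attention is translation equivariant", {
  # every op in the branch is pointwise over pixels, so a circular shift of
  # the input must shift weights and output exactly
  set.seed(6)
  att <- new_spatial_attention()
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  sh <- function(a, s) a[c((s + 1):8, 1:s), , , drop = FALSE]
  r1 <- spatial_attention(att, x)
  r2 <- spatial_attention(att, sh(x, 3))
  expect_equal(r2$weights, sh(r1$weights, 3), tolerance = 1e-12)
  expect_equal(r2$out, sh(r1$out, 3), tolerance = 1e-12)
})

test_that("channel attention shapes, bounds and bottleneck widths", {
  set.seed(7)
  att <- new_channel_attention(16)
  expect_equal(att$bottleneck, 2) # C/8
  expect_equal(dim(att$fc1$W$value)[3:4], c(16, 2))
  expect_equal(dim(att$fc2$W$value)[3:4], c(2, 2))
  expect_equal(dim(att$fc3$W$value)[3:4], c(2, 16))
  expect_equal(dim(att$wf$W$value)[3:4], c(32, 16))
  x <- array(rnorm(6 * 6 * 16), c(6, 6, 16))
  r <- channel_attention(att, x)
  expect_equal(dim(r$weights), c(1, 1, 16))
  expect_true(all(r$weights > 0 & r$weights < 1))
  expect_equal(dim(r$out), dim(x))
  # C not divisible by 8 falls back to ceiling(C/8)
  expect_equal(new_channel_attention(12)$bottleneck, 2)
  expect_equal(new_channel_attention(4)$bottleneck, 1)
})

test_that("channel attention treats identical channels identically", {
  # permutation symmetry of the mechanism: with channel-symmetric transforms
  # (zero-initialized weights, shared biases) equal channels must receive
  # equal weights and remain equal on output
  set.seed(8)
  att <- new_channel_attention(8, zero_init = TRUE)
  att$fc1$b$value[] <- 0.3
  att$fc2$b$value[] <- -0.1
  att$fc3$b$value[] <- 0.2
  att$wf$b$value[] <- 0.4
  plane <- matrix(rnorm(36), 6, 6)
  x <- array(rep(plane, 8), c(6, 6, 8))
  r <- channel_attention(att, x)
  expect_lt(diff(range(r$weights)), 1e-12)
  for (c in 2:8) expect_equal(r$out[, , c], r$out[, , 1])
})

test_that("zero-initialized channel attention halves its input", {
  att <- new_channel_attention(8, zero_init = TRUE)
  x <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  r <- channel_attention(att, x)
  expect_equal(as.vector(r$weights), rep(0.5, 8))
  expect_equal(r$out, 0.5 * x, tolerance = 1e-12)
})

test_that("channel attention is equivariant under coherent channel permutation", {
  # permuting the input channels together with the module's weight tensors
  # must permute the weight vector and the output
  set.seed(9)
  C <- 8
  att <- new_channel_attention(C)
  perm <- sample(C)
  att2 <- new_channel_attention(C)
  att2$fc1$W$value <- att$fc1$W$value[, , perm, , drop = FALSE]
  att2$fc1$b$value <- att$fc1$b$value
  att2$fc2$W$value <- att$fc2$W$value
  att2$fc2$b$value <- att$fc2$b$value
  att2$fc3$W$value <- att$fc3$W$value[, , , perm, drop = FALSE]
  att2$fc3$b$value <- att$fc3$b$value[perm]
  att2$wf$W$value <- att$wf$W$value[, , c(perm, C + perm), perm, drop = FALSE]
  att2$wf$b$value <- att$wf$b$value[perm]
  x <- array(rnorm(6 * 6 * C), c(6, 6, C))
  r1 <- channel_attention(att, x)
  r2 <- channel_attention(att2, x[, , perm, drop = FALSE])
  expect_equal(as.vector(r2$weights), as.vector(r1$weights)[perm],
               tolerance = 1e-12)
  expect_equal(r2$out, r1$out[, , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("sca preserves shape and annihilates a zero input", {
  set.seed(10)
  mod <- new_sca(8)
  x <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  y <- sca(mod, x)
  expect_equal(dim(y), dim(x))
  # both attended branches vanish on zero input; fusion has no bias and its
  # freshly initialized batch norm is the identity
  expect_equal(sca(mod, array(0, c(6, 6, 8))), array(0, c(6, 6, 8)))
})

test_that("attention weights stay strictly inside (0, 1) on random tensors", {
  set.seed(11)
  for (rep in 1:5) {
    C <- sample(c(4, 8, 16), 1)
    x <- array(rnorm(7 * 7 * C, sd = 3), c(7, 7, C))
    rs <- spatial_attention(new_spatial_attention(), x)
    rc <- channel_attention(new_channel_attention(C), x)
    expect_true(all(rs$weights > 0 & rs$weights < 1))
    expect_true(all(rc$weights > 0 & rc$weights < 1))
  }
})
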