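# Reverse-mode automatic differentiation on dense arrays.
#
# All activations are column-major arrays laid out (H, W, C, N).  A "node" is
# a plain list holding the forward value (`v`) and, while a tape is active,
# an integer id into the tape.  Operations append nodes whose `backfn`
# closures map the output gradient to gradients for each parent.  With no
# tape active (inference) the same ops run value-only and allocate nothing
# extra.

.tg <- new.env(parent = emptyenv())
.tg$tape <- NULL

tg_recording <- function() !is.null(.tg$tape)

tg_start_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .tg$tape <- tp
  invisible(tp)
}

tg_stop_tape <- function() {
  .tg$tape <- NULL
  invisible(NULL)
}

# Record a node. `backfn(grad)` must return a list of gradients aligned with
# `parents`; NULL entries mean "no gradient flows there".
tg_node <- function(value, parents = integer(0), backfn = NULL, param = NULL) {
  if (!tg_recording()) {
    return(list(v = value, id = NA_integer_))
  }
  tp <- .tg$tape
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- list(
    parents = parents, backfn = backfn, param = param
  )
  list(v = value, id = tp$n)
}

tg_leaf <- function(x) {
  if (is.list(x) && !is.null(x$v)) x else list(v = x, id = NA_integer_)
}

# Wrap a parameter (see new_param) as a tape leaf; gradients reaching it are
# accumulated into param$grad.  A parameter used twice in one forward pass
# (e.g. the shared attention bottleneck) gets two leaves, both of which add
# into the same accumulator.
tg_param_node <- function(param) {
  tg_node(param$value, parents = integer(0), backfn = NULL, param = param)
}

# Backpropagate from a scalar (or seeded) node through the active tape.
tg_backward <- function(node, seed = 1) {
  tp <- .tg$tape
  if (is.null(tp)) stop("tg_backward() called with no active tape", call. = FALSE)
  if (is.na(node$id)) stop("node was not recorded on the tape", call. = FALSE)
  grads <- vector("list", node$id)
  grads[[node$id]] <- seed
  for (i in seq.int(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (!is.null(nd$param)) {
      p <- nd$param
      gp <- as.numeric(g)
      dim(gp) <- dim(p$value)
      p$grad <- p$grad + gp
      grads[i] <- list(NULL)
      next
    }
    if (!is.null(nd$backfn)) {
      pg <- nd$backfn(g)
      for (k in seq_along(nd$parents)) {
        j <- nd$parents[[k]]
        if (is.na(j)) next
        gk <- pg[[k]]
        if (is.null(gk)) next
        grads[[j]] <- if (is.null(grads[[j]])) gk else grads[[j]] + gk
      }
    }
    grads[i] <- list(NULL)
  }
  invisible(NULL)
}

## ---- elementwise ops -------------------------------------------------------

tg_relu <- function(x) {
  v <- pmax(x$v, 0)
  dim(v) <- dim(x$v)
  mask <- x$v > 0
  tg_node(v, parents = x$id, backfn = function(g) list(g * mask))
}

tg_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$v))
  # keep outputs strictly inside (0, 1): the true sigmoid never reaches the
  # endpoints, but doubles saturate for |z| > ~37
  v <- pmin(pmax(v, 1e-12), 1 - 1e-12)
  dim(v) <- dim(x$v)
  tg_node(v, parents = x$id, backfn = function(g) list(g * v * (1 - v)))
}

tg_add <- function(a, b) {
  tg_node(a$v + b$v, parents = c(a$id, b$id),
          backfn = function(g) list(g, g))
}

tg_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  tg_node(av * bv, parents = c(a$id, b$id),
          backfn = function(g) list(g * bv, g * av))
}

## ---- shape helpers ---------------------------------------------------------

# Sum a (HW x C*N) matrix down to one value per channel.
per_channel_sum <- function(m, C, N) {
  rowSums(matrix(colSums(m), C, N))
}

# Broadcast a length-C vector over an (H, W, C, N) volume (flat vector out).
bcast_channel <- function(v, HW, N) {
  rep(rep(v, each = HW), times = N)
}

## ---- concatenation along channels -----------------------------------------

tg_concat <- function(xs) {
  if (length(xs) == 1L) return(xs[[1L]])
  dims <- lapply(xs, function(x) dim(x$v))
  d1 <- dims[[1L]]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  Ctot <- sum(cs)
  out <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  off <- 0L
  for (x in xs) {
    ci <- dim(x$v)[3]
    out[, , (off + 1L):(off + ci), ] <- x$v
    off <- off + ci
  }
  ends <- cumsum(cs)
  starts <- ends - cs + 1L
  tg_node(out, parents = vapply(xs, function(x) x$id, integer(1)),
          backfn = function(g) {
            lapply(seq_along(cs), function(k) {
              g[, , starts[k]:ends[k], , drop = FALSE]
            })
          })
}

## ---- pooling over channels (per pixel) -------------------------------------

tg_chan_max <- function(x) {
  d <- dim(x$v)
  C <- d[3]
  v <- x$v[, , 1L, , drop = FALSE]
  idx <- array(1L, dim(v))
  if (C > 1L) {
    for (c in 2:C) {
      xc <- x$v[, , c, , drop = FALSE]
      upd <- xc > v
      v[upd] <- xc[upd]
      idx[upd] <- c
    }
  }
  HW <- d[1] * d[2]
  tg_node(v, parents = x$id, backfn = function(g) {
    dx <- array(0, d)
    hw <- rep.int(seq_len(HW), d[4])
    nn <- rep(seq_len(d[4]), each = HW)
    lin <- hw + HW * (as.vector(idx) - 1L) + HW * C * (nn - 1L)
    dx[lin] <- as.vector(g)
    list(dx)
  })
}

tg_chan_mean <- function(x) {
  d <- dim(x$v)
  C <- d[3]
  HW <- d[1] * d[2]
  arr <- array(x$v, c(HW, C, d[4]))
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4])) {
    v[, , 1L, n] <- rowMeans(arr[, , n, drop = FALSE], dims = 1L)
  }
  tg_node(v, parents = x$id, backfn = function(g) {
    gx <- as.vector(g) / C
    dx <- array(0, d)
    for (c in seq_len(C)) dx[, , c, ] <- gx
    list(dx)
  })
}

## ---- global spatial pooling (per channel) ----------------------------------

tg_gpool_max <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  m <- matrix(x$v, HW, d[3] * d[4])
  j <- max.col(t(m), ties.method = "first")
  cols <- seq_len(ncol(m))
  vals <- m[cbind(j, cols)]
  v <- array(vals, c(1L, 1L, d[3], d[4]))
  tg_node(v, parents = x$id, backfn = function(g) {
    dx <- numeric(length(x$v))
    dx[j + HW * (cols - 1L)] <- as.vector(g)
    dim(dx) <- d
    list(dx)
  })
}

tg_gpool_avg <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  m <- matrix(x$v, HW, d[3] * d[4])
  v <- array(colMeans(m), c(1L, 1L, d[3], d[4]))
  tg_node(v, parents = x$id, backfn = function(g) {
    dx <- matrix(as.vector(g) / HW, HW, d[3] * d[4], byrow = TRUE)
    dim(dx) <- d
    list(dx)
  })
}

## ---- broadcast scaling (the attention reweightings) ------------------------

# x: (H, W, C, N) scaled by a per-pixel map s: (H, W, 1, N)
tg_scale_spatial <- function(x, s) {
  d <- dim(x$v)
  C <- d[3]
  sfull <- s$v[, , rep(1L, C), , drop = FALSE]
  xv <- x$v
  tg_node(xv * sfull, parents = c(x$id, s$id), backfn = function(g) {
    t <- g * xv
    HW <- d[1] * d[2]
    ds <- array(0, c(d[1], d[2], 1L, d[4]))
    for (n in seq_len(d[4])) {
      ds[, , 1L, n] <- rowSums(matrix(t[, , , n], HW, C))
    }
    list(g * sfull, ds)
  })
}

# x: (H, W, C, N) scaled by a per-channel vector s: (1, 1, C, N)
tg_scale_channel <- function(x, s) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  sfull <- array(rep(as.vector(s$v), each = HW), d)
  xv <- x$v
  tg_node(xv * sfull, parents = c(x$id, s$id), backfn = function(g) {
    t <- g * xv
    ds <- array(colSums(matrix(t, HW, d[3] * d[4])), c(1L, 1L, d[3], d[4]))
    list(g * sfull, ds)
  })
}

## ---- spatial ops backed by compiled kernels --------------------------------

tg_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  d <- dim(x$v)
  kd <- dim(W$value)
  kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  stopifnot(d[3] == cin)
  Ho <- (d[1] + 2L * pad - dil * (kh - 1L) - 1L) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - dil * (kw - 1L) - 1L) %/% stride + 1L
  pointwise <- kh == 1L && kw == 1L && stride == 1L && pad == 0L
  if (pointwise) {
    cols <- matrix(aperm(x$v, c(3, 1, 2, 4)), cin, d[1] * d[2] * d[4])
  } else {
    cols <- im2col_cpp(x$v, d[1], d[2], d[3], d[4], kh, kw,
                       as.integer(stride), as.integer(pad), as.integer(dil))
  }
  Wmat <- matrix(W$value, kh * kw * cin, cout)
  Y <- crossprod(Wmat, cols)
  if (!is.null(b)) Y <- Y + as.vector(b$value)
  out <- aperm(array(Y, c(cout, Ho, Wo, d[4])), c(2, 3, 1, 4))
  if (!tg_recording()) return(list(v = out, id = NA_integer_))
  pw <- tg_param_node(W)
  pb <- if (!is.null(b)) tg_param_node(b) else NULL
  parents <- c(x$id, pw$id, if (!is.null(pb)) pb$id)
  tg_node(out, parents = parents, backfn = function(g) {
    gmat <- matrix(aperm(g, c(3, 1, 2, 4)), cout, Ho * Wo * d[4])
    dW <- tcrossprod(cols, gmat)
    dim(dW) <- kd
    dcols <- Wmat %*% gmat
    if (pointwise) {
      dx <- aperm(array(dcols, c(cin, d[1], d[2], d[4])), c(2, 3, 1, 4))
    } else {
      dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], kh, kw,
                       as.integer(stride), as.integer(pad), as.integer(dil))
    }
    out <- list(dx, dW)
    if (!is.null(pb)) out <- c(out, list(array(rowSums(gmat), dim(b$value))))
    out
  })
}

tg_maxpool2 <- function(x) {
  d <- dim(x$v)
  r <- maxpool2_cpp(x$v, d[1], d[2], d[3], d[4])
  tg_node(r$y, parents = x$id, backfn = function(g) {
    dx <- numeric(length(x$v))
    dx[r$idx] <- as.vector(g)
    dim(dx) <- d
    list(dx)
  })
}

tg_resize <- function(x, Ho, Wo) {
  d <- dim(x$v)
  if (d[1] == Ho && d[2] == Wo) return(x)
  v <- bilinear_resize_cpp(x$v, d[1], d[2], d[3], d[4],
                           as.integer(Ho), as.integer(Wo))
  tg_node(v, parents = x$id, backfn = function(g) {
    list(bilinear_resize_bwd_cpp(g, d[1], d[2], d[3], d[4],
                                 as.integer(Ho), as.integer(Wo)))
  })
}

## ---- batch normalization ---------------------------------------------------

tg_batchnorm <- function(x, ly, training) {
  d <- dim(x$v)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Nn <- HW * N
  xm <- matrix(x$v, HW, C * N)
  if (training) {
    mu <- per_channel_sum(xm, C, N) / Nn
    vr <- per_channel_sum(xm * xm, C, N) / Nn - mu^2
    vr <- pmax(vr, 0)
    mom <- ly$momentum
    ly$running_mean <- (1 - mom) * ly$running_mean + mom * mu
    ly$running_var <- (1 - mom) * ly$running_var +
      mom * vr * Nn / max(Nn - 1, 1)
  } else {
    mu <- ly$running_mean
    vr <- ly$running_var
  }
  inv <- 1 / sqrt(vr + ly$eps)
  xhat <- (xm - bcast_channel(mu, HW, N)) * bcast_channel(inv, HW, N)
  gam <- ly$gamma$value
  y <- xhat * bcast_channel(gam, HW, N) + bcast_channel(ly$beta$value, HW, N)
  dim(y) <- d
  if (!tg_recording()) return(list(v = y, id = NA_integer_))
  pg <- tg_param_node(ly$gamma)
  pb <- tg_param_node(ly$beta)
  tg_node(y, parents = c(x$id, pg$id, pb$id), backfn = function(g) {
    gm <- matrix(g, HW, C * N)
    dgamma <- per_channel_sum(gm * xhat, C, N)
    dbeta <- per_channel_sum(gm, C, N)
    dxhat <- gm * bcast_channel(gam, HW, N)
    if (training) {
      s1 <- per_channel_sum(dxhat, C, N)
      s2 <- per_channel_sum(dxhat * xhat, C, N)
      dx <- (dxhat - bcast_channel(s1 / Nn, HW, N) -
               xhat * bcast_channel(s2 / Nn, HW, N)) *
        bcast_channel(inv, HW, N)
    } else {
      dx <- dxhat * bcast_channel(inv, HW, N)
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}
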