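# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Every tensor is an environment holding a value, an (accumulated) gradient and
# a backward closure. Nodes are created in topological order, so the reverse
# sweep simply walks ids downwards. Gradients are plain arrays with the same
# dim as the value. The engine is deliberately small: only the operations the
# segmentation network needs are implemented, each with an analytic backward
# that is verified against finite differences in the test suite.

.ag_env <- new.env(parent = emptyenv())
.ag_env$next_id <- 1L

new_ag <- function(value, requires = FALSE, parents = list(), backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires <- requires
  node$parents <- parents
  node$backfn <- backfn
  node$id <- .ag_env$next_id
  .ag_env$next_id <- .ag_env$next_id + 1L
  class(node) <- "ag_tensor"
  node
}

#' Wrap a plain array as a constant tensor
#'
#' Constants take part in forward computation but receive no gradient.
#'
#' @param value numeric array / matrix / vector.
#' @return an `ag_tensor` node.
#' @export
ag_const <- function(value) new_ag(value)

#' Wrap a plain array as a trainable parameter tensor
#'
#' @param value numeric array holding the initial parameter values.
#' @return an `ag_tensor` node with gradient tracking enabled.
#' @export
ag_param <- function(value) new_ag(value, requires = TRUE)

#' Test whether an object is an autodiff tensor
#' @param x object.
#' @return logical.
#' @export
is_ag <- function(x) inherits(x, "ag_tensor")

#' Extract the plain array value of a tensor
#' @param x an `ag_tensor` or plain array (returned unchanged).
#' @return numeric array.
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor ", if (is.null(d)) paste0("len ", length(x$value)) else paste(d, collapse = "x"),
      if (x$requires) " grad" else "", ">\n", sep = "")
  invisible(x)
}

ag_op <- function(value, parents, backfn) {
  req <- FALSE
  for (p in parents) if (p$requires) { req <- TRUE; break }
  new_ag(value, requires = req, parents = parents, backfn = if (req) backfn else NULL)
}

#' Reverse-mode sweep from a root tensor
#'
#' Accumulates gradients into every upstream tensor that requires them
#' (parameters and the intermediates connecting them to the root).
#'
#' @param root the tensor to differentiate (typically a scalar loss).
#' @param seed_grad optional seed gradient; defaults to ones.
#' @return the root, invisibly.
#' @export
ag_backward <- function(root, seed_grad = NULL) {
  if (is.null(seed_grad)) {
    seed_grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  }
  root$grad <- if (is.null(root$grad)) seed_grad else root$grad + seed_grad
  # collect reachable subgraph
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 256L); n <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n <- n + 1L
    if (n > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n]] <- nd
    for (p in nd$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n)]
  ids <- vapply(nodes, function(nd) nd$id, 1L)
  for (nd in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (p$requires && !is.null(gs[[i]])) {
        p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
      }
    }
  }
  invisible(root)
}

#' Clear accumulated gradients on a set of tensors
#' @param params list of `ag_tensor`s.
#' @return invisibly, the list.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value + b$value, list(a, b), function(nd) list(nd$grad, nd$grad))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$value - b$value, list(a, b), function(nd) list(nd$grad, -nd$grad))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(nd) list(nd$grad * bv, nd$grad * av))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_op(av / bv, list(a, b),
        function(nd) list(nd$grad / bv, -nd$grad * av / (bv * bv)))
}

ag_add_const <- function(a, c) ag_op(a$value + c, list(a), function(nd) list(nd$grad))

ag_mul_const <- function(a, c) ag_op(a$value * c, list(a), function(nd) list(nd$grad * c))

ag_neg <- function(a) ag_mul_const(a, -1)

## ---- reductions ------------------------------------------------------------

ag_sum <- function(a) {
  d <- if (is.null(dim(a$value))) length(a$value) else dim(a$value)
  ag_op(sum(a$value), list(a), function(nd) list(array(nd$grad, dim = d)))
}

ag_mean <- function(a) {
  n <- length(a$value)
  d <- if (is.null(dim(a$value))) n else dim(a$value)
  ag_op(sum(a$value) / n, list(a), function(nd) list(array(nd$grad / n, dim = d)))
}

## ---- nonlinearities --------------------------------------------------------

ag_relu <- function(a) {
  m <- a$value > 0
  ag_op(a$value * m, list(a), function(nd) list(nd$grad * m))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  v <- a$value
  y <- ifelse(v > 0, v, slope * v)
  if (!is.null(dim(v))) dim(y) <- dim(v)
  ag_op(y, list(a), function(nd) {
    dm <- ifelse(v > 0, 1, slope)
    list(nd$grad * dm)
  })
}

ag_elu <- function(a, alpha = 1) {
  v <- a$value
  y <- ifelse(v > 0, v, alpha * (exp(v) - 1))
  if (!is.null(dim(v))) dim(y) <- dim(v)
  ag_op(y, list(a), function(nd) {
    dm <- ifelse(v > 0, 1, y + alpha)
    list(nd$grad * dm)
  })
}

ag_gelu <- function(a) {
  v <- a$value
  ph <- stats::pnorm(v)
  y <- v * ph
  if (!is.null(dim(v))) dim(y) <- dim(v)
  ag_op(y, list(a), function(nd) list(nd$grad * (ph + v * stats::dnorm(v))))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ag_op(y, list(a), function(nd) list(nd$grad * y * (1 - y)))
}

ag_log <- function(a) {
  v <- a$value
  ag_op(log(v), list(a), function(nd) list(nd$grad / v))
}

ag_abs <- function(a) {
  v <- a$value
  ag_op(abs(v), list(a), function(nd) list(nd$grad * sign(v)))
}

ag_clamp <- function(a, lo, hi) {
  v <- a$value
  y <- pmin(pmax(v, lo), hi)
  if (!is.null(dim(v))) dim(y) <- dim(v)
  ag_op(y, list(a), function(nd) {
    m <- (v >= lo) & (v <= hi)
    list(nd$grad * m)
  })
}

## ---- shape manipulation ----------------------------------------------------

ag_reshape <- function(a, d) {
  od <- dim(a$value)
  v <- a$value
  dim(v) <- d
  ag_op(v, list(a), function(nd) {
    g <- nd$grad
    dim(g) <- od
    list(g)
  })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  ag_op(aperm(a$value, perm), list(a), function(nd) list(aperm(nd$grad, inv)))
}

# concatenate 4D tensors along the channel axis (dim 2)
ag_concat_ch <- function(xs) {
  xs <- lapply(xs, as_ag)
  dims <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(dims, function(d) d[2], 1)
  d0 <- dims[[1]]
  out <- array(0, c(d0[1], sum(cs), d0[3], d0[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, off + seq_len(cs[i]), , ] <- xs[[i]]$value
    off <- off + cs[i]
  }
  ag_op(out, xs, function(nd) {
    g <- nd$grad
    res <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, off + seq_len(cs[i]), , , drop = FALSE]
      off <- off + cs[i]
    }
    res
  })
}

# column-bind matrices (used to concatenate attention heads)
ag_cbind <- function(xs) {
  xs <- lapply(xs, as_ag)
  ncols <- vapply(xs, function(x) ncol(x$value), 1L)
  out <- do.call(cbind, lapply(xs, ag_value))
  ag_op(out, xs, function(nd) {
    g <- nd$grad
    res <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, off + seq_len(ncols[i]), drop = FALSE]
      off <- off + ncols[i]
    }
    res
  })
}

# extract batch element b of a (B, N, D) tensor as an N x D matrix
ag_slice_b <- function(z, b) {
  d <- dim(z$value)
  v <- z$value[b, , , drop = FALSE]
  dim(v) <- d[2:3]
  ag_op(v, list(z), function(nd) {
    g <- array(0, d)
    g[b, , ] <- nd$grad
    list(g)
  })
}

# stack B matrices (N x D) into a (B, N, D) tensor
ag_stack_b <- function(xs) {
  xs <- lapply(xs, as_ag)
  B <- length(xs)
  nd2 <- dim(xs[[1]]$value)
  out <- array(0, c(B, nd2[1], nd2[2]))
  for (b in seq_len(B)) out[b, , ] <- xs[[b]]$value
  ag_op(out, xs, function(nd) {
    g <- nd$grad
    lapply(seq_len(B), function(b) {
      gb <- g[b, , , drop = FALSE]
      dim(gb) <- nd2
      gb
    })
  })
}

## ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_op(av %*% bv, list(a, b), function(nd) {
    g <- nd$grad
    list(g %*% t(bv), crossprod(av, g))
  })
}

ag_t <- function(a) ag_op(t(a$value), list(a), function(nd) list(t(nd$grad)))

# tokens (B, N, D) times weight (D, D2) plus optional bias (D2)
ag_linear3 <- function(z, w, b = NULL) {
  d <- dim(z$value)
  zm <- matrix(z$value, nrow = d[1] * d[2])
  wv <- w$value
  ym <- zm %*% wv
  if (!is.null(b)) ym <- t(t(ym) + b$value)
  out <- array(ym, c(d[1], d[2], ncol(wv)))
  parents <- if (is.null(b)) list(z, w) else list(z, w, b)
  ag_op(out, parents, function(nd) {
    g <- matrix(nd$grad, nrow = d[1] * d[2])
    dz <- array(g %*% t(wv), d)
    dw <- crossprod(zm, g)
    if (is.null(b)) list(dz, dw) else list(dz, dw, colSums(g))
  })
}

# add a learned (N, D) table to every batch element of (B, N, D)
ag_add_tokens <- function(z, p) {
  d <- dim(z$value)
  pv <- p$value
  pb <- aperm(array(pv, c(d[2], d[3], d[1])), c(3, 1, 2))
  ag_op(z$value + pb, list(z, p), function(nd) {
    g <- nd$grad
    dp <- matrix(colSums(matrix(g, nrow = d[1])), d[2], d[3])
    list(g, dp)
  })
}

# softmax over the rows of a matrix
ag_softmax_rows <- function(a) {
  v <- a$value
  m <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - m)
  y <- e / rowSums(e)
  ag_op(y, list(a), function(nd) {
    g <- nd$grad
    rs <- rowSums(g * y)
    list(y * (g - rs))
  })
}

# E[i, j] = s1[i] + s2[j] from two column vectors
ag_outer_sum <- function(s1, s2) {
  v1 <- as.vector(s1$value); v2 <- as.vector(s2$value)
  ag_op(outer(v1, v2, "+"), list(s1, s2), function(nd) {
    g <- nd$grad
    list(matrix(rowSums(g), ncol = 1), matrix(colSums(g), ncol = 1))
  })
}

## ---- broadcasting over channels -------------------------------------------

# multiply (B, C, H, W) by a one-channel gate (B, 1, H, W)
ag_mul_bcast_ch <- function(x, a) {
  xd <- dim(x$value)
  av <- a$value
  arep <- av[, rep(1L, xd[2]), , , drop = FALSE]
  xv <- x$value
  ag_op(xv * arep, list(x, a), function(nd) {
    g <- nd$grad
    gm <- g * xv
    ap <- aperm(gm, c(2, 1, 3, 4))
    da <- array(colSums(matrix(ap, nrow = xd[2])), c(xd[1], 1L, xd[3], xd[4]))
    list(g * arep, da)
  })
}

## ---- convolution / pooling / resampling ------------------------------------

# 2D cross-correlation, stride 1; w has dim (Cout, Cin, K, K).
# Heavy lifting happens in the compiled im2col + BLAS kernels.
ag_conv2d <- function(x, w, b = NULL, pad = NULL) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  if (xd[2] != wd[2]) {
    stop("conv2d: input has ", xd[2], " channels but kernel expects ", wd[2])
  }
  K <- wd[3]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  xv <- x$value
  wv <- w$value
  out <- cpp_conv2d_forward(xv, wv, if (is.null(b)) NULL else b$value, as.integer(pad))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(out, parents, function(nd) {
    gr <- cpp_conv2d_backward(xv, wv, nd$grad, as.integer(pad),
                              need_dx = x$requires, has_bias = !is.null(b))
    dx <- if (x$requires) gr$dx
    if (is.null(b)) list(dx, gr$dw) else list(dx, gr$dw, gr$db)
  })
}

# 2x2 max pooling, stride 2
ag_maxpool2 <- function(x) {
  d <- dim(x$value)
  H <- d[3]; W <- d[4]
  if (H < 2 || W < 2) stop("maxpool2: spatial dims must be at least 2, got ", H, "x", W)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  subs <- lapply(offs, function(o) {
    x$value[, , seq(1L + o[1], H, 2L), seq(1L + o[2], W, 2L), drop = FALSE]
  })
  m <- pmax(pmax(subs[[1]], subs[[2]]), pmax(subs[[3]], subs[[4]]))
  ag_op(m, list(x), function(nd) {
    g <- nd$grad
    dx <- array(0, d)
    assigned <- array(FALSE, dim(m))
    for (k in seq_along(offs)) {
      sel <- (subs[[k]] == m) & !assigned
      assigned <- assigned | sel
      o <- offs[[k]]
      dx[, , seq(1L + o[1], H, 2L), seq(1L + o[2], W, 2L)] <- g * sel
    }
    list(dx)
  })
}

# index/weight tables for 2x bilinear upsampling (half-pixel centres)
up2_tables <- function(n) {
  i0 <- 0:(2L * n - 1L)
  src <- i0 / 2 - 0.25
  lo <- floor(src)
  frac <- src - lo
  i1 <- pmax(pmin(lo, n - 1L), 0L) + 1L
  i2 <- pmax(pmin(lo + 1L, n - 1L), 0L) + 1L
  list(i1 = i1, i2 = i2, w1 = 1 - frac, w2 = frac)
}

up2_axis_first <- function(ap, u) {
  ap[u$i1, , , , drop = FALSE] * u$w1 + ap[u$i2, , , , drop = FALSE] * u$w2
}

down2_axis_first <- function(g2, u, n) {
  d2 <- dim(g2)
  gm <- matrix(g2, nrow = d2[1])
  dm <- matrix(0, n, ncol(gm))
  for (i in seq_len(d2[1])) {
    dm[u$i1[i], ] <- dm[u$i1[i], ] + u$w1[i] * gm[i, ]
    dm[u$i2[i], ] <- dm[u$i2[i], ] + u$w2[i] * gm[i, ]
  }
  array(dm, c(n, d2[-1]))
}

# bilinear 2x upsampling of (B, C, H, W)
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  uh <- up2_tables(d[3]); uw <- up2_tables(d[4])
  fwd <- function(v) {
    a <- aperm(v, c(3, 1, 2, 4))          # (H, B, C, W)
    a <- up2_axis_first(a, uh)
    v2 <- aperm(a, c(2, 3, 1, 4))          # (B, C, 2H, W)
    a <- aperm(v2, c(4, 1, 2, 3))          # (W, B, C, 2H)
    a <- up2_axis_first(a, uw)
    aperm(a, c(2, 3, 4, 1))                # (B, C, 2H, 2W)
  }
  ag_op(fwd(x$value), list(x), function(nd) {
    g <- nd$grad
    a <- aperm(g, c(4, 1, 2, 3))           # (2W, B, C, 2H)
    a <- down2_axis_first(a, uw, d[4])
    g2 <- aperm(a, c(2, 3, 4, 1))          # (B, C, 2H, W)
    a <- aperm(g2, c(3, 1, 2, 4))          # (2H, B, C, W)
    a <- down2_axis_first(a, uh, d[3])
    list(aperm(a, c(2, 3, 1, 4)))
  })
}

# replicate-pad the two spatial dims of (B, C, H, W) by one pixel
ag_pad_replicate1 <- function(x) {
  d <- dim(x$value)
  H <- d[3]; W <- d[4]
  ih <- c(1L, seq_len(H), H)
  iw <- c(1L, seq_len(W), W)
  ag_op(x$value[, , ih, iw, drop = FALSE], list(x), function(nd) {
    g <- nd$grad
    dx <- g[, , 1L + seq_len(H), 1L + seq_len(W), drop = FALSE]
    dx[, , 1L, ] <- dx[, , 1L, ] + g[, , 1L, 1L + seq_len(W)]
    dx[, , H, ] <- dx[, , H, ] + g[, , H + 2L, 1L + seq_len(W)]
    dx[, , , 1L] <- dx[, , , 1L] + g[, , 1L + seq_len(H), 1L]
    dx[, , , W] <- dx[, , , W] + g[, , 1L + seq_len(H), W + 2L]
    dx[, , 1L, 1L] <- dx[, , 1L, 1L] + g[, , 1L, 1L]
    dx[, , 1L, W] <- dx[, , 1L, W] + g[, , 1L, W + 2L]
    dx[, , H, 1L] <- dx[, , H, 1L] + g[, , H + 2L, 1L]
    dx[, , H, W] <- dx[, , H, W] + g[, , H + 2L, W + 2L]
    list(dx)
  })
}

## ---- normalisation layers --------------------------------------------------

# Batch normalisation over (B, H, W) per channel. The state environment keeps
# one running mean/variance buffer per `key`: layers whose trainable weights
# are shared across the three imaging branches still track per-branch
# statistics, so eval mode reproduces training-mode normalisation exactly
# after recalibration. Biased variance is stored for the same reason.
ag_batchnorm2d <- function(x, gamma, beta, state, train, key = "shared",
                           eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  xv <- x$value
  nn <- d[1] * d[3] * d[4]
  if (!is.null(state$momentum)) momentum <- state$momentum
  C <- d[2]
  if (is.null(state$running_mean[[key]])) {
    state$running_mean[[key]] <- numeric(C)
    state$running_var[[key]] <- rep(1, C)
  }
  if (train) {
    cs <- cpp_channel_sums(xv)
    mu <- cs$sum / nn
    v <- cs$sumsq / nn - mu * mu
    state$running_mean[[key]] <- (1 - momentum) * state$running_mean[[key]] + momentum * mu
    state$running_var[[key]] <- (1 - momentum) * state$running_var[[key]] + momentum * v
  } else {
    mu <- state$running_mean[[key]]
    v <- state$running_var[[key]]
  }
  istd <- 1 / sqrt(v + eps)
  gv <- gamma$value
  out <- cpp_scale_shift(xv, gv * istd, beta$value - gv * istd * mu)
  ag_op(out, list(x, gamma, beta), function(nd) {
    g <- nd$grad
    s1 <- cpp_channel_sums(g)$sum
    sgx <- cpp_channel_dot(g, xv)
    dgamma <- (sgx - mu * s1) * istd
    dbeta <- s1
    if (train) {
      mg <- s1 / nn
      mgx <- (sgx / nn - mu * mg) * istd      # mean of g * xhat per channel
      dx <- cpp_axpb_channels(g, xv,
                              istd * gv,
                              -istd * istd * gv * mgx,
                              istd * gv * (mu * istd * mgx - mg))
    } else {
      dx <- cpp_scale_shift(g, gv * istd, numeric(length(gv)))
    }
    list(dx, dgamma, dbeta)
  })
}

# layer normalisation over the last dim of (B, N, D)
ag_layernorm <- function(z, gamma, beta, eps = 1e-5) {
  d <- dim(z$value)
  Dm <- d[3]
  xm <- matrix(z$value, nrow = d[1] * d[2])
  mu <- rowMeans(xm)
  v <- rowMeans(xm * xm) - mu * mu
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd
  ym <- t(t(xhat) * gamma$value + beta$value)
  out <- array(ym, d)
  ag_op(out, list(z, gamma, beta), function(nd) {
    gm <- matrix(nd$grad, nrow = d[1] * d[2])
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxh <- t(t(gm) * gamma$value)
    dxm <- istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    list(array(dxm, d), dgamma, dbeta)
  })
}
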