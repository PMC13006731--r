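# Straight-line reference implementations used as independent oracles.
# Deliberately naive (explicit loops, no shared code with the package) so a
# defect in the fast path cannot hide in the oracle.

naive_conv2d <- function(x, w, b = NULL, pad = 1L) {
  d <- dim(x); wd <- dim(w)
  H <- d[3] + 2L * pad - wd[3] + 1L
  W <- d[4] + 2L * pad - wd[4] + 1L
  out <- array(0, c(d[1], wd[1], H, W))
  for (bb in seq_len(d[1])) for (co in seq_len(wd[1])) {
    for (h in seq_len(H)) for (wo in seq_len(W)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(wd[2])) for (ki in seq_len(wd[3])) for (kj in seq_len(wd[4])) {
        hi <- h + ki - 1L - pad
        wi <- wo + kj - 1L - pad
        if (hi >= 1L && hi <= d[3] && wi >= 1L && wi <= d[4]) {
          acc <- acc + w[co, ci, ki, kj] * x[bb, ci, hi, wi]
        }
      }
      out[bb, co, h, wo] <- acc
    }
  }
  out
}

softmax_vec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# multi-head self-attention, one batch element at a time
oracle_mhsa <- function(z, Wq, Wk, Wv, Wo) {
  d <- dim(z)
  out <- array(0, d)
  nh <- length(Wq)
  dk <- ncol(Wq[[1]])
  for (b in seq_len(d[1])) {
    Zb <- matrix(z[b, , ], d[2], d[3])
    heads <- NULL
    for (h in seq_len(nh)) {
      Q <- Zb %*% Wq[[h]]; K <- Zb %*% Wk[[h]]; V <- Zb %*% Wv[[h]]
      S <- Q %*% t(K) / sqrt(dk)
      A <- t(apply(S, 1, softmax_vec))
      if (d[2] == 1L) A <- matrix(A, 1, 1)
      heads <- cbind(heads, A %*% V)
    }
    out[b, , ] <- heads %*% Wo
  }
  out
}

# graph attention coefficients and layer output for one batch element
oracle_gat_one <- function(Z, W, a1, a2, slope = 0.2, elu = TRUE) {
  Hn <- Z %*% W
  N <- nrow(Z)
  E <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    e <- sum(a1 * Hn[i, ]) + sum(a2 * Hn[j, ])
    E[i, j] <- if (e > 0) e else slope * e
  }
  A <- t(apply(E, 1, softmax_vec))
  if (N == 1L) A <- matrix(A, 1, 1)
  agg <- A %*% Hn
  out <- if (elu) ifelse(agg > 0, agg, exp(agg) - 1) else agg
  list(alpha = A, out = out)
}

# conv + (neutralised) BN + ReLU with an explicit eval-mode BN formula
oracle_conv_bn_relu <- function(x, w, b, gamma, beta, rm, rv, eps = 1e-5) {
  y <- naive_conv2d(x, w, b, pad = (dim(w)[3] - 1L) %/% 2L)
  C <- dim(y)[2]
  for (cc in seq_len(C)) {
    y[, cc, , ] <- (y[, cc, , ] - rm[cc]) / sqrt(rv[cc] + eps) * gamma[cc] + beta[cc]
  }
  pmax(y, 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# neutralise a conv-block's batch norm so eval mode is the exact identity
neutralize_bn <- function(mod) {
  for (key in names(mod$bn$state$running_var)) {
    mod$bn$state$running_var[[key]] <- mod$bn$state$running_var[[key]] - 1e-5
  }
  invisible(mod)
}

# small helpers shared across test files
make_phantom_study <- function(shape = c(4L, 32L, 32L), seed = 11L, id = "T",
                               ...) {
  generate_phantom(phantom_spec(shape = shape,
                                tumor_center = (shape + 1) / 2,
                                tumor_radii = pmax(1.2, shape / 3.2),
                                seed = seed, patient_id = id, ...))
}

tiny_cohort <- function(n = 10L, seed = 123L, shape = c(8L, 32L, 32L)) {
  generate_cohort(n, seed = seed, shape = shape)
}
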