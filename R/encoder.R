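# Weight-sharing hybrid encoder: convolutional DownBlocks extract local
# features, transformer VitBlocks at the bottleneck model global context via
# multi-head self-attention. One parameter set serves the pre-contrast,
# post-contrast and residual branches alike.

#' Encoder architecture configuration
#'
#' @param n_stages number of downsampling stages (default 4).
#' @param channels per-stage channel widths; default `base * 2^(0:(n-1))`.
#' @param base_channels width of the stem / first stage (default 32).
#' @param n_vit_layers transformer depth at the bottleneck (default 6).
#' @param n_heads attention heads (default 4); must divide the bottleneck width.
#' @param use_local keep the convolutional (local) path; FALSE swaps every
#'   encoder conv to a 1x1 projection while retaining pooling.
#' @param use_global keep the bottleneck VitBlocks (global path).
#' @param use_posemb add a learned positional embedding before the first
#'   VitBlock.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_stages = 4L, channels = NULL, base_channels = 32L,
                           n_vit_layers = 6L, n_heads = 4L,
                           use_local = TRUE, use_global = TRUE,
                           use_posemb = TRUE) {
  n_stages <- as.integer(n_stages)
  if (n_stages < 1L) stop("n_stages must be >= 1")
  if (is.null(channels)) channels <- as.integer(base_channels * 2^(seq_len(n_stages) - 1L))
  if (length(channels) != n_stages) stop("channels must have one entry per stage")
  if (use_global && channels[n_stages] %% n_heads != 0L) {
    stop("n_heads (", n_heads, ") must divide the bottleneck width (",
         channels[n_stages], ")")
  }
  structure(list(n_stages = n_stages, channels = channels,
                 stem_channels = channels[1], n_vit_layers = as.integer(n_vit_layers),
                 n_heads = as.integer(n_heads), use_local = use_local,
                 use_global = use_global, use_posemb = use_posemb),
            class = "encoder_config")
}

#' Create a conv block (conv + batch norm + ReLU)
#' @param cin,cout channel counts.
#' @param k kernel size.
#' @return module list.
#' @export
new_conv_block <- function(cin, cout, k = 3L) {
  mod <- list(conv = new_conv2d(cin, cout, k), bn = new_batchnorm2d(cout))
  class(mod) <- c("nn_conv_block", "nn_module")
  mod
}

#' Apply a conv block: ReLU(BN(W * x + b))
#'
#' Same-padding convolution, so spatial dims are preserved; all outputs are
#' non-negative.
#'
#' @param x input feature map (B, C, H, W), plain array or `ag_tensor`.
#' @param mod module from [new_conv_block()].
#' @param train use batch statistics and update running stats (default FALSE).
#' @return feature map of the same spatial size (array if `x` was an array).
#' @export
conv_block <- function(x, mod, train = FALSE, key = "shared") {
  plain <- !is_ag(x)
  out <- ag_relu(bn_fwd(mod$bn, conv2d_fwd(mod$conv, as_ag(x)), train, key))
  if (plain) ag_value(out) else out
}

#' Create a DownBlock (pool + two conv blocks + projected shortcut)
#' @param cin,cout channel counts.
#' @param k main-branch kernel size (1 disables the local conv path).
#' @return module list.
#' @export
new_down_block <- function(cin, cout, k = 3L) {
  mod <- list(cb1 = new_conv_block(cin, cout, k),
              cb2 = new_conv_block(cout, cout, k),
              shortcut = new_conv2d(cin, cout, 1L, bias = FALSE),
              shortcut_bn = new_batchnorm2d(cout))
  class(mod) <- c("nn_down_block", "nn_module")
  mod
}

#' Apply a DownBlock
#'
#' 2x2 max pooling halves the spatial dims, two conv blocks map to the stage
#' width, and a 1x1-projected shortcut of the pooled input is added before a
#' final ReLU.
#'
#' @inheritParams conv_block
#' @param mod module from [new_down_block()].
#' @return feature map (B, cout, H/2, W/2).
#' @export
down_block <- function(x, mod, train = FALSE, key = "shared") {
  plain <- !is_ag(x)
  x <- as_ag(x)
  p <- ag_maxpool2(x)
  main <- conv_block(conv_block(p, mod$cb1, train, key), mod$cb2, train, key)
  sc <- bn_fwd(mod$shortcut_bn, conv2d_fwd(mod$shortcut, p, pad = 0L), train, key)
  out <- ag_relu(ag_add(main, sc))
  if (plain) ag_value(out) else out
}

## ---- patch sequence --------------------------------------------------------

#' Flatten a feature map into a raster-ordered patch sequence
#'
#' Token i holds the feature vector at raster position
#' (i div W, i mod W) (row-major), embedding dim D = C.
#'
#' @param x feature map (B, C, H, W).
#' @return patch sequence (B, N = H*W, D = C).
#' @export
patchify <- function(x) {
  plain <- !is_ag(x)
  x <- as_ag(x)
  d <- dim(x$value)
  out <- ag_reshape(ag_aperm(x, c(1, 4, 3, 2)), c(d[1], d[3] * d[4], d[2]))
  if (plain) ag_value(out) else out
}

#' Restore a patch sequence to a feature map
#' @param z patch sequence (B, N, D).
#' @param H,W target spatial dims with `N = H * W`.
#' @return feature map (B, D, H, W).
#' @export
unpatchify <- function(z, H, W) {
  plain <- !is_ag(z)
  z <- as_ag(z)
  d <- dim(z$value)
  if (d[2] != H * W) stop("token count ", d[2], " != H*W = ", H * W)
  out <- ag_aperm(ag_reshape(z, c(d[1], W, H, d[3])), c(1, 4, 3, 2))
  if (plain) ag_value(out) else out
}

## ---- multi-head self-attention --------------------------------------------

#' Create multi-head self-attention parameters
#'
#' Per-head query/key/value projections of size D x (D/H) and an output
#' projection (D x D); no projection biases.
#'
#' @param D embedding dim.
#' @param H head count; must divide D.
#' @return module list.
#' @export
new_attention <- function(D, H = 4L) {
  if (D %% H != 0L) stop("head count ", H, " does not divide embedding dim ", D)
  dk <- D %/% H
  proj <- function() ag_param(matrix(he_init(D * dk, D, gain = 1), D, dk))
  mod <- list(Wq = lapply(seq_len(H), function(i) proj()),
              Wk = lapply(seq_len(H), function(i) proj()),
              Wv = lapply(seq_len(H), function(i) proj()),
              Wo = ag_param(matrix(he_init(D * D, D, gain = 1), D, D)),
              H = as.integer(H), dk = dk)
  class(mod) <- c("nn_attention", "nn_module")
  mod
}

#' Multi-head self-attention over a patch sequence
#'
#' Per head h, softmax(Q_h K_h^T / sqrt(dk)) V_h; head outputs are
#' concatenated and projected. Every attention row sums to one.
#'
#' @param z patch sequence (B, N, D), plain array or `ag_tensor`.
#' @param mod module from [new_attention()].
#' @param return_attention also return the attention tensor (B, H, N, N).
#' @return sequence of the same shape; with `return_attention`, a list
#'   `(out, attention)`.
#' @export
mhsa <- function(z, mod, return_attention = FALSE) {
  plain <- !is_ag(z)
  z <- as_ag(z)
  d <- dim(z$value)
  B <- d[1]; N <- d[2]
  scale <- 1 / sqrt(mod$dk)
  attn <- if (return_attention) array(0, c(B, mod$H, N, N))
  outs <- vector("list", B)
  for (b in seq_len(B)) {
    Zb <- ag_slice_b(z, b)
    heads <- vector("list", mod$H)
    for (h in seq_len(mod$H)) {
      Q <- ag_matmul(Zb, mod$Wq[[h]])
      K <- ag_matmul(Zb, mod$Wk[[h]])
      V <- ag_matmul(Zb, mod$Wv[[h]])
      A <- ag_softmax_rows(ag_mul_const(ag_matmul(Q, ag_t(K)), scale))
      if (return_attention) attn[b, h, , ] <- A$value
      heads[[h]] <- ag_matmul(A, V)
    }
    outs[[b]] <- ag_matmul(ag_cbind(heads), mod$Wo)
  }
  out <- ag_stack_b(outs)
  if (plain) out <- ag_value(out)
  if (return_attention) list(out = out, attention = attn) else out
}

#' Create a pre-norm transformer block
#' @param D embedding dim.
#' @param H head count.
#' @param mlp_ratio hidden expansion of the MLP (default 4).
#' @return module list.
#' @export
new_vit_block <- function(D, H = 4L, mlp_ratio = 4L) {
  mod <- list(ln1 = new_layernorm(D), attn = new_attention(D, H),
              ln2 = new_layernorm(D),
              fc1 = new_linear(D, D * mlp_ratio), fc2 = new_linear(D * mlp_ratio, D))
  class(mod) <- c("nn_vit_block", "nn_module")
  mod
}

#' Apply a transformer block (pre-norm residual composition)
#'
#' `z + MHSA(LN(z))`, then `+ MLP(LN(.))` with a GELU MLP; shape preserved.
#'
#' @param z patch sequence (B, N, D).
#' @param mod module from [new_vit_block()].
#' @return sequence of the same shape.
#' @export
vit_block <- function(z, mod) {
  plain <- !is_ag(z)
  z <- as_ag(z)
  z <- ag_add(z, mhsa(ln_fwd(mod$ln1, z), mod$attn))
  h <- linear3_fwd(mod$fc1, ln_fwd(mod$ln2, z))
  z <- ag_add(z, linear3_fwd(mod$fc2, ag_gelu(h)))
  if (plain) ag_value(z) else z
}

## ---- full encoder ----------------------------------------------------------

#' Build the weight-sharing encoder
#'
#' @param cfg an `encoder_config`.
#' @param input_size spatial dims c(H, W) of network input; must be divisible
#'   by `2^n_stages` (fixes the positional-embedding size).
#' @param in_channels input channels per branch (default 1).
#' @return encoder module list.
#' @export
new_encoder <- function(cfg, input_size, in_channels = 1L) {
  H <- input_size[1]; W <- input_size[2]
  div <- 2L^cfg$n_stages
  if (H %% div != 0L || W %% div != 0L) {
    stop("input size ", H, "x", W, " not divisible by 2^n_stages = ", div,
         "; pad the slices to a multiple of ", div)
  }
  k <- if (cfg$use_local) 3L else 1L
  stem <- new_conv_block(in_channels, cfg$stem_channels, k)
  stages <- vector("list", cfg$n_stages)
  cin <- cfg$stem_channels
  for (i in seq_len(cfg$n_stages)) {
    stages[[i]] <- new_down_block(cin, cfg$channels[i], k)
    cin <- cfg$channels[i]
  }
  D <- cfg$channels[cfg$n_stages]
  Nb <- (H %/% div) * (W %/% div)
  vit <- NULL; posemb <- NULL
  if (cfg$use_global) {
    if (cfg$use_posemb) posemb <- ag_param(matrix(stats::rnorm(Nb * D, sd = 0.02), Nb, D))
    vit <- lapply(seq_len(cfg$n_vit_layers), function(i) new_vit_block(D, cfg$n_heads))
  }
  mod <- list(cfg = cfg, stem = stem, stages = stages, vit = vit, posemb = posemb,
              input_size = c(H, W), bottleneck_hw = c(H %/% div, W %/% div))
  class(mod) <- c("nn_encoder", "nn_module")
  mod
}

# One branch through stem, stages and (at the bottleneck) the ViT stack;
# returns features at every level: [[1]] stem (full res), [[i+1]] stage i.
# `key` selects the per-branch batch-norm statistics buffer: the trainable
# encoder weights are shared across branches, the normalisation statistics
# are not (they are buffers, not weights).
encode_branch <- function(enc, x, train = FALSE, key = "shared") {
  feats <- vector("list", enc$cfg$n_stages + 1L)
  f <- conv_block(x, enc$stem, train, key)
  feats[[1]] <- f
  for (i in seq_len(enc$cfg$n_stages)) {
    f <- down_block(f, enc$stages[[i]], train, key)
    feats[[i + 1L]] <- f
  }
  if (enc$cfg$use_global) {
    z <- patchify(f)
    if (!is.null(enc$posemb)) z <- ag_add_tokens(z, enc$posemb)
    for (blk in enc$vit) z <- vit_block(z, blk)
    feats[[enc$cfg$n_stages + 1L]] <- unpatchify(z, enc$bottleneck_hw[1], enc$bottleneck_hw[2])
  }
  feats
}

#' Encode the three study branches with shared weights
#'
#' One parameter set is applied to the pre, post and residual branches; the
#' per-stage feature pyramids are retained for multi-scale refinement and the
#' decoder skips.
#'
#' @param batch a `slice_batch` or a list with `pre`, `post`, `res` tensors of
#'   shape (B, 1, H, W).
#' @param enc encoder from [new_encoder()].
#' @param train training-mode batch norm.
#' @return list with elements `pre`, `post`, `res`, each a list of feature
#'   maps from full resolution (stem) down to the bottleneck.
#' @export
encode_branches <- function(batch, enc, train = FALSE) {
  plain <- !is_ag(batch$pre)
  res <- list(pre = encode_branch(enc, as_ag(batch$pre), train, "pre"),
              post = encode_branch(enc, as_ag(batch$post), train, "post"),
              res = encode_branch(enc, as_ag(batch$res), train, "res"))
  if (plain) lapply(res, function(pyr) lapply(pyr, ag_value)) else res
}
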