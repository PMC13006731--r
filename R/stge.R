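# Spatiotemporal graph enhancement. Inter-slice attention (ISA) runs a dense
# graph attention layer over the bottleneck's spatial nodes for each modality,
# followed by a batch-wise slice recalibration; inter-temporal attention (ITA)
# then fuses the three modalities channel-wise with sigmoid spatial gating.

#' Create graph-attention parameters
#'
#' @param C input node feature dim.
#' @param Cp output dim (default C).
#' @param leaky_slope LeakyReLU negative slope for attention logits
#'   (default 0.2, the GAT-literature convention).
#' @return module list: node transform `W` (C x Cp) and the attention vector
#'   split into its two halves `a1`, `a2` (each Cp x 1).
#' @export
new_gat <- function(C, Cp = C, leaky_slope = 0.2) {
  mod <- list(W = ag_param(matrix(he_init(C * Cp, C, gain = 1), C, Cp)),
              a1 = ag_param(matrix(stats::rnorm(Cp, sd = 0.1), Cp, 1)),
              a2 = ag_param(matrix(stats::rnorm(Cp, sd = 0.1), Cp, 1)),
              slope = leaky_slope)
  class(mod) <- c("nn_gat", "nn_module")
  mod
}

gat_scores <- function(Zb, mod) {
  Hn <- ag_matmul(Zb, mod$W)
  E <- ag_leaky_relu(ag_outer_sum(ag_matmul(Hn, mod$a1), ag_matmul(Hn, mod$a2)),
                     mod$slope)
  list(Hn = Hn, A = ag_softmax_rows(E))
}

#' Dense graph-attention coefficients over spatial nodes
#'
#' For nodes i, j of a fully connected graph,
#' `alpha_ij = softmax_j LeakyReLU(a^T [W h_i || W h_j])`; every row sums to
#' one and all coefficients are positive.
#'
#' @param nodes graph nodes (B, N, C), plain array or `ag_tensor`.
#' @param mod module from [new_gat()].
#' @return attention tensor (B, N, N).
#' @export
gat_attention <- function(nodes, mod) {
  plain <- !is_ag(nodes)
  nodes <- as_ag(nodes)
  B <- dim(nodes$value)[1]
  out <- ag_stack_b(lapply(seq_len(B), function(b) {
    gat_scores(ag_slice_b(nodes, b), mod)$A
  }))
  if (plain) ag_value(out) else out
}

#' One graph-attention layer
#'
#' Aggregates `h_i_out = sigma(sum_j alpha_ij W h_j)` with an ELU output
#' nonlinearity (GAT convention).
#'
#' @inheritParams gat_attention
#' @param activation output nonlinearity: "elu" (default) or "identity".
#' @return node features (B, N, Cp).
#' @export
gat_layer <- function(nodes, mod, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  plain <- !is_ag(nodes)
  nodes <- as_ag(nodes)
  B <- dim(nodes$value)[1]
  out <- ag_stack_b(lapply(seq_len(B), function(b) {
    gs <- gat_scores(ag_slice_b(nodes, b), mod)
    agg <- ag_matmul(gs$A, gs$Hn)
    if (activation == "elu") ag_elu(agg) else agg
  }))
  if (plain) ag_value(out) else out
}

#' Create the inter-slice attention state
#'
#' Holds one local-enhancement conv block per modality, shared GAT parameters
#' and the 1x1 convolution of the batch-wise slice recalibration.
#'
#' @param C bottleneck channel width.
#' @param leaky_slope LeakyReLU slope of the GAT logits.
#' @return module list.
#' @export
new_isa <- function(C, leaky_slope = 0.2) {
  mod <- list(fconv = list(pre = new_conv_block(C, C, 3L),
                           post = new_conv_block(C, C, 3L),
                           d = new_conv_block(C, C, 3L)),
              gat = new_gat(C, C, leaky_slope),
              batch_attn = new_conv2d(C, C, 1L))
  class(mod) <- c("nn_isa", "nn_module")
  mod
}

#' Batch-wise slice recalibration
#'
#' The feature tensor is permuted and reshaped so batch and height aggregate
#' into one axis — the batch dimension acting as a proxy for adjacent slices —
#' a 1x1 convolution + sigmoid produces per-element weights in (0, 1), the
#' weights multiply the features, and the original layout is restored. The
#' layout shuffle is isolated here so it can be swapped wholesale.
#'
#' @param x feature map (B, C, H, W).
#' @param mod a module holding the 1x1 conv (field `batch_attn`), e.g. an ISA
#'   state from [new_isa()].
#' @return recalibrated map, same shape, with `|out| <= |in|` element-wise.
#' @export
batch_slice_attention <- function(x, mod) {
  plain <- !is_ag(x)
  x <- as_ag(x)
  d <- dim(x$value)
  # (B, C, H, W) -> (B, H, C, W) -> (B*H, C, 1, W)
  xp <- ag_reshape(ag_aperm(x, c(1, 3, 2, 4)), c(d[1] * d[3], d[2], 1L, d[4]))
  w <- ag_sigmoid(conv2d_fwd(mod$batch_attn, xp, pad = 0L))
  wb <- ag_aperm(ag_reshape(w, c(d[1], d[3], d[2], d[4])), c(1, 3, 2, 4))
  out <- ag_mul(x, wb)
  if (plain) ag_value(out) else out
}

#' Inter-slice attention for one modality
#'
#' Local conv enhancement, flatten to graph nodes, one dense GAT layer,
#' reshape back, then batch-wise slice recalibration; shape preserved.
#'
#' @param Fm feature map (B, C, H, W) of one modality.
#' @param mod ISA state from [new_isa()].
#' @param modality one of "pre", "post", "d" (selects the modality-specific
#'   conv transform).
#' @param train training-mode batch norm.
#' @return enhanced feature map (B, C, H, W).
#' @export
isa <- function(Fm, mod, modality = c("pre", "post", "d"), train = FALSE) {
  modality <- match.arg(modality)
  plain <- !is_ag(Fm)
  Fm <- as_ag(Fm)
  d <- dim(Fm$value)
  fh <- conv_block(Fm, mod$fconv[[modality]], train)
  z <- patchify(fh)
  z <- gat_layer(z, mod$gat)
  fg <- unpatchify(z, d[3], d[4])
  out <- batch_slice_attention(fg, mod)
  if (plain) ag_value(out) else out
}

#' Create the inter-temporal attention module
#' @param C channel width of each modality feature.
#' @return module list: channel-fusion MLP (two 1x1 convolutions,
#'   3C -> C -> C with ReLU between) and the 1x1 attention conv.
#' @export
new_ita <- function(C) {
  mod <- list(mlp1 = new_conv2d(3L * C, C, 1L),
              mlp2 = new_conv2d(C, C, 1L),
              attn = new_conv2d(C, 1L, 1L))
  class(mod) <- c("nn_ita", "nn_module")
  mod
}

#' Inter-temporal attention fusion of the three modalities
#'
#' Channel-wise concatenation, channel-wise MLP fusion, then sigmoid spatial
#' gating: `Fout = Ffused * sigmoid(Conv1x1(Ffused))`.
#'
#' @param f_pre,f_post,f_res co-shaped (B, C, H, W) feature maps.
#' @param mod module from [new_ita()].
#' @return fused feature map (B, C, H, W).
#' @export
ita <- function(f_pre, f_post, f_res, mod) {
  plain <- !is_ag(f_pre)
  dims <- lapply(list(f_pre, f_post, f_res), function(x) dim(ag_value(x)))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("modality features must share shape (B, C, H, W)")
  }
  cat3 <- ag_concat_ch(list(as_ag(f_pre), as_ag(f_post), as_ag(f_res)))
  fused <- conv2d_fwd(mod$mlp2, ag_relu(conv2d_fwd(mod$mlp1, cat3, pad = 0L)), pad = 0L)
  a <- ag_sigmoid(conv2d_fwd(mod$attn, fused, pad = 0L))
  out <- ag_mul_bcast_ch(fused, a)
  if (plain) ag_value(out) else out
}
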