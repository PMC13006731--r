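# Residual-guided multi-scale refinement: modality-specific conv transforms,
# a shared channel-wise MLP fusing the concatenated features, and sigmoid
# spatial attention recalibrating the fused map. One instance per encoder
# level; the refined maps feed the decoder skips and the bottleneck.

#' Create a multi-scale refinement module
#'
#' @param C channel width of the three incoming modality features.
#' @return module list: three modality-specific conv blocks, a shared
#'   channel-wise MLP (two 1x1 convolutions, 3C -> C -> C, ReLU between) and
#'   a 1x1 convolution producing the spatial attention logit.
#' @export
new_msr <- function(C) {
  mod <- list(f_pre = new_conv_block(C, C, 3L),
              f_post = new_conv_block(C, C, 3L),
              f_res = new_conv_block(C, C, 3L),
              mlp1 = new_conv2d(3L * C, C, 1L),
              mlp2 = new_conv2d(C, C, 1L),
              attn = new_conv2d(C, 1L, 1L))
  class(mod) <- c("nn_msr", "nn_module")
  mod
}

#' Residual-guided multi-scale refinement of one encoder level
#'
#' The three modality features are transformed by modality-specific
#' convolutions, concatenated, fused by the shared channel-wise MLP, and
#' recalibrated: `Fout = Ffused * sigmoid(Conv1x1(Ffused))`. The attention
#' map lies strictly in (0, 1), so `|Fout| <= |Ffused|` element-wise.
#'
#' @param pre_f,post_f,res_f co-shaped feature maps (B, C, H, W).
#' @param mod module from [new_msr()].
#' @param train training-mode batch norm.
#' @return refined feature map (B, C, H, W).
#' @export
msr_refine <- function(pre_f, post_f, res_f, mod, train = FALSE) {
  plain <- !is_ag(pre_f)
  dims <- lapply(list(pre_f, post_f, res_f), function(x) dim(ag_value(x)))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("modality features must share shape (B, C, H, W)")
  }
  ph <- conv_block(as_ag(pre_f), mod$f_pre, train)
  oh <- conv_block(as_ag(post_f), mod$f_post, train)
  rh <- conv_block(as_ag(res_f), mod$f_res, train)
  cat3 <- ag_concat_ch(list(ph, oh, rh))
  fused <- conv2d_fwd(mod$mlp2, ag_relu(conv2d_fwd(mod$mlp1, cat3, pad = 0L)), pad = 0L)
  a <- ag_sigmoid(conv2d_fwd(mod$attn, fused, pad = 0L))
  out <- ag_mul_bcast_ch(fused, a)
  if (plain) ag_value(out) else out
}

#' Create the plain-fusion replacement used by the "w/o MSR" ablation
#'
#' Channel concatenation followed by a single 1x1 projection, with no
#' modality-specific transforms and no attention recalibration.
#'
#' @param C channel width.
#' @return module list.
#' @export
new_concat_proj <- function(C) {
  mod <- list(proj = new_conv2d(3L * C, C, 1L))
  class(mod) <- c("nn_concat_proj", "nn_module")
  mod
}

concat_proj_fuse <- function(pre_f, post_f, res_f, mod, train = FALSE) {
  conv2d_fwd(mod$proj, ag_concat_ch(list(as_ag(pre_f), as_ag(post_f), as_ag(res_f))),
             pad = 0L)
}
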