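# End-to-end model assembly: residual-guided branches -> weight-sharing
# encoder -> per-level multi-scale refinement -> spatiotemporal graph
# enhancement -> U-Net-style decoder -> per-slice probability map. Also the
# ablation variants and Grad-CAM interpretability.

#' Full model configuration
#'
#' @param encoder an [encoder_config()].
#' @param input_size network input spatial dims c(H, W); must be divisible by
#'   `2^n_stages`.
#' @param msr_enabled use multi-scale refinement (FALSE swaps in plain
#'   concat + 1x1 projection, the "w/o MSR" ablation).
#' @param stge_enabled use spatiotemporal graph enhancement (FALSE passes the
#'   bottleneck fusion straight to the decoder, the "w/o STGE" ablation).
#' @param lambda,beta hybrid-loss weights (defaults 0.5 and 0.2).
#' @param threshold probability threshold for the binary mask, in (0, 1);
#'   ties go to foreground.
#' @param seed RNG seed for weight initialisation.
#' @return an `rst2g_config` list.
#' @export
rst2g_config <- function(encoder = encoder_config(), input_size = c(64L, 64L),
                         msr_enabled = TRUE, stge_enabled = TRUE,
                         lambda = 0.5, beta = 0.2, threshold = 0.5,
                         seed = 42L) {
  if (lambda < 0 || lambda > 1 || beta < 0 || beta > 1) {
    stop("lambda and beta must lie in [0, 1]")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  structure(list(encoder = encoder, input_size = as.integer(input_size),
                 msr_enabled = msr_enabled, stge_enabled = stge_enabled,
                 lambda = lambda, beta = beta, threshold = threshold,
                 seed = as.integer(seed)),
            class = "rst2g_config")
}

#' A small configuration for CPU-scale experiments
#'
#' Two stages, one transformer layer and 16 base channels on 32 x 32 slices.
#'
#' @param input_size spatial dims (default c(32, 32)).
#' @param seed initialisation seed.
#' @param ... overrides passed to [rst2g_config()].
#' @return an `rst2g_config`.
#' @export
rst2g_tiny_config <- function(input_size = c(32L, 32L), seed = 42L, ...) {
  rst2g_config(encoder = encoder_config(n_stages = 2L, base_channels = 16L,
                                        n_vit_layers = 1L, n_heads = 4L),
               input_size = input_size, seed = seed, ...)
}

#' Build the full segmentation model
#'
#' Level channels run stem, stage 1, ..., stage n; a fusion module (MSR or
#' the plain concat projection) sits at every level; the graph-enhancement
#' block sits at the bottleneck; the decoder mirrors the encoder with fused
#' skips and ends in a 1-channel 1x1 convolution.
#'
#' @param cfg an `rst2g_config`.
#' @return an `rst2g_model` list.
#' @export
rst2g_model <- function(cfg) {
  stopifnot(inherits(cfg, "rst2g_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  ec <- cfg$encoder
  enc <- new_encoder(ec, cfg$input_size)
  level_ch <- c(ec$stem_channels, ec$channels)   # levels 0..n
  n <- ec$n_stages
  fusion <- lapply(level_ch, function(C) {
    if (cfg$msr_enabled) new_msr(C) else new_concat_proj(C)
  })
  Cb <- level_ch[n + 1L]
  stge <- if (cfg$stge_enabled) list(isa = new_isa(Cb), ita = new_ita(Cb))
  up <- vector("list", n)
  for (l in n:1) {
    cin <- level_ch[l + 1L] + level_ch[l]   # upsampled deep + skip
    up[[l]] <- list(cb1 = new_conv_block(cin, level_ch[l], 3L),
                    cb2 = new_conv_block(level_ch[l], level_ch[l], 3L))
  }
  head <- new_conv2d(level_ch[1], 1L, 1L)
  model <- list(cfg = cfg, encoder = enc, fusion = fusion, stge = stge,
                up = up, head = head)
  class(model) <- c("rst2g_model", "nn_module")
  model
}

#' @export
print.rst2g_model <- function(x, ...) {
  cat(sprintf(
    "<rst2g_model: %d stages, %s channels, %d ViT layer(s), msr=%s, stge=%s, %d parameters>\n",
    x$cfg$encoder$n_stages, paste(x$cfg$encoder$channels, collapse = "-"),
    if (x$cfg$encoder$use_global) x$cfg$encoder$n_vit_layers else 0L,
    x$cfg$msr_enabled, x$cfg$stge_enabled, count_params(x)))
  invisible(x)
}

fuse_level <- function(model, pre_f, post_f, res_f, level, train) {
  mod <- model$fusion[[level]]
  if (inherits(mod, "nn_msr")) {
    msr_refine(pre_f, post_f, res_f, mod, train)
  } else {
    concat_proj_fuse(pre_f, post_f, res_f, mod, train)
  }
}

#' Decode a bottleneck feature map through the skip chain
#'
#' Each of the n stages bilinearly upsamples by 2, concatenates the fused
#' skip of the level above and applies two conv blocks; a final 1x1
#' convolution produces the 1-channel logits at the network input size.
#'
#' @param bottleneck (B, C_n, H/2^n, W/2^n) feature map.
#' @param skips list of fused skip maps ordered shallow -> deep (levels
#'   0 .. n-1).
#' @param model an `rst2g_model`.
#' @param train training-mode batch norm.
#' @return logits (B, 1, H, W).
#' @export
cdecode <- function(bottleneck, skips, model, train = FALSE) {
  plain <- !is_ag(bottleneck)
  f <- as_ag(bottleneck)
  n <- model$cfg$encoder$n_stages
  if (length(skips) != n) stop("expected ", n, " skip maps, got ", length(skips))
  for (l in n:1) {
    u <- ag_upsample2(f)
    sk <- as_ag(skips[[l]])
    du <- dim(u$value); ds <- dim(sk$value)
    if (!identical(du[c(1, 3, 4)], ds[c(1, 3, 4)])) {
      stop("skip at level ", l - 1L, " has spatial dims ",
           paste(ds[3:4], collapse = "x"), " but decoder expects ",
           paste(du[3:4], collapse = "x"))
    }
    f <- ag_concat_ch(list(u, sk))
    f <- conv_block(conv_block(f, model$up[[l]]$cb1, train), model$up[[l]]$cb2, train)
  }
  out <- conv2d_fwd(model$head, f, pad = 0L)
  if (plain) ag_value(out) else out
}

# graph-building forward; returns ag logits plus recorded activations
forward_ag <- function(model, batch, train = FALSE, record = FALSE) {
  ec <- model$cfg$encoder
  n <- ec$n_stages
  pyr <- encode_branches(list(pre = as_ag(batch$pre), post = as_ag(batch$post),
                              res = as_ag(batch$res)), model$encoder, train)
  fused <- lapply(seq_len(n + 1L), function(l) {
    fuse_level(model, pyr$pre[[l]], pyr$post[[l]], pyr$res[[l]], l, train)
  })
  cache <- if (record) {
    stats::setNames(fused, c("stem", paste0("stage", seq_len(n))))
  }
  if (!is.null(model$stge)) {
    e_pre <- isa(pyr$pre[[n + 1L]], model$stge$isa, "pre", train)
    e_post <- isa(pyr$post[[n + 1L]], model$stge$isa, "post", train)
    e_res <- isa(pyr$res[[n + 1L]], model$stge$isa, "d", train)
    bott <- ag_add(ita(e_pre, e_post, e_res, model$stge$ita), fused[[n + 1L]])
  } else {
    bott <- fused[[n + 1L]]
  }
  if (record) cache$bottleneck <- bott
  logits <- cdecode(bott, fused[seq_len(n)], model, train)
  list(logits = logits, cache = cache)
}

#' Run the model on a slice batch
#'
#' @param model an `rst2g_model`.
#' @param batch a `slice_batch` or list with `pre`, `post`, `res` arrays of
#'   shape (B, 1, H, W).
#' @param train training-mode batch norm (default FALSE: deterministic,
#'   repeatable eval).
#' @return a `segmentation_output`: sigmoid `probabilities` in (0, 1), the
#'   thresholded binary `mask` (ties to foreground) and the raw `logits`,
#'   all (B, 1, H, W).
#' @export
rst2g_forward <- function(model, batch, train = FALSE) {
  fw <- forward_ag(model, batch, train)
  logits <- ag_value(fw$logits)
  probs <- 1 / (1 + exp(-logits))
  structure(list(probabilities = probs,
                 mask = (probs >= model$cfg$threshold) * 1,
                 logits = logits),
            class = "segmentation_output")
}

#' Build an ablation variant of the model
#'
#' @param cfg a full `rst2g_config` (all components enabled).
#' @param variant one of "full", "no_cfe_l" (encoder convs become 1x1
#'   projections, pooling kept), "no_cfe_g" (no VitBlocks), "no_msr"
#'   (concat + 1x1 fusion), "no_stge" (bottleneck fusion straight to the
#'   decoder). The table-style names "w/o CFE-L" etc. are also accepted.
#' @return an `rst2g_model`.
#' @export
build_variant <- function(cfg, variant = "full") {
  canon <- c("full" = "full",
             "no_cfe_l" = "no_cfe_l", "w/o cfe-l" = "no_cfe_l",
             "no_cfe_g" = "no_cfe_g", "w/o cfe-g" = "no_cfe_g",
             "no_msr" = "no_msr", "w/o msr" = "no_msr",
             "no_stge" = "no_stge", "w/o stge" = "no_stge")
  key <- canon[tolower(variant)]
  if (is.na(key)) {
    stop("unknown variant '", variant, "'; use one of full, no_cfe_l, ",
         "no_cfe_g, no_msr, no_stge")
  }
  if (!cfg$encoder$use_local || !cfg$encoder$use_global ||
      !cfg$msr_enabled || !cfg$stge_enabled) {
    stop("build_variant expects a full configuration; the supplied config ",
         "already disables a component")
  }
  if (key == "no_cfe_l") cfg$encoder$use_local <- FALSE
  if (key == "no_cfe_g") cfg$encoder$use_global <- FALSE
  if (key == "no_msr") cfg$msr_enabled <- FALSE
  if (key == "no_stge") cfg$stge_enabled <- FALSE
  rst2g_model(cfg)
}

#' All ablation variant names
#' @return character vector.
#' @export
rst2g_variants <- function() c("full", "no_cfe_l", "no_cfe_g", "no_msr", "no_stge")

upsample_to <- function(a4, H, W) {
  # repeated bilinear doubling (spatial dims are powers-of-two apart)
  x <- ag_const(a4)
  while (dim(x$value)[3] < H) x <- ag_upsample2(x)
  if (!identical(dim(x$value)[3:4], as.integer(c(H, W)))) {
    stop("cannot upsample ", paste(dim(a4)[3:4], collapse = "x"), " to ", H, "x", W)
  }
  ag_value(x)
}

#' Grad-CAM heatmap for a slice batch
#'
#' The target score is the sum of logits inside the predicted mask (over the
#' whole batch). Channel weights are the spatially averaged gradients at the
#' target layer; the weighted, ReLU-rectified activation map is bilinearly
#' upsampled to input size and min-max normalised per slice (all-zero maps
#' stay zero).
#'
#' @param model an `rst2g_model`.
#' @param batch a `slice_batch` or pre/post/res list.
#' @param target_layer one of "stem", "stage1", ..., "bottleneck"
#'   (default: the deepest conv stage, "bottleneck").
#' @return heatmap array (B, 1, H, W) with values in [0, 1].
#' @export
grad_cam <- function(model, batch, target_layer = "bottleneck") {
  fw <- forward_ag(model, batch, train = FALSE, record = TRUE)
  if (!target_layer %in% names(fw$cache)) {
    stop("unknown target layer '", target_layer, "'; available: ",
         paste(names(fw$cache), collapse = ", "))
  }
  act_node <- fw$cache[[target_layer]]
  logits <- fw$logits
  probs <- 1 / (1 + exp(-ag_value(logits)))
  sel <- (probs >= model$cfg$threshold) * 1
  if (sum(sel) == 0) sel <- sel + 1   # empty prediction: attribute all logits
  score <- ag_sum(ag_mul(logits, ag_const(sel)))
  ag_backward(score)
  act <- act_node$value
  gr <- act_node$grad
  if (is.null(gr)) gr <- act * 0
  d <- dim(act)
  B <- d[1]; C <- d[2]
  wts <- apply(gr, c(1, 2), mean)                       # (B, C)
  cam <- array(0, c(B, 1L, d[3], d[4]))
  for (b in seq_len(B)) {
    m <- matrix(0, d[3], d[4])
    for (cc in seq_len(C)) m <- m + wts[b, cc] * act[b, cc, , ]
    cam[b, 1, , ] <- pmax(m, 0)
  }
  H <- dim(ag_value(batch$pre))[3]; W <- dim(ag_value(batch$pre))[4]
  cam <- upsample_to(cam, H, W)
  for (b in seq_len(B)) {
    m <- cam[b, 1, , ]
    mx <- max(m)
    if (mx > 0) cam[b, 1, , ] <- (m - min(m)) / (mx - min(m))
  }
  cam
}

## ---- checkpoints -----------------------------------------------------------

#' Save model weights and config to a checkpoint file
#' @param model an `rst2g_model`.
#' @param path output `.rds` path.
#' @return the path, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  state <- lapply(params, function(p) p$value)
  bns <- collect_bn_states(model)
  saveRDS(list(cfg = model$cfg, params = state,
               bn = lapply(bns, function(s) list(m = s$running_mean, v = s$running_var))),
          path)
  invisible(path)
}

collect_bn_states <- function(x) {
  acc <- list()
  walk <- function(o) {
    if (is.list(o)) {
      if (inherits(o, "nn_batchnorm2d")) acc[[length(acc) + 1L]] <<- o$state
      else for (el in o) if (!is.null(el) && is.list(el)) walk(el)
    }
  }
  walk(x)
  acc
}

#' Load a model from a checkpoint file
#' @param path checkpoint written by [save_checkpoint()].
#' @return an `rst2g_model` with restored weights and batch-norm statistics.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- rst2g_model(ck$cfg)
  params <- collect_params(model)
  if (length(params) != length(ck$params)) stop("checkpoint does not match the config")
  for (i in seq_along(params)) params[[i]]$value <- ck$params[[i]]
  bns <- collect_bn_states(model)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- ck$bn[[i]]$m
    bns[[i]]$running_var <- ck$bn[[i]]$v
  }
  model
}
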