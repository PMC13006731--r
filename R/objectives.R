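# Hybrid training objective — Dice + weighted binary cross-entropy + Sobel
# boundary loss — and the overlap/volume evaluation metrics (Dice similarity
# coefficient, Jaccard index, relative volume difference).
#
# Every loss accepts plain arrays (returning a plain scalar) or ag_tensors
# (returning a differentiable scalar node); a single implementation serves
# evaluation and training.

as_loss <- function(out, plain) if (plain) ag_value(out) else out

check_coshaped <- function(p, g) {
  dp <- dim(ag_value(p)); dg <- dim(ag_value(g))
  if (is.null(dp)) dp <- length(ag_value(p))
  if (is.null(dg)) dg <- length(ag_value(g))
  if (!identical(dp, dg)) {
    stop("prediction and target shapes differ: ",
         paste(dp, collapse = "x"), " vs ", paste(dg, collapse = "x"))
  }
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`; zero when the
#' prediction equals the target, including the empty-vs-empty case where the
#' stabiliser makes the ratio exactly one.
#'
#' @param p predicted probabilities in [0, 1] (array or `ag_tensor`).
#' @param g binary ground truth of the same shape.
#' @param eps stabiliser (default 1e-6).
#' @return scalar in [0, 1].
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  check_coshaped(p, g)
  plain <- !is_ag(p) && !is_ag(g)
  p <- as_ag(p); g <- as_ag(g)
  num <- ag_add_const(ag_mul_const(ag_sum(ag_mul(p, g)), 2), eps)
  den <- ag_add_const(ag_add(ag_sum(p), ag_sum(g)), eps)
  as_loss(ag_sub(ag_const(1), ag_div(num, den)), plain)
}

#' Binary cross-entropy loss
#'
#' Probabilities are clamped to `[clip, 1 - clip]` before the logarithms.
#'
#' @inheritParams dice_loss
#' @param clip probability clamp (default 1e-7), must lie in (0, 0.5).
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, g, clip = 1e-7) {
  if (clip <= 0 || clip >= 0.5) stop("clip must lie in (0, 0.5)")
  check_coshaped(p, g)
  plain <- !is_ag(p) && !is_ag(g)
  p <- as_ag(p); g <- as_ag(g)
  pc <- ag_clamp(p, clip, 1 - clip)
  ll <- ag_add(ag_mul(g, ag_log(pc)),
               ag_mul(ag_add_const(ag_neg(g), 1),
                      ag_log(ag_add_const(ag_neg(pc), 1))))
  as_loss(ag_neg(ag_mean(ll)), plain)
}

#' The two fixed 3x3 Sobel kernels
#'
#' @return list with `gx` (horizontal gradient; column weights -1, 0, 1
#'   scaled by row weights 1, 2, 1) and `gy = t(gx)`. Each kernel sums to
#'   zero.
#' @export
sobel_kernels <- function() {
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  list(gx = gx, gy = t(gx))
}

to_b1hw <- function(x) {
  v <- ag_value(x)
  d <- dim(v)
  if (is.null(d) || length(d) == 2L) {
    x <- if (is_ag(x)) ag_reshape(x, c(1L, 1L, nrow(v), ncol(v))) else
      array(v, c(1L, 1L, nrow(v), ncol(v)))
  } else if (length(d) == 3L) {
    x <- if (is_ag(x)) ag_reshape(x, c(d[1], 1L, d[2], d[3])) else
      array(v, c(d[1], 1L, d[2], d[3]))
  }
  x
}

sobel_ag <- function(x4) {
  k <- sobel_kernels()
  wx <- ag_const(array(k$gx, c(1L, 1L, 3L, 3L)))
  wy <- ag_const(array(k$gy, c(1L, 1L, 3L, 3L)))
  xp <- ag_pad_replicate1(as_ag(x4))
  list(gx = ag_conv2d(xp, wx, NULL, pad = 0L),
       gy = ag_conv2d(xp, wy, NULL, pad = 0L))
}

#' Sobel gradients of a 2D map
#'
#' Valid correlation with the two 3x3 kernels after replicate padding, so
#' shape is preserved.
#'
#' @param img 2D numeric matrix with both dims >= 3.
#' @return list with matrices `gx`, `gy`.
#' @export
sobel_gradients <- function(img) {
  if (length(dim(img)) != 2L) stop("img must be a 2D matrix")
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop("image too small for 3x3 Sobel kernels: ", nrow(img), "x", ncol(img))
  }
  g <- sobel_ag(to_b1hw(img))
  list(gx = ag_value(g$gx)[1, 1, , ], gy = ag_value(g$gy)[1, 1, , ])
}

#' Sobel boundary loss
#'
#' Mean absolute difference between the Sobel gradient maps of prediction and
#' target, summed over the horizontal and vertical directions; applied per
#' slice and averaged over all voxels. Zero for identical inputs and for any
#' pair of constant images, and invariant to adding a constant to both.
#'
#' @inheritParams dice_loss
#' @return non-negative scalar.
#' @export
boundary_loss <- function(p, g) {
  check_coshaped(p, g)
  plain <- !is_ag(p) && !is_ag(g)
  p4 <- to_b1hw(if (plain) p else as_ag(p))
  g4 <- to_b1hw(if (plain) g else as_ag(g))
  sp <- sobel_ag(p4)
  sg <- sobel_ag(g4)
  out <- ag_add(ag_mean(ag_abs(ag_sub(sp$gx, sg$gx))),
                ag_mean(ag_abs(ag_sub(sp$gy, sg$gy))))
  as_loss(out, plain)
}

#' Loss weights for the hybrid objective
#' @param lambda BCE weight in [0, 1] (default 0.5).
#' @param beta boundary weight in [0, 1] (default 0.2).
#' @param eps Dice stabiliser.
#' @param clip BCE probability clamp.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda = 0.5, beta = 0.2, eps = 1e-6, clip = 1e-7) {
  if (lambda < 0 || lambda > 1 || beta < 0 || beta > 1) {
    stop("lambda and beta must lie in [0, 1]")
  }
  if (eps <= 0) stop("eps must be positive")
  if (clip <= 0 || clip >= 0.5) stop("clip must lie in (0, 0.5)")
  structure(list(lambda = lambda, beta = beta, eps = eps, clip = clip),
            class = "loss_weights")
}

#' Combine precomputed loss components
#' @param dice,bce,boundary scalar component values.
#' @param w a `loss_weights`.
#' @return `dice + lambda * bce + beta * boundary`.
#' @export
combine_losses <- function(dice, bce, boundary, w = loss_weights()) {
  plain <- !is_ag(dice)
  dice <- as_ag(dice)
  out <- ag_add(dice, ag_add(ag_mul_const(as_ag(bce), w$lambda),
                             ag_mul_const(as_ag(boundary), w$beta)))
  as_loss(out, plain)
}

#' Hybrid segmentation loss: Dice + lambda BCE + beta boundary
#'
#' @inheritParams dice_loss
#' @param w a `loss_weights` (defaults: lambda 0.5, beta 0.2).
#' @return scalar loss.
#' @export
total_loss <- function(p, g, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  combine_losses(dice_loss(p, g, w$eps), bce_loss(p, g, w$clip),
                 boundary_loss(p, g), w)
}

## ---- evaluation metrics ----------------------------------------------------

mask_counts <- function(P, G) {
  P <- if (inherits(P, "dce_volume")) P$voxels else ag_value(P)
  G <- if (inherits(G, "dce_volume")) G$voxels else ag_value(G)
  if (!identical(dim(P), dim(G))) stop("masks are not co-shaped")
  if (!all(P %in% c(0, 1)) || !all(G %in% c(0, 1))) stop("masks must be binary")
  list(i = sum(P * G), p = sum(P), g = sum(G))
}

#' Dice similarity coefficient between binary masks
#'
#' `2|P&G| / (|P| + |G|)`; the empty-vs-empty case is defined as 1 (perfect
#' agreement).
#'
#' @param P predicted binary mask (array or `dce_volume`).
#' @param G ground-truth binary mask of the same shape.
#' @return scalar in [0, 1].
#' @export
dsc <- function(P, G) {
  m <- mask_counts(P, G)
  if (m$p + m$g == 0) return(1)
  2 * m$i / (m$p + m$g)
}

#' Jaccard index between binary masks
#' @inheritParams dsc
#' @return scalar in [0, 1]; empty-vs-empty defined as 1.
#' @export
ji <- function(P, G) {
  m <- mask_counts(P, G)
  u <- m$p + m$g - m$i
  if (u == 0) return(1)
  m$i / u
}

#' Relative volume difference
#'
#' `(|P| - |G|) / |G|`; requires a nonempty ground truth.
#'
#' @inheritParams dsc
#' @return scalar >= -1.
#' @export
rvd <- function(P, G) {
  m <- mask_counts(P, G)
  if (m$g == 0) stop("RVD is undefined for an empty ground-truth mask")
  (m$p - m$g) / m$g
}
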