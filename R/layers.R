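# Layer constructors: each returns a plain list holding ag_param tensors (and,
# for batch norm, an environment with running statistics). Forward functions
# take the module plus an ag_tensor and return an ag_tensor, so the same code
# path serves inference and training.

he_init <- function(n, fan_in, gain = sqrt(2)) {
  stats::rnorm(n, sd = gain / sqrt(fan_in))
}

#' Create a 2D convolution layer
#'
#' Kernel weights use He initialisation; stride is 1 and padding defaults to
#' "same" for odd kernels.
#'
#' @param cin,cout input/output channel counts.
#' @param k square kernel size (default 3).
#' @param bias include a per-channel bias (default TRUE).
#' @return a module list with `$w` (and optionally `$b`) parameter tensors.
#' @export
new_conv2d <- function(cin, cout, k = 3L, bias = TRUE) {
  w <- array(he_init(cout * cin * k * k, cin * k * k), c(cout, cin, k, k))
  mod <- list(w = ag_param(w), b = if (bias) ag_param(numeric(cout)) else NULL,
              k = as.integer(k))
  class(mod) <- c("nn_conv2d", "nn_module")
  mod
}

conv2d_fwd <- function(mod, x, pad = NULL) {
  ag_conv2d(x, mod$w, mod$b, pad = pad)
}

#' Create a batch-normalisation layer
#' @param c channel count.
#' @return a module list with `gamma`, `beta` parameters and running statistics.
#' @export
new_batchnorm2d <- function(c) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- list(shared = numeric(c))
  state$running_var <- list(shared = rep(1, c))
  mod <- list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)), state = state)
  class(mod) <- c("nn_batchnorm2d", "nn_module")
  mod
}

bn_fwd <- function(mod, x, train = FALSE, key = "shared") {
  ag_batchnorm2d(x, mod$gamma, mod$beta, mod$state, train, key)
}

#' Create a layer-normalisation layer over the embedding dim
#' @param d embedding dimension.
#' @return module list.
#' @export
new_layernorm <- function(d) {
  mod <- list(gamma = ag_param(rep(1, d)), beta = ag_param(numeric(d)))
  class(mod) <- c("nn_layernorm", "nn_module")
  mod
}

ln_fwd <- function(mod, z) ag_layernorm(z, mod$gamma, mod$beta)

#' Create a token-wise linear layer
#' @param din,dout input/output dimensions.
#' @param bias include bias.
#' @return module list.
#' @export
new_linear <- function(din, dout, bias = TRUE) {
  w <- matrix(he_init(din * dout, din, gain = 1), din, dout)
  mod <- list(w = ag_param(w), b = if (bias) ag_param(numeric(dout)) else NULL)
  class(mod) <- c("nn_linear", "nn_module")
  mod
}

linear3_fwd <- function(mod, z) ag_linear3(z, mod$w, mod$b)

## ---- parameter bookkeeping -------------------------------------------------

#' Collect all trainable parameter tensors in a module tree
#'
#' Walks nested lists and returns every `ag_tensor` marked as requiring a
#' gradient, deduplicated by identity so shared (tied) weights appear once.
#'
#' @param x a module, list of modules, or model.
#' @return list of `ag_tensor` parameters.
#' @export
collect_params <- function(x) {
  acc <- new.env(parent = emptyenv())
  walk <- function(o) {
    if (is_ag(o)) {
      if (o$requires) acc[[as.character(o$id)]] <- o
    } else if (is.list(o)) {
      for (el in o) if (!is.null(el)) walk(el)
    }
  }
  walk(x)
  out <- as.list(acc)
  out[order(as.integer(names(out)))]
}

#' Count trainable parameters
#' @param x module tree.
#' @return integer total number of scalar parameters.
#' @export
count_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), 1))
}

## ---- optimiser -------------------------------------------------------------

#' Create an Adam optimiser
#'
#' Classic Adam with decoupled-from-schedule L2 weight decay added to the
#' gradient (the convention of the reference deep-learning stacks).
#'
#' @param params list of parameter tensors (from [collect_params()]).
#' @param lr learning rate (default 1e-3).
#' @param weight_decay L2 coefficient (default 1e-4).
#' @param betas first/second moment decay rates.
#' @param eps numerical stabiliser.
#' @return optimiser object (environment).
#' @export
new_adam <- function(params, lr = 1e-3, weight_decay = 1e-4,
                     betas = c(0.9, 0.999), eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$wd <- weight_decay
  opt$b1 <- betas[1]; opt$b2 <- betas[2]
  opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  class(opt) <- "adam_optimizer"
  opt
}

#' Apply one Adam update using accumulated gradients
#' @param opt optimiser from [new_adam()].
#' @return invisibly, the optimiser.
#' @export
adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + opt$wd * p$value
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(opt)
}

#' Recalibrate batch-norm running statistics ("precise BN")
#'
#' Running means/variances lag the activations of a network whose weights are
#' still moving; after training, an exact pass over representative batches
#' replaces them with the average batch statistics. Resets every BN state,
#' then runs `forward_fn(batch)` in training mode with an expanding-average
#' momentum.
#'
#' @param model module tree containing batch-norm layers.
#' @param batches list of batches.
#' @param forward_fn function invoked as `forward_fn(batch)`; it must run the
#'   model in training mode.
#' @return invisibly, the model.
#' @export
recalibrate_bn <- function(model, batches, forward_fn) {
  states <- collect_bn_states(model)
  for (s in states) {
    s$running_mean <- lapply(s$running_mean, function(m) m * 0)
    s$running_var <- lapply(s$running_var, function(v) v * 0)
  }
  for (i in seq_along(batches)) {
    for (s in states) s$momentum <- 1 / i
    forward_fn(batches[[i]])
  }
  for (s in states) s$momentum <- NULL
  invisible(model)
}
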