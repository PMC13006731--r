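# Training loop, patient-level stratified cross-validation, volume-level
# prediction with slice stitching, cohort evaluation and the ablation runner.

#' Training hyperparameters
#'
#' Defaults follow the published protocol: Adam, learning rate 1e-3, weight
#' decay 1e-4, batches of 4 consecutive slices, no data augmentation.
#'
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay L2 coefficient (> 0).
#' @param batch_size slices per batch (B >= 1).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation Dice (ignored when
#'   no validation studies are supplied).
#' @param seed RNG seed controlling batch shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         batch_size = 4L, epochs = 10L, patience = 10L,
                         seed = 1L) {
  if (learning_rate <= 0 || weight_decay <= 0) stop("lr and weight decay must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

tumor_volumes <- function(studies) {
  vapply(studies, function(s) sum(s$mask$voxels) * prod(s$mask$spacing), 1)
}

#' Patient-level stratified train/test split with k folds
#'
#' Holds out `test_frac` of the patients, then partitions the remainder into
#' k folds. Both steps stratify on tumor-volume quantile so every fold sees
#' small and large tumors; no patient ever crosses a fold or the train/test
#' boundary. Deterministic per seed.
#'
#' @param studies list of `dce_study` (cohort).
#' @param k number of folds (default 5).
#' @param test_frac held-out test fraction (default 0.3).
#' @param n_strata number of tumor-volume quantile bins (default 2).
#' @param seed RNG seed.
#' @return a `fold_split`: `test_ids`, `folds` (list of k patient-id vectors),
#'   `strata` (named stratum labels).
#' @export
split_patients <- function(studies, k = 5L, test_frac = 0.3, n_strata = 2L,
                           seed = 1L) {
  ids <- vapply(studies, function(s) s$pre$patient_id, "")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  vols <- tumor_volumes(studies)
  qs <- stats::quantile(vols, probs = seq(0, 1, length.out = n_strata + 1L))
  strata <- cut(vols, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  strata[is.na(strata)] <- 1L
  names(strata) <- ids
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  test_ids <- character(0)
  train_ids <- character(0)
  for (s in sort(unique(strata))) {
    sids <- sample(ids[strata == s])
    n_test <- round(length(sids) * test_frac)
    test_ids <- c(test_ids, sids[seq_len(n_test)])
    train_ids <- c(train_ids, if (n_test > 0) sids[-seq_len(n_test)] else sids)
  }
  if (length(train_ids) < k) {
    stop("only ", length(train_ids), " training patients for k = ", k, " folds")
  }
  folds <- rep(list(character(0)), k)
  i <- 0L
  for (s in sort(unique(strata))) {
    for (id in sample(train_ids[strata[train_ids] == s])) {
      folds[[i %% k + 1L]] <- c(folds[[i %% k + 1L]], id)
      i <- i + 1L
    }
  }
  structure(list(test_ids = sort(test_ids), folds = lapply(folds, sort),
                 strata = strata, k = k, test_frac = test_frac),
            class = "fold_split")
}

#' Select studies from a cohort by patient id
#' @param studies list of `dce_study`.
#' @param ids character vector of patient ids (e.g. from a `fold_split`).
#' @return the matching studies, in the order of `ids`.
#' @export
studies_by_id <- function(studies, ids) {
  all_ids <- vapply(studies, function(s) s$pre$patient_id, "")
  studies[match(ids, all_ids)]
}

## ---- training --------------------------------------------------------------

batch_masks <- function(study, batches) {
  mv <- study$mask$voxels
  S <- dim(mv)[1]
  lapply(batches, function(b) {
    take <- c(b$slice_indices, rep(S, b$n_pad))
    a <- mv[take, , , drop = FALSE]
    array(a, c(length(take), 1L, dim(mv)[2], dim(mv)[3]))
  })
}

training_pool <- function(studies, B) {
  pool <- list()
  for (s in studies) {
    bs <- assemble_slice_batches(s, B)
    ms <- batch_masks(s, bs)
    for (i in seq_along(bs)) {
      pool[[length(pool) + 1L]] <- list(batch = bs[[i]], mask = ms[[i]])
    }
  }
  pool
}

#' Train a model on a set of studies
#'
#' Batches are B consecutive slices of a single study (never mixed across
#' patients, since inter-slice attention reads the batch axis as adjacent
#' slices). Every Adam step minimises the hybrid Dice/BCE/boundary loss; the
#' full per-step loss history is recorded. Before any eval-mode inference
#' (validation scoring, and once after the final epoch) the batch-norm
#' running statistics are recalibrated over the training batches (exact
#' "precise BN" averaging) so inference matches the trained network.
#' Reproducible per seed.
#'
#' @param model an `rst2g_model` (modified in place; also returned).
#' @param studies training `dce_study` list.
#' @param cfg a `train_config`.
#' @param val_studies optional validation studies; when supplied, early
#'   stopping monitors their mean Dice with `cfg$patience`.
#' @param checkpoint_path optional path; the (best, if validating) weights
#'   are saved there.
#' @param verbose print per-epoch progress.
#' @return list: `model`, `history` (data.frame step/epoch/loss), `val_dsc`
#'   (per-epoch validation Dice or NULL), `epochs_run`.
#' @export
train_model <- function(model, studies, cfg = train_config(), val_studies = NULL,
                        checkpoint_path = NULL, verbose = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  pool <- training_pool(studies, cfg$batch_size)
  if (!length(pool)) stop("no training batches")
  params <- collect_params(model)
  opt <- new_adam(params, lr = cfg$learning_rate, weight_decay = cfg$weight_decay)
  w <- loss_weights(model$cfg$lambda, model$cfg$beta)
  history <- data.frame(step = integer(0), epoch = integer(0), loss = numeric(0))
  val_dsc <- if (!is.null(val_studies)) numeric(0)
  best <- -Inf; stall <- 0L; step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    for (i in sample(seq_along(pool))) {
      item <- pool[[i]]
      ag_zero_grad(params)
      fw <- forward_ag(model, item$batch, train = TRUE)
      probs <- ag_sigmoid(fw$logits)
      loss <- total_loss(probs, ag_const(item$mask), w)
      lv <- ag_value(loss)
      if (!is.finite(lv)) {
        stop("non-finite loss at step ", step + 1L,
             " (epoch ", epoch, "); try a smaller learning rate")
      }
      ag_backward(loss)
      adam_step(opt)
      step <- step + 1L
      history[step, ] <- list(step, epoch, lv)
    }
    msg <- sprintf("epoch %d/%d  mean loss %.4f", epoch, cfg$epochs,
                   mean(history$loss[history$epoch == epoch]))
    if (!is.null(val_studies)) {
      recalibrate_bn(model, pool, function(it) forward_ag(model, it$batch, train = TRUE))
      ev <- evaluate_model(model, val_studies)
      vd <- ev$summary$mean[ev$summary$metric == "dsc"]
      val_dsc <- c(val_dsc, vd)
      msg <- paste0(msg, sprintf("  val DSC %.3f", vd))
      if (vd > best + 1e-6) {
        best <- vd; stall <- 0L
        if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
      } else {
        stall <- stall + 1L
      }
      if (verbose) message(msg)
      if (stall >= cfg$patience) break
    } else {
      if (verbose) message(msg)
    }
  }
  if (is.null(val_studies)) {
    recalibrate_bn(model, pool, function(it) forward_ag(model, it$batch, train = TRUE))
    if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  }
  list(model = model, history = history, val_dsc = val_dsc, epochs_run = max(history$epoch))
}

## ---- prediction ------------------------------------------------------------

#' Predict a binary tumor mask for a whole study
#'
#' Slice batches are assembled, run through the network in eval mode, padded
#' slices dropped, slices stitched in order and probabilities thresholded
#' (>= threshold, ties to foreground).
#'
#' @param model a trained `rst2g_model`.
#' @param study a `dce_study`.
#' @param B slices per batch during inference (default 4).
#' @param return_probabilities also return the stitched probability volume.
#' @return predicted mask as a `dce_volume`; with `return_probabilities`, a
#'   list `(mask, probabilities)`.
#' @export
predict_volume <- function(model, study, B = 4L, return_probabilities = FALSE) {
  dim0 <- dim(study$pre$voxels)
  batches <- assemble_slice_batches(study, B)
  probs <- array(0, dim0)
  for (b in batches) {
    out <- rst2g_forward(model, b)
    keep <- seq_along(b$slice_indices)
    probs[b$slice_indices, , ] <- out$probabilities[keep, 1, , ]
  }
  mask <- dce_volume((probs >= model$cfg$threshold) * 1, study$pre$spacing,
                     study$pre$patient_id)
  if (return_probabilities) {
    list(mask = mask, probabilities = dce_volume(probs, study$pre$spacing,
                                                 study$pre$patient_id))
  } else {
    mask
  }
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a model (or precomputed masks) on studies
#'
#' Reports per-study Dice, Jaccard and relative volume difference plus the
#' cohort mean and SD (SD is 0 for a single study). Studies with an empty
#' ground-truth mask are skipped with a warning since RVD is undefined there.
#'
#' @param model an `rst2g_model`, or NULL when `masks` are supplied.
#' @param studies list of `dce_study`.
#' @param masks optional list of predicted mask `dce_volume`s (bypasses
#'   prediction).
#' @param csv_path optional path; the per-study table is written as CSV with
#'   the summary rows appended.
#' @return list: `per_study` data.frame (patient_id, dsc, ji, rvd) and
#'   `summary` data.frame (metric, mean, sd).
#' @export
evaluate_model <- function(model, studies, masks = NULL, csv_path = NULL) {
  rows <- list()
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    if (sum(s$mask$voxels) == 0) {
      warning("study ", s$pre$patient_id,
              " has an empty ground-truth mask; skipped (RVD undefined)")
      next
    }
    pm <- if (is.null(masks)) predict_volume(model, s) else masks[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = s$pre$patient_id,
      dsc = dsc(pm$voxels, s$mask$voxels),
      ji = ji(pm$voxels, s$mask$voxels),
      rvd = rvd(pm$voxels, s$mask$voxels), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no evaluable studies (all ground-truth masks empty)")
  per_study <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  summary <- data.frame(metric = c("dsc", "ji", "rvd"),
                        mean = c(mean(per_study$dsc), mean(per_study$ji),
                                 mean(per_study$rvd)),
                        sd = c(sd0(per_study$dsc), sd0(per_study$ji),
                               sd0(per_study$rvd)))
  if (!is.null(csv_path)) {
    utils::write.csv(per_study, csv_path, row.names = FALSE)
    utils::write.csv(summary, sub("\\.csv$", "_summary.csv", csv_path),
                     row.names = FALSE)
  }
  list(per_study = per_study, summary = summary)
}

## ---- ablation --------------------------------------------------------------

#' Train and evaluate ablation variants under identical conditions
#'
#' Every variant is built, trained and evaluated with the same seed, studies
#' and hyperparameters, so rows differ only in architecture.
#'
#' @param train_studies,test_studies study lists.
#' @param cfg a full `rst2g_config`.
#' @param tcfg a `train_config`.
#' @param variants subset of [rst2g_variants()] (default: all five).
#' @param verbose print progress.
#' @return data.frame: variant, n_params, mean/sd of DSC and JI, mean RVD.
#' @export
run_ablation <- function(train_studies, test_studies, cfg, tcfg = train_config(),
                         variants = rst2g_variants(), verbose = FALSE) {
  rows <- lapply(variants, function(v) {
    model <- build_variant(cfg, v)   # errors on unknown variant
    fit <- train_model(model, train_studies, tcfg, verbose = FALSE)
    ev <- evaluate_model(fit$model, test_studies)
    if (verbose) message(sprintf("%-10s DSC %.3f", v,
                                 ev$summary$mean[ev$summary$metric == "dsc"]))
    data.frame(variant = v, n_params = count_params(model),
               dsc_mean = ev$summary$mean[1], dsc_sd = ev$summary$sd[1],
               ji_mean = ev$summary$mean[2], ji_sd = ev$summary$sd[2],
               rvd_mean = ev$summary$mean[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
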