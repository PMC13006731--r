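# Volume / study data model, NIfTI IO, residual computation, intensity
# normalisation and slice-batch assembly for dynamic contrast-enhanced MRI.
#
# Conventions: voxel arrays are (slice, row, col); the slice axis is the
# batching axis fed to the network. Spacing is a positive mm triple in the
# same axis order. Indices are 1-based throughout (R convention).

#' Construct an MR volume
#'
#' @param voxels rank-3 numeric array ordered (slice, row, col); all finite.
#' @param spacing positive mm triple (slice, row, col), default 1 mm isotropic.
#' @param patient_id character label.
#' @return a `dce_volume` object.
#' @export
dce_volume <- function(voxels, spacing = c(1, 1, 1), patient_id = "") {
  if (length(dim(voxels)) != 3L) {
    stop("voxels must be a rank-3 array (slice, row, col), got rank ",
         length(dim(voxels)))
  }
  if (!all(is.finite(voxels))) stop("voxels contain non-finite values")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be a strictly positive mm triple")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id)),
            class = "dce_volume")
}

#' @export
print.dce_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dce_volume %s: %d x %d x %d, spacing %s mm>\n",
              if (nzchar(x$patient_id)) x$patient_id else "(unnamed)",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

check_aligned <- function(a, b, what = "volumes") {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop(what, " are not co-registered: shapes ",
         paste(dim(a$voxels), collapse = "x"), " vs ",
         paste(dim(b$voxels), collapse = "x"))
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop(what, " are not co-registered: spacings differ")
  }
  invisible(TRUE)
}

#' Voxel-wise residual between post- and pre-contrast volumes
#'
#' The residual (post minus pre) highlights contrast uptake; it may contain
#' negative values. Inputs must be co-registered: no silent resampling.
#'
#' @param pre,post co-registered `dce_volume`s.
#' @return a `dce_volume` holding `post - pre`.
#' @export
compute_residual <- function(pre, post) {
  check_aligned(pre, post, "pre/post volumes")
  dce_volume(post$voxels - pre$voxels, pre$spacing, pre$patient_id)
}

#' Min-max normalise a volume to [0, 1]
#'
#' Constant volumes map to all zeros (degenerate case by decision).
#'
#' @param v a `dce_volume`.
#' @return normalised `dce_volume`.
#' @export
normalize_volume <- function(v) {
  x <- v$voxels
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  dce_volume(y, v$spacing, v$patient_id)
}

#' Construct a DCE study from co-registered volumes
#'
#' Pre and post volumes are min-max normalised before the residual is formed,
#' so the residual lies in [-1, 1]. With several post-contrast phases the
#' residual uses `phase_index_used` (default 1, the earliest enhancement).
#'
#' @param pre pre-contrast `dce_volume`.
#' @param posts a `dce_volume` or list of 1-5 post-contrast `dce_volume`s.
#' @param mask binary tumor mask `dce_volume` (values in \{0, 1\}).
#' @param phase_index_used 1-based index of the post phase feeding the residual.
#' @return a `dce_study` object.
#' @export
dce_study <- function(pre, posts, mask, phase_index_used = 1L) {
  if (inherits(posts, "dce_volume")) posts <- list(posts)
  if (length(posts) < 1L || length(posts) > 5L) {
    stop("a study needs 1-5 post-contrast volumes, got ", length(posts))
  }
  for (p in posts) check_aligned(pre, p, "study volumes")
  check_aligned(pre, mask, "mask and image volumes")
  mv <- mask$voxels
  if (!all(mv %in% c(0, 1))) {
    bad <- unique(mv[!(mv %in% c(0, 1))])
    stop("mask is not binary; offending values include ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  phase_index_used <- as.integer(phase_index_used)
  if (phase_index_used < 1L || phase_index_used > length(posts)) {
    stop("phase_index_used must be in 1..", length(posts))
  }
  residual <- compute_residual(normalize_volume(pre),
                               normalize_volume(posts[[phase_index_used]]))
  structure(list(pre = pre, posts = posts, residual = residual, mask = mask,
                 phase_index_used = phase_index_used),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  d <- dim(x$pre$voxels)
  cat(sprintf("<dce_study %s: %d x %d x %d, %d post phase(s), phase used %d, tumor voxels %d>\n",
              x$pre$patient_id, d[1], d[2], d[3], length(x$posts),
              x$phase_index_used, sum(x$mask$voxels)))
  invisible(x)
}

## ---- NIfTI IO --------------------------------------------------------------

#' Write a volume to NIfTI
#'
#' Arrays are stored with NIfTI axes (col, row, slice) so the on-disk file is
#' a conventional x/y/z image; [read_volume()] inverts the layout.
#'
#' @param v a `dce_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(aperm(v$voxels, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#' @param path NIfTI file path.
#' @param patient_id label attached to the volume.
#' @return a `dce_volume` with (slice, row, col) voxel order.
#' @export
read_volume <- function(path, patient_id = "") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume at ", path)
  dce_volume(aperm(a, c(3, 2, 1)), rev(RNifti::pixdim(img)[1:3]), patient_id)
}

#' Write a binary mask volume to NIfTI
#' @param mask a strictly binary `dce_volume`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask$voxels %in% c(0, 1))) stop("mask is not binary")
  write_volume(mask, path)
}

#' Load a study from NIfTI files
#'
#' @param pre_path pre-contrast NIfTI path.
#' @param post_paths character vector of 1-5 post-contrast paths.
#' @param mask_path binary mask path.
#' @param patient_id label.
#' @param phase_index_used post phase feeding the residual (1-based).
#' @return a `dce_study`.
#' @export
load_study <- function(pre_path, post_paths, mask_path, patient_id = "",
                       phase_index_used = 1L) {
  pre <- read_volume(pre_path, patient_id)
  posts <- lapply(post_paths, read_volume, patient_id = patient_id)
  mask <- read_volume(mask_path, patient_id)
  mask$voxels <- round(mask$voxels)   # guard against float quantisation only
  dce_study(pre, posts, mask, phase_index_used)
}

#' Write a cohort of studies as NIfTI files plus a manifest
#'
#' Creates `<id>_pre.nii.gz`, `<id>_post<k>.nii.gz`, `<id>_mask.nii.gz` under
#' `dir` and a `manifest.csv` with columns patient_id, pre_path, post_paths
#' (semicolon separated) and mask_path.
#'
#' @param studies list of `dce_study`.
#' @param dir output directory (created if missing).
#' @return manifest path, invisibly.
#' @export
write_cohort <- function(studies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(studies, function(s) {
    id <- s$pre$patient_id
    pre_p <- file.path(dir, paste0(id, "_pre.nii.gz"))
    write_volume(s$pre, pre_p)
    post_ps <- character(length(s$posts))
    for (k in seq_along(s$posts)) {
      post_ps[k] <- file.path(dir, paste0(id, "_post", k, ".nii.gz"))
      write_volume(s$posts[[k]], post_ps[k])
    }
    mask_p <- file.path(dir, paste0(id, "_mask.nii.gz"))
    write_mask(s$mask, mask_p)
    data.frame(patient_id = id, pre_path = pre_p,
               post_paths = paste(post_ps, collapse = ";"),
               mask_path = mask_p, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Load a cohort from a manifest CSV
#' @param manifest_path path to a manifest written by [write_cohort()].
#' @param phase_index_used post phase feeding the residual.
#' @return list of `dce_study`.
#' @export
load_cohort <- function(manifest_path, phase_index_used = 1L) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    load_study(m$pre_path[i], strsplit(m$post_paths[i], ";", fixed = TRUE)[[1]],
               m$mask_path[i], m$patient_id[i], phase_index_used)
  })
}

## ---- slice batches ---------------------------------------------------------

#' Assemble consecutive slice batches from a study
#'
#' The network consumes stacks of B consecutive 2D slices per branch, the
#' batch dimension doubling as the slice axis. Pre and the selected post are
#' min-max normalised per volume; the residual is their difference. The final
#' window is padded by edge-slice replication and the padding recorded so
#' stitching can drop it.
#'
#' @param study a `dce_study`.
#' @param B slices per batch (default 4).
#' @param pad allow replication-padding of a short final window (default TRUE).
#' @return list of `slice_batch` objects, each with `pre`, `post`, `res`
#'   tensors of shape (B, 1, H, W), `slice_indices` and `n_pad`.
#' @export
assemble_slice_batches <- function(study, B = 4L, pad = TRUE) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  pre_n <- normalize_volume(study$pre)$voxels
  post_n <- normalize_volume(study$posts[[study$phase_index_used]])$voxels
  res <- study$residual$voxels
  S <- dim(pre_n)[1]
  if (!pad && S %% B != 0L) {
    stop("volume has ", S, " slices, not a multiple of B = ", B,
         ", and padding is disabled")
  }
  if (!pad && B > S) stop("B = ", B, " exceeds slice count ", S, " with padding disabled")
  n_batches <- ceiling(S / B)
  lapply(seq_len(n_batches), function(i) {
    idx <- ((i - 1L) * B + 1L):min(i * B, S)
    n_pad <- B - length(idx)
    take <- c(idx, rep(S, n_pad))
    to4 <- function(vol) {
      a <- vol[take, , , drop = FALSE]
      array(a, c(B, 1L, dim(vol)[2], dim(vol)[3]))
    }
    structure(list(pre = to4(pre_n), post = to4(post_n), res = to4(res),
                   slice_indices = idx, n_pad = n_pad),
              class = "slice_batch")
  })
}
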