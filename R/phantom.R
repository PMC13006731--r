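# Synthetic DCE-MRI phantom cohort generator: smooth baseline anatomy, a
# contrast-enhancing ellipsoidal tumor and additive Gaussian acquisition
# noise, so the whole pipeline is exercisable without any image download.

#' Specify a DCE phantom
#'
#' Defaults mirror a clinical breast DCE study: 60 slices of 256 x 256, a
#' tumor that roughly doubles in intensity after contrast (enhancement factor
#' 1), mild parenchymal background enhancement, and low acquisition noise.
#'
#' @param shape volume dims (slices, rows, cols).
#' @param background_level mean baseline tissue intensity (arbitrary units).
#' @param tissue_texture_sd standard deviation of the smooth tissue texture.
#' @param texture_smooth Gaussian smoothing sd of the texture field, voxels.
#' @param tumor_center ellipsoid centre, 1-based voxel triple (slice, row, col).
#' @param tumor_radii ellipsoid radii in voxels (slice, row, col).
#' @param enhancement_factor relative post-contrast intensity gain inside the
#'   tumor: post = pre * (1 + factor).
#' @param background_enhancement relative gain outside the tumor (>= 0).
#' @param noise_sd additive Gaussian noise sd, applied independently to pre
#'   and post acquisitions.
#' @param n_posts number of post-contrast phases to synthesise (1-5; later
#'   phases share the plateau enhancement, differing only in noise).
#' @param seed RNG seed making the phantom fully reproducible.
#' @param patient_id label.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(60L, 256L, 256L),
                         background_level = 0.35,
                         tissue_texture_sd = 0.05,
                         texture_smooth = 3,
                         tumor_center = NULL,
                         tumor_radii = NULL,
                         enhancement_factor = 1.0,
                         background_enhancement = 0.1,
                         noise_sd = 0.02,
                         n_posts = 1L,
                         seed = 1L,
                         patient_id = "phantom") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be three positive dims")
  if (is.null(tumor_center)) tumor_center <- (shape + 1) / 2
  if (is.null(tumor_radii)) tumor_radii <- pmax(1, shape / 8)
  if (any(tumor_radii <= 0)) stop("tumor radii must be positive")
  if (any(tumor_center - tumor_radii < 1) || any(tumor_center + tumor_radii > shape)) {
    stop("tumor ellipsoid extends outside the volume")
  }
  if (enhancement_factor < 0 || background_enhancement < 0 || noise_sd < 0) {
    stop("enhancement factors and noise_sd must be non-negative")
  }
  if (n_posts < 1L || n_posts > 5L) stop("n_posts must be 1-5")
  structure(list(shape = shape, background_level = background_level,
                 tissue_texture_sd = tissue_texture_sd,
                 texture_smooth = texture_smooth,
                 tumor_center = as.numeric(tumor_center),
                 tumor_radii = as.numeric(tumor_radii),
                 enhancement_factor = enhancement_factor,
                 background_enhancement = background_enhancement,
                 noise_sd = noise_sd, n_posts = as.integer(n_posts),
                 seed = as.integer(seed), patient_id = patient_id),
            class = "phantom_spec")
}

# separable Gaussian smoothing with replicate edges, along every axis
smooth_field <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (t in -r:r) out <- out + kern[t + r + 1L] * m[idx(seq_len(n) + t), , drop = FALSE]
    a <- aperm(array(out, d[perm]), order(perm))
  }
  a
}

ellipsoid_mask <- function(shape, center, radii) {
  s <- (seq_len(shape[1]) - center[1]) / radii[1]
  r <- (seq_len(shape[2]) - center[2]) / radii[2]
  cc <- (seq_len(shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(s^2, r^2, "+"), cc^2, "+")
  (d2 <= 1) * 1
}

#' Generate a synthetic DCE study from a phantom spec
#'
#' The pre-contrast volume is a smooth textured background; each post-contrast
#' volume scales it by `1 + enhancement_factor` inside the tumor ellipsoid and
#' `1 + background_enhancement` elsewhere, with independent Gaussian noise on
#' every acquisition. The mask is exact ellipsoid membership. Deterministic
#' given the spec seed.
#'
#' @param spec a `phantom_spec`.
#' @return a `dce_study`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  d <- spec$shape
  texture <- array(stats::rnorm(prod(d)), d)
  texture <- smooth_field(texture, spec$texture_smooth)
  sdt <- stats::sd(texture)
  if (sdt > 0) texture <- texture / sdt * spec$tissue_texture_sd
  pre_clean <- pmax(spec$background_level + texture, 0)
  tumor <- ellipsoid_mask(d, spec$tumor_center, spec$tumor_radii)
  gain <- 1 + spec$background_enhancement +
    (spec$enhancement_factor - spec$background_enhancement) * tumor
  pre_obs <- pre_clean + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
  posts <- lapply(seq_len(spec$n_posts), function(k) {
    dce_volume(pre_clean * gain + array(stats::rnorm(prod(d), sd = spec$noise_sd), d),
               patient_id = spec$patient_id)
  })
  dce_study(dce_volume(pre_obs, patient_id = spec$patient_id), posts,
            dce_volume(tumor, patient_id = spec$patient_id))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a reproducible cohort of phantom studies
#'
#' Per-patient geometry and enhancement are drawn uniformly from the stated
#' ranges; tumor radii vary so tumor volume spreads across patients, enabling
#' volume-stratified splitting. Patient ids are unique.
#'
#' @param n_patients number of studies (>= 2).
#' @param spec_ranges named list of `c(min, max)` ranges overriding defaults;
#'   recognised names: `radius_frac` (tumor radius as a fraction of each dim),
#'   `enhancement_factor`, `background_enhancement`, `noise_sd`,
#'   `center_jitter_frac` (centre offset as a fraction of each dim).
#' @param seed cohort RNG seed; per-patient seeds derive from it.
#' @param shape volume dims shared by the cohort.
#' @param id_prefix prefix for patient ids.
#' @return list of `dce_study`.
#' @export
generate_cohort <- function(n_patients, spec_ranges = list(), seed = 1L,
                            shape = c(60L, 256L, 256L), id_prefix = "P") {
  if (n_patients < 2L) stop("a cohort needs at least 2 patients")
  defaults <- list(radius_frac = c(0.10, 0.22),
                   enhancement_factor = c(0.8, 1.2),
                   background_enhancement = c(0.05, 0.15),
                   noise_sd = c(0.015, 0.025),
                   center_jitter_frac = c(-0.08, 0.08))
  unknown <- setdiff(names(spec_ranges), names(defaults))
  if (length(unknown)) stop("unknown spec_ranges entries: ", paste(unknown, collapse = ", "))
  rng <- utils::modifyList(defaults, spec_ranges)
  for (nm in names(rng)) {
    if (length(rng[[nm]]) != 2L || rng[[nm]][2] < rng[[nm]][1]) {
      stop("range for ", nm, " must be c(min, max)")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shape <- as.integer(shape)
  lapply(seq_len(n_patients), function(i) {
    runif2 <- function(r) stats::runif(1, r[1], r[2])
    radii <- pmax(1, shape * c(runif2(rng$radius_frac), runif2(rng$radius_frac),
                               runif2(rng$radius_frac)))
    jitter <- shape * c(runif2(rng$center_jitter_frac), runif2(rng$center_jitter_frac),
                        runif2(rng$center_jitter_frac))
    center <- pmin(pmax((shape + 1) / 2 + jitter, radii + 1), shape - radii)
    spec <- phantom_spec(shape = shape,
                         tumor_center = center, tumor_radii = radii,
                         enhancement_factor = runif2(rng$enhancement_factor),
                         background_enhancement = runif2(rng$background_enhancement),
                         noise_sd = runif2(rng$noise_sd),
                         seed = sample.int(.Machine$integer.max %/% 2L, 1L),
                         patient_id = sprintf("%s%03d", id_prefix, i))
    generate_phantom(spec)
  })
}
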