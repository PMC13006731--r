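# Volume data model, residual computation, normalisation, NIfTI round trips
# and slice-batch assembly.

test_that("compute_residual subtracts voxel-wise and enforces co-registration", {
  pre <- dce_volume(array(c(1, 2, 3, 4), c(1, 2, 2)))
  post <- dce_volume(array(c(2, 2, 5, 3), c(1, 2, 2)))
  r <- compute_residual(pre, post)
  expect_equal(r$voxels, array(c(1, 0, 2, -1), c(1, 2, 2)))
  # residual + pre == post to float precision
  expect_equal(r$voxels + pre$voxels, post$voxels, tolerance = 1e-15)
  # identity and zero-pre cases
  expect_true(all(compute_residual(pre, pre)$voxels == 0))
  zero <- dce_volume(array(0, c(1, 2, 2)))
  expect_equal(compute_residual(zero, post)$voxels, post$voxels)
  # misalignment is rejected, never silently resampled
  expect_error(compute_residual(pre, dce_volume(array(0, c(1, 2, 3)))), "co-registered")
  expect_error(compute_residual(pre, dce_volume(array(0, c(1, 2, 2)), spacing = c(2, 1, 1))),
               "co-registered")
})

test_that("normalize_volume min-max scales to [0,1] with constant volumes at zero", {
  v <- dce_volume(array(c(2, 4, 6, 4), c(1, 2, 2)))
  expect_equal(sort(unique(as.vector(normalize_volume(v)$voxels))), c(0, 0.5, 1))
  cst <- dce_volume(array(7, c(2, 3, 3)))
  expect_true(all(normalize_volume(cst)$voxels == 0))
  spanning <- dce_volume(array(seq(0, 1, length.out = 8), c(2, 2, 2)))
  nv <- normalize_volume(spanning)$voxels
  expect_equal(range(nv), c(0, 1))
  expect_equal(nv, spanning$voxels)
})

test_that("dce_study validates members and builds the residual from the selected phase", {
  set.seed(1)
  base <- array(runif(2 * 4 * 4), c(2, 4, 4))
  pre <- dce_volume(base, patient_id = "A")
  posts <- lapply(1:3, function(k) dce_volume(base * (1 + 0.2 * k), patient_id = "A"))
  mask <- dce_volume((base > 0.5) * 1, patient_id = "A")
  st <- dce_study(pre, posts, mask, phase_index_used = 1L)
  expected <- normalize_volume(posts[[1]])$voxels - normalize_volume(pre)$voxels
  expect_equal(st$residual$voxels, expected)
  st3 <- dce_study(pre, posts, mask, phase_index_used = 3L)
  expect_equal(st3$residual$voxels,
               normalize_volume(posts[[3]])$voxels - normalize_volume(pre)$voxels)
  # non-binary masks and bad phase indices are rejected
  expect_error(dce_study(pre, posts, dce_volume(mask$voxels + mask$voxels)), "binary")
  expect_error(dce_study(pre, posts, mask, phase_index_used = 4L), "phase_index_used")
  expect_error(dce_study(pre, list(), mask), "1-5")
})

test_that("NIfTI round trip preserves voxels bit-exactly and spacing to float precision", {
  set.seed(2)
  v <- dce_volume(array(rnorm(3 * 5 * 4), c(3, 5, 4)), spacing = c(2.5, 0.7, 0.7),
                  patient_id = "RT")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, "RT")
  expect_identical(dim(v2$voxels), dim(v$voxels))
  expect_identical(as.vector(v2$voxels), as.vector(v$voxels))
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(write_mask(v, tempfile(fileext = ".nii")), "binary")
})

test_that("cohort write/load round trip reproduces studies including multi-phase residuals", {
  st <- make_phantom_study(shape = c(4L, 16L, 16L), seed = 5, id = "C1", n_posts = 3L)
  st2 <- make_phantom_study(shape = c(4L, 16L, 16L), seed = 6, id = "C2")
  dir <- tempfile("cohort")
  manifest <- file.path(dir, "manifest.csv")
  write_cohort(list(st, st2), dir)
  back <- load_cohort(manifest)
  expect_length(back, 2L)
  expect_equal(back[[1]]$pre$voxels, st$pre$voxels, tolerance = 1e-12)
  expect_length(back[[1]]$posts, 3L)
  expect_equal(back[[1]]$mask$voxels, st$mask$voxels)
  expect_equal(back[[2]]$residual$voxels, st2$residual$voxels, tolerance = 1e-12)
  # a corrupted (non-binary) mask file is rejected at load time
  bad <- dce_volume(st$mask$voxels * 2, patient_id = "C1")
  write_volume(bad, file.path(dir, "C1_mask.nii.gz"))
  expect_error(load_cohort(manifest), "binary")
})

test_that("slice batches form consecutive windows with recorded edge padding", {
  vox <- array(rep(seq_len(60), each = 1), c(60, 8, 8))
  for (i in seq_len(60)) vox[i, , ] <- i
  st <- dce_study(dce_volume(vox, patient_id = "S"),
                  dce_volume(vox * 1.5, patient_id = "S"),
                  dce_volume((vox > 30) * 1, patient_id = "S"))
  b4 <- assemble_slice_batches(st, 4L)
  expect_length(b4, 15L)
  expect_equal(b4[[1]]$slice_indices, 1:4)
  expect_equal(b4[[15]]$slice_indices, 57:60)
  expect_true(all(vapply(b4, function(b) b$n_pad, 1L) == 0L))
  expect_length(assemble_slice_batches(st, 1L), 60L)
  # short cohort: 7 slices, B = 4 -> second window padded with one edge slice
  st7 <- dce_study(dce_volume(vox[1:7, , , drop = FALSE], patient_id = "S7"),
                   dce_volume(vox[1:7, , , drop = FALSE] * 2, patient_id = "S7"),
                   dce_volume(array(0, c(7, 8, 8)) , patient_id = "S7"))
  b7 <- assemble_slice_batches(st7, 4L)
  expect_length(b7, 2L)
  expect_equal(b7[[2]]$slice_indices, 5:7)
  expect_equal(b7[[2]]$n_pad, 1L)
  expect_equal(dim(b7[[2]]$pre), c(4L, 1L, 8L, 8L))
  # padded slice replicates the edge slice
  expect_equal(b7[[2]]$pre[4, 1, , ], b7[[2]]$pre[3, 1, , ])
  expect_error(assemble_slice_batches(st7, 4L, pad = FALSE), "padding")
  # slice order is recoverable: slice i of the pre volume carries value i
  got <- unlist(lapply(b4, function(b) {
    vapply(seq_along(b$slice_indices), function(k) {
      # normalised value maps back to the slice index
      b$pre[k, 1, 1, 1] * 59 + 1
    }, 1)
  }))
  expect_equal(round(got), 1:60)
})
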