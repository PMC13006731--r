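# Hybrid loss components (Dice, BCE, Sobel boundary) and the overlap/volume
# metrics, against closed-form arithmetic.

test_that("dice_loss satisfies its closed-form identities", {
  z <- array(0, c(2, 1, 4, 4))
  expect_equal(dice_loss(z, z), 0)                      # empty vs empty, eps/eps
  g <- z; g[1, 1, 1:2, 1:2] <- 1
  expect_equal(dice_loss(g, g), 0, tolerance = 1e-6)    # binary identity
  # |P & G| = 2, |P| = 4, |G| = 4 -> 1 - (2*2)/(4+4) = 0.5
  # P = {(1,1),(2,2),(1,2),(1,3)}, G = {(1,1),(2,2),(2,1),(3,1)}
  p <- z; p[1, 1, 1, 1] <- 1; p[1, 1, 2, 2] <- 1; p[1, 1, 1, 2] <- 1; p[1, 1, 1, 3] <- 1
  g2 <- z; g2[1, 1, 1, 1] <- 1; g2[1, 1, 2, 2] <- 1; g2[1, 1, 2, 1] <- 1; g2[1, 1, 3, 1] <- 1
  expect_equal(dice_loss(p, g2, eps = 1e-6), 0.5, tolerance = 1e-6)
  expect_error(dice_loss(p, array(0, c(1, 1, 4, 4))), "differ")
})

test_that("bce_loss reproduces hand arithmetic and the p = 0.5 constant", {
  g <- array(c(1, 0, 1, 0), c(1, 1, 2, 2))
  p_half <- array(0.5, c(1, 1, 2, 2))
  expect_equal(bce_loss(p_half, g), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(p_half, g * 0), log(2), tolerance = 1e-12)
  # binary p = g after clamping: loss <= -log(1 - clip) ~ clip
  expect_lt(bce_loss(g, g), 1e-6)
  # N = 2, p = (0.9, 0.1), g = (1, 0) -> -(log 0.9 + log 0.9)/2 = -log 0.9
  p2 <- array(c(0.9, 0.1), c(1, 1, 1, 2))
  g2 <- array(c(1, 0), c(1, 1, 1, 2))
  expect_equal(bce_loss(p2, g2), -log(0.9), tolerance = 1e-9)
  expect_error(bce_loss(p2, g2, clip = 0.7), "clip")
})

test_that("sobel kernels and gradients follow the directional convention", {
  k <- sobel_kernels()
  expect_equal(sum(k$gx), 0)
  expect_equal(sum(k$gy), 0)
  expect_equal(k$gy, t(k$gx))
  # constant image: both gradients identically zero
  gz <- sobel_gradients(matrix(3.7, 5, 6))
  expect_true(all(gz$gx == 0) && all(gz$gy == 0))
  # horizontal unit ramp I(r, c) = c: interior gx = 8, gy = 0
  ramp <- matrix(rep(1:6, each = 5), 5, 6)
  gr <- sobel_gradients(ramp)
  expect_true(all(gr$gx[2:4, 2:5] == 8))
  expect_true(all(gr$gy == 0))
  # transposing the image swaps the directional maps
  set.seed(501)
  img <- matrix(rnorm(30), 5, 6)
  gi <- sobel_gradients(img)
  gt <- sobel_gradients(t(img))
  expect_equal(gt$gx, t(gi$gy), tolerance = 1e-12)
  expect_equal(gt$gy, t(gi$gx), tolerance = 1e-12)
  expect_error(sobel_gradients(matrix(0, 2, 5)), "too small")
})

test_that("boundary_loss vanishes on identical or constant inputs and matches brute force", {
  set.seed(502)
  p <- matrix(runif(25), 5, 5)
  expect_equal(boundary_loss(p, p), 0)
  expect_equal(boundary_loss(matrix(2, 5, 5), matrix(7, 5, 5)), 0, tolerance = 1e-12)
  # invariance to adding a constant to both inputs
  g <- matrix(runif(25), 5, 5)
  expect_equal(boundary_loss(p, g), boundary_loss(p + 3, g + 3), tolerance = 1e-10)
  # 5x5 toy masks differing in one edge pixel vs direct convolution + L1
  pm <- matrix(0, 5, 5); pm[2:4, 2:4] <- 1
  gm <- pm; gm[2, 4] <- 0
  k <- sobel_kernels()
  pad <- function(m) m[c(1, 1:5, 5), c(1, 1:5, 5)]
  conv_valid <- function(m, kk) {
    out <- matrix(0, 5, 5)
    mp <- pad(m)
    for (i in 1:5) for (j in 1:5) out[i, j] <- sum(mp[i:(i + 2), j:(j + 2)] * kk)
    out
  }
  expected <- mean(abs(conv_valid(pm, k$gx) - conv_valid(gm, k$gx))) +
    mean(abs(conv_valid(pm, k$gy) - conv_valid(gm, k$gy)))
  expect_equal(boundary_loss(pm, gm), expected, tolerance = 1e-10)
})

test_that("total_loss combines components with the published weights", {
  w <- loss_weights(lambda = 0.5, beta = 0.2)
  expect_equal(combine_losses(0.5, 0.2, 0.1, w), 0.62, tolerance = 1e-12)
  expect_equal(combine_losses(1, 0, 0, w), 1)
  expect_equal(combine_losses(0, 0, 0, w), 0)
  expect_error(loss_weights(lambda = 1.2), "lambda")
  expect_error(loss_weights(beta = -0.1), "lambda and beta")
  # total_loss equals the sum of its components
  set.seed(503)
  p <- array(runif(32), c(2, 1, 4, 4))
  g <- array(rbinom(32, 1, 0.4), c(2, 1, 4, 4))
  expect_equal(total_loss(p, g, w),
               dice_loss(p, g) + 0.5 * bce_loss(p, g) + 0.2 * boundary_loss(p, g),
               tolerance = 1e-10)
  # monotone non-decreasing in each component weight
  expect_gte(combine_losses(0.5, 0.3, 0.1, loss_weights(lambda = 1)),
             combine_losses(0.5, 0.3, 0.1, loss_weights(lambda = 0.1)))
})

test_that("overlap metrics match set arithmetic including degenerate cases", {
  m <- array(0, c(2, 3, 3))
  g <- m; g[1, 1:2, 1] <- 1
  expect_equal(dsc(g, g), 1)
  expect_equal(ji(g, g), 1)
  expect_equal(rvd(g, g), 0)
  # empty vs empty defined as perfect agreement
  expect_equal(dsc(m, m), 1)
  expect_equal(ji(m, m), 1)
  expect_error(rvd(m, m), "empty")
  # disjoint nonempty masks
  p <- m; p[2, 3, 3] <- 1
  expect_equal(dsc(p, g), 0)
  expect_equal(ji(p, g), 0)
  # |P & G| = 1, |P| = |G| = 2 -> DSC 0.5, JI 1/3
  p2 <- m; p2[1, 1, 1] <- 1; p2[1, 3, 3] <- 1
  g2 <- m; g2[1, 1, 1] <- 1; g2[2, 2, 2] <- 1
  expect_equal(dsc(p2, g2), 0.5)
  expect_equal(ji(p2, g2), 1 / 3)
  # |P| = 6, |G| = 4 -> RVD 0.5
  p3 <- array(0, c(2, 3, 3)); p3[1:6] <- 1
  g3 <- array(0, c(2, 3, 3)); g3[1:4] <- 1
  expect_equal(rvd(p3, g3), 0.5)
  expect_error(dsc(p3, g3 + 0.5), "binary")
})

test_that("DSC = 2 JI / (1 + JI) and dice_loss + dsc ~ 1 on random mask pairs", {
  set.seed(504)
  for (i in 1:100) {
    P <- array(rbinom(27, 1, runif(1, 0.2, 0.8)), c(3, 3, 3))
    G <- array(rbinom(27, 1, runif(1, 0.2, 0.8)), c(3, 3, 3))
    j <- ji(P, G)
    expect_equal(dsc(P, G), 2 * j / (1 + j), tolerance = 1e-12)
  }
  P <- array(rbinom(64, 1, 0.5), c(4, 4, 4))
  G <- array(rbinom(64, 1, 0.5), c(4, 4, 4))
  if (sum(P) + sum(G) > 0) {
    expect_equal(dice_loss(P, G, eps = 1e-12) + dsc(P, G), 1, tolerance = 1e-8)
  }
})
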