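# Spatiotemporal graph enhancement: GAT coefficients, inter-slice attention
# with batch-wise recalibration, and inter-temporal fusion.

test_that("gat_attention rows are normalised with correct degenerate cases", {
  set.seed(401)
  gm <- new_gat(3)
  # single node: alpha = 1 exactly
  z1 <- array(rnorm(3), c(1, 1, 3))
  expect_equal(as.vector(gat_attention(z1, gm)), 1)
  # identical node features: uniform 1/N attention
  zu <- array(rep(rnorm(3), each = 4), c(1, 4, 3))
  au <- gat_attention(zu, gm)
  expect_equal(as.vector(au), rep(1 / 4, 16), tolerance = 1e-12)
  # random instances: every row sums to one, all coefficients positive
  z <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  a <- gat_attention(z, gm)
  expect_true(all(a > 0))
  expect_true(all(abs(apply(a, c(1, 2), sum) - 1) < 1e-6))
})

test_that("gat attention and aggregation match the 3-node brute-force oracle", {
  set.seed(402)
  gm <- new_gat(3, 3)
  gm$W$value <- matrix(c(0.5, -0.2, 0.1, 1, 0.3, -0.7, 0.2, 0.8, -0.1), 3, 3)
  gm$a1$value <- matrix(c(0.4, -0.6, 0.2), 3, 1)
  gm$a2$value <- matrix(c(-0.3, 0.5, 0.9), 3, 1)
  Z <- matrix(rnorm(9), 3, 3)
  z <- array(Z, c(1, 3, 3))
  or <- oracle_gat_one(Z, gm$W$value, as.vector(gm$a1$value), as.vector(gm$a2$value))
  expect_equal(gat_attention(z, gm)[1, , ], or$alpha, tolerance = 1e-10)
  expect_equal(gat_layer(z, gm)[1, , ], or$out, tolerance = 1e-10)
})

test_that("gat_layer with uniform attention performs mean aggregation", {
  set.seed(403)
  gm <- new_gat(4)
  zu <- array(rep(rnorm(4), each = 5), c(1, 5, 4))   # identical nodes -> uniform alpha
  out <- gat_layer(zu, gm)
  for (i in 2:5) expect_equal(out[1, i, ], out[1, 1, ], tolerance = 1e-12)
})

test_that("batch_slice_attention gates elements in (0,1) and restores the layout", {
  set.seed(404)
  s <- new_isa(3)
  x <- array(rnorm(2 * 3 * 4 * 5), c(2, 3, 4, 5))
  out <- batch_slice_attention(x, s)
  expect_equal(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
  # zero conv weights: every gate is exactly 0.5
  s$batch_attn$w$value <- s$batch_attn$w$value * 0
  s$batch_attn$b$value <- s$batch_attn$b$value * 0
  expect_equal(batch_slice_attention(x, s), 0.5 * x, tolerance = 1e-12)
  # large bias drives every gate to ~1: the permute/reshape round trip is the identity
  s$batch_attn$b$value <- s$batch_attn$b$value + 50
  expect_equal(batch_slice_attention(x, s), x, tolerance = 1e-8)
})

test_that("isa preserves shape and composes conv, graph attention and recalibration", {
  set.seed(405)
  s <- new_isa(2)
  x <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
  for (m in c("pre", "post", "d")) {
    out <- isa(x, s, m)
    expect_equal(dim(out), dim(x))
  }
  # modality-specific conv transforms differ
  expect_gt(max(abs(isa(x, s, "pre") - isa(x, s, "post"))), 1e-6)
})

test_that("the full ISA -> ITA chain matches a straight-line implementation", {
  set.seed(406)
  C <- 2
  s <- new_isa(C)
  it <- new_ita(C)
  for (m in c("pre", "post", "d")) neutralize_bn(s$fconv[[m]])
  xs <- list(pre = array(rnorm(1 * C * 2 * 2), c(1, C, 2, 2)),
             post = array(rnorm(1 * C * 2 * 2), c(1, C, 2, 2)),
             d = array(rnorm(1 * C * 2 * 2), c(1, C, 2, 2)))
  # straight-line oracle
  oracle_isa <- function(x, m) {
    cb <- s$fconv[[m]]
    fh <- oracle_conv_bn_relu(x, cb$conv$w$value, cb$conv$b$value,
                              rep(1, C), rep(0, C), rep(0, C), rep(1 - 1e-5, C))
    # flatten raster row-major: token (h, w) -> (h-1)*W + w
    Z <- matrix(0, 4, C)
    k <- 1L
    for (h in 1:2) for (w in 1:2) { Z[k, ] <- fh[1, , h, w]; k <- k + 1L }
    g <- oracle_gat_one(Z, s$gat$W$value, as.vector(s$gat$a1$value),
                        as.vector(s$gat$a2$value))$out
    fg <- array(0, c(1, C, 2, 2))
    k <- 1L
    for (h in 1:2) for (w in 1:2) { fg[1, , h, w] <- g[k, ]; k <- k + 1L }
    # batch-slice recalibration: a 1x1 conv is layout-invariant
    wgt <- sigmoid(naive_conv2d(fg, s$batch_attn$w$value, s$batch_attn$b$value, pad = 0L))
    fg * wgt
  }
  es <- lapply(names(xs), function(m) oracle_isa(xs[[m]], m))
  cat3 <- array(0, c(1, 3 * C, 2, 2))
  for (i in 1:3) cat3[, (i - 1) * C + seq_len(C), , ] <- es[[i]]
  h1 <- pmax(naive_conv2d(cat3, it$mlp1$w$value, it$mlp1$b$value, pad = 0L), 0)
  fused <- naive_conv2d(h1, it$mlp2$w$value, it$mlp2$b$value, pad = 0L)
  a <- sigmoid(naive_conv2d(fused, it$attn$w$value, it$attn$b$value, pad = 0L))
  expected <- fused * a[, rep(1, C), , , drop = FALSE]

  got <- ita(isa(xs$pre, s, "pre"), isa(xs$post, s, "post"), isa(xs$d, s, "d"), it)
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("ita obeys the attenuation bound and forced-zero algebra", {
  set.seed(407)
  it <- new_ita(3)
  xs <- lapply(1:3, function(i) array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4)))
  out <- ita(xs[[1]], xs[[2]], xs[[3]], it)
  expect_equal(dim(out), c(2L, 3L, 4L, 4L))
  it$mlp1$w$value <- it$mlp1$w$value * 0
  it$mlp1$b$value <- it$mlp1$b$value * 0
  it$mlp2$w$value <- it$mlp2$w$value * 0
  it$mlp2$b$value <- it$mlp2$b$value * 0
  expect_true(all(ita(xs[[1]], xs[[2]], xs[[3]], it) == 0))
  expect_error(ita(xs[[1]], xs[[2]], array(0, c(1, 3, 4, 4)), it), "share shape")
})
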