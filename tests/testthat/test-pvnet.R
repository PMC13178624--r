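test_that("RoPE at position zero is the identity", {
  q <- withr::with_seed(1, matrix(rnorm(12), 3, 4))
  expect_equal(rope_rotate(q, positions = c(0, 0, 0)), q, tolerance = 1e-15)
})

test_that("RoPE rotations are isometries", {
  for (D in c(4, 16, 32, 48, 64)) {
    x <- withr::with_seed(D, matrix(rnorm(8 * D), 8, D))
    r <- rope_rotate(x, positions = withr::with_seed(D + 1,
                                                     sample(0:50, 8)))
    expect_equal(sqrt(rowSums(r^2)), sqrt(rowSums(x^2)), tolerance = 1e-12)
  }
})

test_that("RoPE inner products depend only on relative position", {
  for (D in c(8, 16, 64)) {
    q <- withr::with_seed(D, rnorm(D))
    k <- withr::with_seed(D + 100, rnorm(D))
    for (s in c(1, 5, 17)) {
      m <- 3; n <- 11
      d1 <- sum(rope_rotate(matrix(q, 1), m) *
                  rope_rotate(matrix(k, 1), n))
      d2 <- sum(rope_rotate(matrix(q, 1), m + s) *
                  rope_rotate(matrix(k, 1), n + s))
      expect_equal(d1, d2, tolerance = 1e-9)
    }
  }
})

test_that("RoPE rejects odd dimensions", {
  expect_error(rope_rotate(matrix(rnorm(6), 2, 3), c(0, 1)),
               class = "sawoce_config")
})

test_that("EAA with one token returns its own global query", {
  Q <- matrix(withr::with_seed(2, rnorm(6)), 1, 6)
  K <- matrix(withr::with_seed(3, rnorm(6)), 1, 6)
  out <- eaa(Q, K, w_a = rep(0.3, 6))
  # alpha = 1 exactly, q = Q, output = K * Q + Q under the identity projection
  expect_equal(as.vector(out[1, ]), as.vector(K * Q + Q),
               tolerance = 1e-14)
})

test_that("EAA attention weights normalize and match a naive loop", {
  N <- 7; D <- 6
  Q <- withr::with_seed(10, matrix(rnorm(N * D), N, D))
  K <- withr::with_seed(11, matrix(rnorm(N * D), N, D))
  wa <- withr::with_seed(12, rnorm(D))
  Wo <- withr::with_seed(13, matrix(rnorm(D * D), D, D))
  bo <- withr::with_seed(14, rnorm(D))
  out <- eaa(Q, K, wa, Wo, bo)
  # naive loop oracle
  s <- numeric(N)
  for (i in 1:N) s[i] <- sum(Q[i, ] * wa) / sqrt(D)
  a <- exp(s) / sum(exp(s))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  q <- numeric(D)
  for (i in 1:N) q <- q + a[i] * Q[i, ]
  oracle <- matrix(0, N, D)
  for (i in 1:N) {
    g <- K[i, ] * q
    for (d in 1:D) oracle[i, d] <- sum(g * Wo[, d]) + bo[d] + Q[i, d]
  }
  expect_equal(unclass(out), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(eaa(Q, K[1:3, ], wa), class = "sawoce_config")
})

test_that("EAA cost grows linearly in the token count", {
  D <- 16
  for (N in c(8, 64, 256)) {
    expect_equal(eaa_ops(2 * N, D) / eaa_ops(N, D), 2)
  }
  # attribute matches the closed form for an actual call
  Q <- matrix(rnorm(32 * D), 32, D)
  out <- eaa(Q, Q, rnorm(D))
  expect_equal(attr(out, "ops"), eaa_ops(32, D))
})

test_that("ConvEncoder is a residual block with a shape contract", {
  x <- withr::with_seed(20, array(rnorm(8 * 16 * 16), c(8, 16, 16)))
  p <- conv_encoder_init_seeded(16, expansion = 2, seed = 1)
  out <- conv_encoder(x, p)
  expect_equal(dim(out), dim(x))
  # zero final projection: pure residual
  p0 <- p
  p0[["ce.pw2.W"]][] <- 0
  p0[["ce.pw2.b"]][] <- 0
  expect_equal(conv_encoder(x, p0), x, tolerance = 1e-14)
  expect_error(conv_encoder(array(rnorm(8 * 8 * 4), c(8, 8, 4)), p),
               class = "sawoce_config")
})

test_that("gradients reach every ConvEncoder parameter", {
  x <- withr::with_seed(21, array(rnorm(6 * 5 * 2 * 4), c(6, 5, 2, 4)))
  p <- conv_encoder_init_seeded(4, expansion = 2, seed = 2)
  names(p) <- sub("^ce", "blk", names(p))
  fwd <- sawoce:::conv_encoder_fwd(p, "blk", x, training = TRUE,
                                   run_stats = NULL)
  bwd <- sawoce:::conv_encoder_bwd(p, "blk", fwd$cache,
                                   array(1, dim(x)))
  expect_setequal(names(bwd$grads), names(p))
  for (nm in names(p)) {
    expect_gt(max(abs(bwd$grads[[nm]])), 0)
  }
})

test_that("block backward passes agree with finite differences", {
  x <- withr::with_seed(30, array(rnorm(5 * 4 * 2 * 4), c(5, 4, 2, 4)))
  dl <- withr::with_seed(31, array(rnorm(5 * 4 * 2 * 4), c(5, 4, 2, 4)))
  checks <- list(
    conv_encoder = list(
      params = conv_encoder_init_seeded(4, 2, seed = 3),
      fwd = function(p) sawoce:::conv_encoder_fwd(p, "ce", x, TRUE, NULL),
      bwd = function(p, cache) sawoce:::conv_encoder_bwd(p, "ce", cache, dl)),
    swiftformer = list(
      params = swiftformer_init_seeded(4, seed = 4),
      fwd = function(p) sawoce:::swiftformer_fwd(p, "sf", x, TRUE, NULL),
      bwd = function(p, cache) sawoce:::swiftformer_bwd(p, "sf", cache, dl)))
  for (chk in checks) {
    loss <- function(p) sum(chk$fwd(p)$out * dl)
    r <- chk$fwd(chk$params)
    g <- chk$bwd(chk$params, r$cache)$grads
    for (nm in names(g)) {
      i <- withr::with_seed(nchar(nm), sample(length(g[[nm]]), 1))
      eps <- 1e-5
      p2 <- chk$params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- chk$params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("SwiftFormer block preserves shape and is position sensitive", {
  x <- withr::with_seed(22, array(rnorm(6 * 6 * 8), c(6, 6, 8)))
  p <- swiftformer_init_seeded(8, seed = 5)
  out <- swiftformer_block(x, p)
  expect_equal(dim(out), dim(x))
  # permute spatial positions: a positional encoding must change the output
  perm <- withr::with_seed(23, sample(6))
  out_perm <- swiftformer_block(x[perm, , ], p)
  expect_gt(max(abs(out_perm[order(perm), , ] - out)), 1e-6)
})

test_that("the forward pass yields one finite deterministic scalar", {
  cfg <- pvnet_config("tiny")
  m <- pvnet(cfg, seed = 1)
  zero <- matrix(0, 64, 64)
  v <- predict(m, zero)
  expect_length(v, 1)
  expect_true(is.finite(v))
  img <- withr::with_seed(40, matrix(runif(64 * 64, -pi, pi), 64, 64))
  expect_identical(predict(m, img), predict(m, img))
  expect_error(predict(m, matrix(0, 32, 32)), class = "sawoce_config")
  expect_error(predict(m, matrix(c(NA, rep(0, 64 * 64 - 1)), 64, 64)),
               class = "sawoce_invariant")
})

test_that("tiny parameter count matches the analytic layer-by-layer total", {
  cfg <- pvnet_config("tiny")
  m <- pvnet(cfg, seed = 0)
  dims <- c(16, 32, 48, 64)
  conv3 <- function(ci, co) 9 * ci * co + co
  bn <- function(c) 2 * c
  lin <- function(i, o) i * o + o
  swift <- function(c) {
    (9 * c + c) +            # depthwise a
      lin(c, c) +            # pointwise a
      (c * c + c * c + c) +  # Wq, Wk, wa
      lin(c, c) +            # attention projection
      (9 * c + c) +          # depthwise b
      bn(c) +                # norm b
      lin(c, c)              # pointwise b
  }
  expected <- conv3(1, 8) + bn(8) + conv3(8, 16) + bn(16) +
    sum(vapply(dims, swift, numeric(1))) +
    conv3(dims[1], dims[2]) + bn(dims[2]) +
    conv3(dims[2], dims[3]) + bn(dims[3]) +
    conv3(dims[3], dims[4]) + bn(dims[4]) +
    lin(dims[4], 32) + lin(32, 1)
  expect_equal(n_parameters(m), expected)
})
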