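test_that("robust LOESS reproduces an exact line and a constant", {
  z <- 0:99
  line <- 2 + 0.01 * z
  prof <- velocity_profile(z, dz = 4.7, v_raw = line)
  sm <- rloess_smooth(prof, window = 30)
  expect_equal(sm$v_smooth, line, tolerance = 1e-9)
  const <- velocity_profile(z, dz = 4.7, v_raw = rep(3.5, 100))
  expect_equal(rloess_smooth(const, window = 30)$v_smooth, rep(3.5, 100),
               tolerance = 1e-9)
})

test_that("robust LOESS suppresses large sparse outliers", {
  z <- 0:99
  line <- 2 + 0.01 * z
  y <- line
  out_idx <- withr::with_seed(4, sample(100, 5))
  y[out_idx] <- y[out_idx] * 10
  sm <- rloess_smooth(velocity_profile(z, dz = 4.7, v_raw = y), window = 30)
  expect_lt(max(abs(sm$v_smooth - line) / line), 0.05)
})

test_that("smoothing requires enough points", {
  prof <- velocity_profile(0:9, dz = 4.7, v_raw = rep(3, 10))
  expect_error(rloess_smooth(prof, window = 30), class = "sawoce_config")
})

test_that("noiseless step profiles are segmented exactly", {
  prof <- velocity_profile(0:99, dz = 4.7,
                           v_raw = c(rep(5.5, 58), rep(3.1, 42)))
  fit <- fit_bilinear(prof, channel = "raw")
  expect_equal(fit$z_break, 58)
  expect_lt(fit$sse, 1e-9)
  expect_equal(fit$jump, 2.4, tolerance = 1e-9)
  expect_true(fit$has_interface)

  thin <- velocity_profile(0:99, dz = 4.7,
                           v_raw = c(rep(5.2, 29), rep(3.0, 71)))
  expect_equal(fit_bilinear(thin, channel = "raw")$z_break, 29)
})

test_that("segmentation matches a brute-force lm() oracle on noisy data", {
  z <- 0:79
  truth <- ifelse(z < 33, 5 - 0.008 * z, 2.9 + 0.004 * z)
  y <- truth + withr::with_seed(8, rnorm(80, sd = 0.12))
  prof <- velocity_profile(z, dz = 4.7, v_raw = pmax(y, 0.1))
  fit <- fit_bilinear(prof, min_segment = 5, channel = "raw")
  # oracle: explicit lm per candidate split
  best <- NULL
  yv <- prof$v_raw
  for (p in 5:75) {
    up <- lm(yv[1:p] ~ z[1:p])
    lo <- lm(yv[(p + 1):80] ~ z[(p + 1):80])
    sse <- sum(residuals(up)^2) + sum(residuals(lo)^2)
    if (is.null(best) || sse < best$sse) best <- list(p = p, sse = sse)
  }
  expect_equal(fit$z_break, z[best$p + 1])
  expect_equal(fit$sse, best$sse, tolerance = 1e-9)
})

test_that("the bilinear fit never loses to the single line", {
  for (i in 1:20) {
    y <- withr::with_seed(i, runif(40, 1, 8))
    prof <- velocity_profile(0:39, dz = 4.7, v_raw = y)
    fit <- fit_bilinear(prof, channel = "raw")
    expect_lte(fit$sse, fit$sse_single + 1e-9)
  }
})

test_that("velocity rescaling scales SSE quadratically, breakpoint fixed", {
  y <- withr::with_seed(3, c(rep(5, 30), rep(3, 30)) + rnorm(60, sd = 0.2))
  prof <- velocity_profile(0:59, dz = 4.7, v_raw = pmax(y, 0.1))
  f1 <- fit_bilinear(prof, channel = "raw")
  a <- 2.5
  prof2 <- velocity_profile(0:59, dz = 4.7, v_raw = prof$v_raw * a)
  f2 <- fit_bilinear(prof2, channel = "raw")
  expect_equal(f2$z_break, f1$z_break)
  expect_equal(f2$sse, a^2 * f1$sse, tolerance = 1e-9)
  expect_equal(f2$jump, a * f1$jump, tolerance = 1e-9)
})

test_that("breakpoints of noisy two-layer profiles are recovered", {
  hits <- 0
  for (seed in 0:19) {
    z_true <- withr::with_seed(300 + seed, sample(20:60, 1))
    v1 <- 5.4; v2 <- 3.2                       # contrast 1.7x
    truth <- ifelse(0:79 < z_true, v1, v2)
    y <- truth + withr::with_seed(seed, rnorm(80, sd = 0.05 * mean(truth)))
    prof <- velocity_profile(0:79, dz = 4.7, v_raw = pmax(y, 0.1))
    fit <- fit_bilinear(prof, channel = "raw")
    if (abs(fit$z_break - z_true) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("homogeneous profiles yield a no-interface verdict", {
  y <- 3.5 + withr::with_seed(5, rnorm(80, sd = 0.03))
  prof <- velocity_profile(0:79, dz = 4.7, v_raw = y)
  fit <- fit_bilinear(prof, channel = "raw")
  expect_false(fit$has_interface)
})

test_that("fit preconditions are enforced", {
  prof <- velocity_profile(0:5, dz = 4.7, v_raw = rep(3, 6))
  expect_error(fit_bilinear(prof, min_segment = 5), class = "sawoce_config")
  expect_error(fit_bilinear(prof, min_segment = 1), class = "sawoce_config")
})

test_that("depth indices convert to the printed physical depths", {
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  expect_equal(index_to_depth(35, 4.7), 0.1645, tolerance = 1e-12)
  expect_equal(round_half_up(index_to_depth(35, 4.7), 3), 0.165)
  expect_equal(round_half_up(index_to_depth(15, 4.7), 3), 0.071)
  expect_equal(index_to_depth(0, 4.7), 0)
})

test_that("tidy and glance summarize a fit", {
  prof <- velocity_profile(0:49, dz = 4.7,
                           v_raw = c(rep(5, 25), rep(3, 25)))
  fit <- fit_bilinear(prof, channel = "raw")
  td <- tidy(fit)
  expect_equal(td$segment, c("upper", "lower"))
  expect_equal(td$slope, c(fit$a1, fit$a2))
  gl <- glance(fit)
  expect_equal(gl$z_break, 25)
  expect_true(gl$has_interface)
})
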