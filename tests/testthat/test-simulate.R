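test_that("true profiles are piecewise constant over the configured layers", {
  single <- sim_config(shape = c(100, 32, 64), layers = list(c(100, 3.2)),
                       surface = 1)
  expect_equal(true_profile(single)$v_true, rep(3.2, 100))

  layered <- sim_config(shape = c(100, 32, 64),
                        layers = list(c(58, 5.5), c(42, 3.1)), surface = 1)
  tp <- true_profile(layered)
  expect_equal(tp$v_true[tp$depth_index < 58], rep(5.5, 58))
  expect_equal(tp$v_true[tp$depth_index >= 58], rep(3.1, 42))
  expect_equal(min(tp$depth_index[tp$v_true == 3.1]), 58)

  degen <- sim_config(shape = c(100, 32, 64),
                      layers = list(c(100, 3.2), c(0, 9)), surface = 1)
  expect_equal(true_profile(degen, 100)$v_true, rep(3.2, 100))
})

test_that("invalid configurations are rejected with the violated bound", {
  expect_error(sim_config(shape = c(64, 32, 64), layers = list(c(80, 3))),
               class = "sawoce_config")
  expect_error(sim_config(layers = list(c(64, -1))), class = "sawoce_config")
  expect_error(sim_config(shape = c(64, 32, 64), dt = 1, f0 = 4000),
               "Nyquist", class = "sawoce_config")
  expect_error(sim_config(shape = c(64, 32, 64), dx = 8.6,
                          layers = list(c(64, 0.01))),
               "Nyquist", class = "sawoce_config")
})

test_that("no excitation means no phase modulation", {
  cfg <- sim_preset("small", displacement_amp = 0, noise_sigma = 0)
  vol <- simulate_volume(cfg)
  stack <- extract_phase_stack(flatten_volume(vol, cfg$surface),
                               n_depths = 20)
  expect_equal(max(abs(stack$phase)), 0)
})

test_that("the temporal spectrum of the optical phase peaks at f0", {
  cfg <- sim_preset("small", layers = list(c(64, 3.2)), noise_sigma = 0)
  vol <- simulate_volume(cfg)
  # independent oracle: discrete FFT of the phase time series at a voxel
  # below the surface; 16 excitation cycles in 128 frames -> bin 17 (1-based)
  for (x in c(10, 60, 120)) {
    ts <- Arg(unclass(vol)[20, x, ])
    mag <- Mod(fft(ts - mean(ts)))
    expect_equal(which.max(mag[2:64]) + 1L, 17L)
  }
})

test_that("simulation is deterministic given the seed, noise is not shared", {
  cfg <- sim_preset("small", shape = c(16, 32, 64), surface = 4,
                    noise_sigma = 0.1, seed = 7)
  v1 <- simulate_volume(cfg)
  v2 <- simulate_volume(cfg)
  expect_identical(unclass(v1)[, , ], unclass(v2)[, , ])
  cfg2 <- sim_preset("small", shape = c(16, 32, 64), surface = 4,
                     noise_sigma = 0.1, seed = 8)
  v3 <- simulate_volume(cfg2)
  expect_false(identical(unclass(v1)[, , ], unclass(v3)[, , ]))
  # identical ground truth regardless of the noise seed
  expect_equal(true_profile(cfg)$v_true, true_profile(cfg2)$v_true)
})

# Demodulate the oscillating optical phase at f0: the complex coefficient
# F(x) = sum_t phi(z, x, t) exp(-2 pi i f0 t dt) carries the wave's spatial
# phase, which must advance linearly along x at 2 pi f0 dx / c.
lateral_wave_slope <- function(vol, cfg, z = 20) {
  Tn <- cfg$shape[3]
  kern <- exp(-2i * pi * cfg$f0 * (0:(Tn - 1)) * cfg$dt)
  Fx <- vapply(seq_len(cfg$shape[2]), function(x) {
    sum(Arg(unclass(vol)[z, x, ]) * kern)
  }, complex(1))
  ph <- Arg(Fx)
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  unwrapped <- cumsum(c(ph[1], dph))
  fit <- lm(unwrapped ~ seq_along(unwrapped))
  list(slope = unname(coef(fit)[2]), resid = max(abs(residuals(fit))))
}

test_that("noiseless lateral phase advances linearly at slope 2 pi f0 dx / c", {
  cfg <- sim_preset("small", layers = list(c(64, 4)), noise_sigma = 0)
  vol <- simulate_volume(cfg)
  r <- lateral_wave_slope(vol, cfg)
  expect_equal(r$slope, -2 * pi * cfg$f0 * cfg$dx * 1e-6 / 4,
               tolerance = 1e-9)
  expect_lt(r$resid, 1e-6)
})

test_that("faster layers have flatter lateral phase slopes", {
  slopes <- vapply(c(2, 3, 4, 5, 6, 8), function(cv) {
    cfg <- sim_preset("small", layers = list(c(64, cv)), noise_sigma = 0)
    abs(lateral_wave_slope(simulate_volume(cfg), cfg)$slope)
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("above the surface only noise remains", {
  cfg <- sim_preset("small", noise_sigma = 0.2, seed = 3)
  vol <- simulate_volume(cfg)
  above <- Mod(unclass(vol)[1:6, , ])   # surface sits at 8
  expect_lt(mean(above), 3 * 0.2)
  expect_gt(mean(Mod(unclass(vol)[9, , ])), 3 * mean(above))
})

test_that("training sets pair each depth with its layer's true velocity", {
  cfg <- sim_preset("small", layers = list(c(20, 5), c(44, 3)),
                    noise_sigma = 0.02, seed = 1)
  pairs <- make_training_set(cfg, depths_per_volume = 40,
                             image_size = c(32, 32), shuffle_seed = 5)
  expect_equal(nrow(pairs), 40)
  expect_setequal(unique(pairs$v_true), c(5, 3))
  expect_true(all(vapply(pairs$image, function(m) all(dim(m) == c(32, 32)),
                         logical(1))))
  # shuffling and noise are seed-isolated: same configs, other noise seed
  cfg2 <- sim_preset("small", layers = list(c(20, 5), c(44, 3)),
                     noise_sigma = 0.02, seed = 2)
  pairs2 <- make_training_set(cfg2, depths_per_volume = 40,
                              image_size = c(32, 32), shuffle_seed = 5)
  ord1 <- pairs[order(pairs$depth_index), ]
  ord2 <- pairs2[order(pairs2$depth_index), ]
  expect_equal(ord1$v_true, ord2$v_true)
  expect_false(identical(ord1$image[[1]], ord2$image[[1]]))
  # requesting more depths than the usable range is an error
  expect_error(make_training_set(cfg, depths_per_volume = 60),
               class = "sawoce_config")
})
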