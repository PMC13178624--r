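make_map <- function(S, k_axis, f_axis) {
  structure(list(S = S, k_axis = k_axis, f_axis = f_axis,
                 roi = c(k_min = min(k_axis), k_max = max(k_axis),
                         f_min = min(f_axis), f_max = max(f_axis))),
            class = "spectral_map")
}

test_that("auto_roi maps the velocity search band to a wavenumber window", {
  roi <- auto_roi(4000, 1, 20, 0.5)
  expect_equal(roi$roi_f, c(2000, 6000))
  expect_equal(roi$roi_k, c(100, 6000))
  expect_error(auto_roi(4000, 5, 5, 0.5), class = "sawoce_config")
  expect_error(auto_roi(4000, 1, 20, 0))
  # a vanishing band around an off-bin frequency leaves no padded bin
  cfg <- nsa_config(band = 1e-9)
  stack <- small_stack(3.2, noise_sigma = 0)
  expect_error(spectral_map(stack, 5, cfg, f0 = 4001),
               class = "sawoce_config")
})

test_that("centroid of a delta spectrum is f / k", {
  m <- make_map(matrix(5, 1, 1), k_axis = 1000, f_axis = 4000)
  expect_equal(centroid_velocity(m), 4.0)
})

test_that("the centroid is linear in the mass distribution", {
  m <- make_map(matrix(c(1, 1), 1, 2), k_axis = 1000,
                f_axis = c(3000, 5000))
  expect_equal(centroid_velocity(m), 4000 / 1000)
  m2 <- make_map(matrix(c(3, 1), 1, 2), k_axis = 1000,
                 f_axis = c(3000, 5000))
  expect_equal(centroid_velocity(m2), (0.75 * 3000 + 0.25 * 5000) / 1000)
})

test_that("centroid matches a brute-force double loop on random maps", {
  for (i in 1:100) {
    S <- withr::with_seed(i, matrix(runif(25), 5, 5))
    k <- sort(withr::with_seed(1000 + i, runif(5, 100, 6000)))
    f <- sort(withr::with_seed(2000 + i, runif(5, 2000, 6000)))
    num_f <- 0; num_k <- 0; den <- 0
    for (a in 1:5) for (b in 1:5) {
      num_k <- num_k + k[a] * S[a, b]
      num_f <- num_f + f[b] * S[a, b]
      den <- den + S[a, b]
    }
    oracle <- (num_f / den) / (num_k / den)
    expect_equal(centroid_velocity(make_map(S, k, f)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("centroid velocity is scale invariant and ROI contained", {
  S <- withr::with_seed(9, matrix(runif(30), 6, 5))
  k <- seq(500, 3000, length.out = 6)
  f <- seq(2500, 5500, length.out = 5)
  m <- make_map(S, k, f)
  v <- centroid_velocity(m)
  expect_equal(centroid_velocity(make_map(S * 137.5, k, f)), v,
               tolerance = 1e-12)
  expect_gte(v, min(f) / max(k))
  expect_lte(v, max(f) / min(k))
})

test_that("degenerate spectra raise typed errors", {
  expect_error(centroid_velocity(make_map(matrix(0, 2, 2), c(1, 2),
                                          c(1, 2))),
               class = "sawoce_degenerate")
})

test_that("a noiseless plane wave concentrates at (f0 / c, f0)", {
  c_true <- 3.2
  stack <- small_stack(c_true, noise_sigma = 0)
  m <- spectral_map(stack, 10, nsa_config())
  peak <- which(m$S == max(m$S), arr.ind = TRUE)[1, ]
  pad_x <- 2 * 128; pad_t <- 2 * 128   # pad_factor x next power of two
  k_bin <- 1 / (pad_x * stack$dx * 1e-6)
  f_bin <- 1 / (pad_t * stack$dt)
  expect_lt(abs(m$k_axis[peak[1]] - 4000 / c_true), k_bin + 1e-9)
  expect_lt(abs(m$f_axis[peak[2]] - 4000), f_bin + 1e-9)
})

test_that("an all-zero phase slice yields an empty map and a typed error", {
  stack <- small_stack(3.2, noise_sigma = 0)
  zero_stack <- stack
  zero_stack$phase <- array(0, dim(stack$phase))
  m <- spectral_map(zero_stack, 3, nsa_config(depth_radius = 0,
                                              energy_floor = 0))
  expect_equal(max(m$S), 0)
  expect_error(centroid_velocity(m), class = "sawoce_degenerate")
})

test_that("edge depths truncate the averaging window, not the profile", {
  stack <- small_stack(3.2, noise_sigma = 0, n_depths = 12)
  prof <- nsa_profile(stack, nsa_config(depth_radius = 2))
  expect_equal(nrow(prof), 12)
  expect_true(all(is.finite(prof$v_raw)))
  # the top-edge map equals the average over the 3 existing slices only
  maps <- sawoce:::nsa_slice_maps(stack, 1:3, nsa_config(), f0 = 4000)
  manual <- sawoce:::assemble_map(maps, 1:3, 0.5)
  via_api <- spectral_map(stack, 1, nsa_config())
  expect_equal(via_api$S, manual$S, tolerance = 1e-12)
})

test_that("homogeneous phantoms are recovered within 5 percent", {
  for (c_true in c(3.2, 5.3)) {
    prof <- nsa_profile(small_stack(c_true, noise_sigma = 0), nsa_config())
    expect_rel_error(mean(prof$v_raw), c_true, 0.05)
  }
})

test_that("a two-layer phantom recovers both layer velocities", {
  cfg <- sim_preset("small", layers = list(c(25, 5.5), c(39, 3.1)),
                    noise_sigma = 0.05, seed = 1)
  vol <- simulate_volume(cfg)
  stack <- extract_phase_stack(flatten_volume(vol, detect_surface(vol)),
                               n_depths = 50)
  prof <- nsa_profile(stack, nsa_config())
  upper <- prof$v_raw[prof$depth_index <= 25 - 7]
  lower <- prof$v_raw[prof$depth_index >= 25 + 6]
  expect_rel_error(median(upper), 5.5, 0.05)
  expect_rel_error(median(lower), 3.1, 0.05)
})

test_that("the complex-field input mode recovers the same velocity", {
  cfg <- sim_preset("small", layers = list(c(64, 3.2)), noise_sigma = 0,
                    seed = 0)
  vol <- simulate_volume(cfg)
  flat <- flatten_volume(vol, cfg$surface)
  stack_c <- extract_phase_stack(flat, n_depths = 20, type = "complex")
  prof <- nsa_profile(stack_c, nsa_config())
  expect_rel_error(mean(prof$v_raw, na.rm = TRUE), 3.2, 0.05)
})

test_that("recovered velocity increases strictly with the true velocity", {
  est <- vapply(c(2, 3, 4, 5, 6, 8), function(cv) {
    prof <- nsa_profile(small_stack(cv, noise_sigma = 0.05, seed = 11),
                        nsa_config())
    mean(prof$v_raw, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
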