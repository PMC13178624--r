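# Shared fixtures. Simulated volumes are memoised so several test files can
# reuse the same small acquisitions without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Homogeneous small-preset phase stack at velocity `c_true`.
small_stack <- function(c_true, noise_sigma = 0, seed = 0, n_depths = 40) {
  key <- sprintf("stack_%g_%g_%d_%d", c_true, noise_sigma, seed, n_depths)
  cached(key, {
    cfg <- sim_preset("small", layers = list(c(64, c_true)),
                      noise_sigma = noise_sigma, seed = seed)
    vol <- simulate_volume(cfg)
    surf <- detect_surface(vol)
    extract_phase_stack(flatten_volume(vol, surf), n_depths = n_depths)
  })
}

# The desk-scale labelled training set: 40 homogeneous small-preset volumes
# with velocities drawn uniformly from [2, 8] m/s, 50 depth layers each.
desk_training_set <- function() {
  cached("desk_pairs", {
    cs <- withr::with_seed(100, runif(40, 2, 8))
    cfgs <- lapply(seq_along(cs), function(i) {
      sim_preset("small", layers = list(c(64, cs[i])), seed = i,
                 noise_sigma = 0.05)
    })
    make_training_set(cfgs, depths_per_volume = 50, image_size = c(64, 64),
                      shuffle_seed = 1)
  })
}

desk_test_set <- function() {
  cached("desk_test_pairs", {
    cs <- withr::with_seed(200, runif(4, 2, 8))
    cfgs <- lapply(seq_along(cs), function(i) {
      sim_preset("small", layers = list(c(64, cs[i])), seed = 100 + i,
                 noise_sigma = 0.05)
    })
    make_training_set(cfgs, depths_per_volume = 50, image_size = c(64, 64),
                      shuffle_seed = 2)
  })
}

# Small random complex volume for I/O tests.
random_volume <- function(dim = c(4, 4, 4), seed = 1, dz = 4.7, dx = 8.6,
                          dt = 1e-5) {
  withr::with_seed(seed, {
    oce_volume(array(complex(real = rnorm(prod(dim)),
                             imaginary = rnorm(prod(dim))), dim),
               dz = dz, dx = dx, dt = dt, meta = list(f0 = 4000))
  })
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
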