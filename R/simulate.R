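#' Surface topography generators
#'
#' Helpers describing where the sample surface sits in a simulated volume,
#' as a 1-based axial index per lateral position: flat, linearly tilted, or
#' sinusoidal topography.
#'
#' @param z0 Surface depth index at the first lateral position.
#' @param z1 Surface depth index at the last lateral position (tilt).
#' @param amplitude Peak surface modulation in depth indices (sine).
#' @param cycles Number of full sine periods across the lateral aperture.
#' @return A function mapping a lateral size `X` to an integer vector of
#'   surface indices.
#' @export
surface_flat <- function(z0) {
  force(z0)
  function(X) rep(as.integer(round(z0)), X)
}

#' @rdname surface_flat
#' @export
surface_tilt <- function(z0, z1) {
  force(z0); force(z1)
  function(X) as.integer(round(seq(z0, z1, length.out = X)))
}

#' @rdname surface_flat
#' @export
surface_sine <- function(z0, amplitude, cycles = 1) {
  force(z0); force(amplitude); force(cycles)
  function(X) {
    x <- seq(0, 1, length.out = X)
    as.integer(round(z0 + amplitude * sin(2 * pi * cycles * x)))
  }
}

#' Simulation configuration
#'
#' Describes a synthetic SAW-OCE acquisition: a surface acoustic wave driven
#' at `f0` propagating in +x along the sample surface, imprinting a phase
#' modulation on the complex OCT field. Depth-dependent phase velocity is
#' piecewise constant over `layers`; the field amplitude decays exponentially
#' with depth below the surface and laterally away from the excitation;
#' circularly symmetric complex Gaussian noise is added everywhere.
#'
#' Defaults mirror the acquisition geometry of the target instrument:
#' 384 x 600 x 600 volume (axial x lateral x time), `dz = 4.7` um,
#' `dx = 8.6` um, 4 kHz excitation, and `dt` chosen so the time axis spans
#' `cycles` full excitation periods (16 by default, comfortably above the
#' minimum of 8 the spectral analysis needs). A `sim_preset("small")`
#' (64 x 128 x 128) is provided for fast tests.
#'
#' @param shape Integer vector `(Z, X, T)`.
#' @param dz,dx Axial/lateral spacing, micrometres.
#' @param dt Frame interval, seconds; `NULL` derives it as
#'   `cycles / (f0 * T)`.
#' @param cycles Excitation cycles spanned by the time axis when `dt` is
#'   derived.
#' @param f0 Excitation frequency, Hz.
#' @param layers List of `c(thickness_indices, velocity_mps)` pairs ordered
#'   from the surface down; thicknesses must sum to at most `Z`.
#' @param displacement_amp Peak optical phase modulation, radians.
#' @param depth_decay Amplitude e-folding depth below the surface, indices.
#' @param lateral_decay Amplitude e-folding length along x, indices.
#' @param surface Surface topography: a single index (flat), an integer
#'   vector of length `X`, or a generator from [surface_flat()] and friends.
#' @param noise_sigma Std of the additive complex noise relative to the unit
#'   signal amplitude at the surface (total over both quadratures).
#' @param seed Integer seed making the noise realization reproducible.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(shape = c(64, 128, 128), layers = list(c(64, 3.2)))
#' cfg$dt
#' @export
sim_config <- function(shape = c(384, 600, 600), dz = 4.7, dx = 8.6,
                       dt = NULL, cycles = 16, f0 = 4000,
                       layers = list(c(shape[1], 3.2)),
                       displacement_amp = 1, depth_decay = 100,
                       lateral_decay = 600, surface = NULL,
                       noise_sigma = 0.05, seed = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 2), dz > 0, dx > 0, f0 > 0,
            displacement_amp >= 0, depth_decay > 0, lateral_decay > 0,
            noise_sigma >= 0)
  if (is.null(dt)) dt <- cycles / (f0 * shape[3])
  stopifnot(dt > 0)
  lay <- do.call(rbind, lapply(layers, function(l) {
    stopifnot(length(l) == 2)
    c(thickness = as.integer(l[1]), velocity = as.numeric(l[2]))
  }))
  if (any(lay[, "velocity"] <= 0)) {
    stop_sawoce("layer velocities must be > 0", "sawoce_config")
  }
  if (any(lay[, "thickness"] < 0) || sum(lay[, "thickness"]) > shape[1]) {
    stop_sawoce("layer thicknesses must be >= 0 and sum to <= Z",
                "sawoce_config")
  }
  if (f0 >= 1 / (2 * dt)) {
    stop_sawoce(sprintf(
      "temporal Nyquist violated: f0 = %g Hz >= 1/(2 dt) = %g Hz",
      f0, 1 / (2 * dt)), "sawoce_config")
  }
  k_max <- f0 / min(lay[, "velocity"])
  if (k_max >= 1 / (2 * dx * 1e-6)) {
    stop_sawoce(sprintf(
      "spatial Nyquist violated: f0/min(c) = %g cycles/m >= 1/(2 dx) = %g",
      k_max, 1 / (2 * dx * 1e-6)), "sawoce_config")
  }
  if (is.null(surface)) surface <- max(1L, as.integer(round(shape[1] / 8)))
  surf <- if (is.function(surface)) {
    as.integer(surface(shape[2]))
  } else if (length(surface) == 1) {
    rep(as.integer(round(surface)), shape[2])
  } else {
    as.integer(round(surface))
  }
  if (length(surf) != shape[2] || any(surf < 1) || any(surf > shape[1])) {
    stop_sawoce("surface profile must give indices in [1, Z] for every x",
                "sawoce_config")
  }
  structure(list(
    shape = shape, dz = dz, dx = dx, dt = dt, f0 = f0, layers = lay,
    displacement_amp = displacement_amp, depth_decay = depth_decay,
    lateral_decay = lateral_decay, surface = surf,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"full"` reproduces the instrument-scale geometry (384 x 600 x 600);
#' `"small"` is a 64 x 128 x 128 configuration with the same pixel spacings
#' and excitation, sized for fast tests and desk-scale training.
#'
#' @param name `"full"` or `"small"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("small", "full"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    full = list(shape = c(384L, 600L, 600L), surface = 40),
    # The small preset keeps the instrument's ~5.1 mm lateral field of view
    # (and >= 1 surface wavelength at soft-tissue speeds) by sampling it
    # with 128 coarser pixels instead of 600 fine ones.
    small = list(shape = c(64L, 128L, 128L), surface = 8, dx = 40,
                 depth_decay = 100, lateral_decay = 600)
  )
  args <- modifyList(base, list(...))
  if (is.null(args$layers)) {
    args$layers <- list(c(args$shape[1], 3.2))
  }
  do.call(sim_config, args)
}

# Piecewise-constant layer velocity at 0-based depth `d` below the surface.
# Depths beyond the configured stack keep the deepest layer's velocity.
layer_velocity <- function(config, d) {
  th <- config$layers[, "thickness"]
  v <- config$layers[, "velocity"]
  keep <- th > 0
  if (!any(keep)) stop_sawoce("all layers have zero thickness", "sawoce_config")
  th <- th[keep]; v <- v[keep]
  upper <- cumsum(th)  # first depth index beyond each layer
  idx <- findInterval(d, c(0, upper), rightmost.closed = FALSE)
  idx[idx > length(v)] <- length(v)
  v[idx]
}

#' Ground-truth velocity profile of a simulation
#'
#' The simulator's depth-resolved truth channel: phase velocity of the layer
#' containing each depth below the (flattened) surface, piecewise constant
#' per layer.
#'
#' @param config A [sim_config()].
#' @param n_depths Number of depth layers; defaults to the summed layer
#'   thicknesses.
#' @return A [velocity_profile()] with only `v_true` populated.
#' @examples
#' cfg <- sim_config(shape = c(100, 32, 64), layers = list(c(58, 5.5), c(42, 3.1)))
#' table(true_profile(cfg)$v_true)
#' @export
true_profile <- function(config, n_depths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_depths)) n_depths <- sum(config$layers[, "thickness"])
  stopifnot(n_depths >= 1)
  d <- 0:(n_depths - 1L)
  velocity_profile(d, dz = config$dz, v_true = layer_velocity(config, d))
}

#' Simulate a SAW-OCE complex volume
#'
#' Forward model: below the local surface the field is
#' `A(z, x) * exp(i * phi(z, x, t))` with amplitude
#' `A = exp(-d / depth_decay) * exp(-(x-1) / lateral_decay)` (`d` = depth
#' below the surface in indices) and phase
#' `phi = displacement_amp * sin(2 pi f0 (t_s - x_m / c(d)))`, where `c(d)`
#' is the layer velocity from [true_profile()], `t_s` the frame time in
#' seconds and `x_m` the lateral position in metres. Above the surface the
#' signal is zero. Circular complex Gaussian noise of total std
#' `noise_sigma` is added everywhere. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [oce_volume()] whose `meta` records `f0`, the seed, the
#'   surface profile and a configuration hash.
#' @export
simulate_volume <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  Z <- config$shape[1]; X <- config$shape[2]; Tn <- config$shape[3]
  x_m <- (0:(X - 1L)) * config$dx * 1e-6
  t_s <- (0:(Tn - 1L)) * config$dt
  surf <- config$surface
  data <- array(0i, dim = c(Z, X, Tn))
  phase_t <- matrix(2 * pi * config$f0 * t_s, nrow = X, ncol = Tn,
                    byrow = TRUE)
  for (z in seq_len(Z)) {
    d <- z - surf                       # depth below surface, 0 at surface
    below <- d >= 0
    if (!any(below)) next
    cz <- layer_velocity(config, pmax(d, 0))
    amp <- ifelse(below,
                  exp(-pmax(d, 0) / config$depth_decay) *
                    exp(-(0:(X - 1L)) / config$lateral_decay),
                  0)
    lag <- 2 * pi * config$f0 * x_m / cz
    phi <- config$displacement_amp * sin(phase_t - lag)
    data[z, , ] <- amp * exp(1i * phi)
  }
  if (config$noise_sigma > 0) {
    s <- config$noise_sigma / sqrt(2)
    data <- data + with_seed(config$seed, {
      complex(real = rnorm(length(data), sd = s),
              imaginary = rnorm(length(data), sd = s))
    })
  }
  oce_volume(data, dz = config$dz, dx = config$dx, dt = config$dt,
             meta = list(f0 = config$f0, seed = config$seed,
                         surface = surf,
                         config_hash = rlang::hash(unclass(config))))
}

#' Build a labelled training set of phase images
#'
#' Simulates each configuration, flattens it on the generator's own surface,
#' extracts lag-1 phase-difference images for `depths_per_volume`
#' consecutive depth layers below the surface, and pairs each image with the
#' true phase velocity of its layer. Pairs are shuffled with `shuffle_seed`.
#' Deterministic given the config seeds and `shuffle_seed`.
#'
#' @param configs A [sim_config()] or list of them.
#' @param depths_per_volume Depth layers extracted per volume (default 100).
#' @param image_size Optional `c(H, W)`; images are bilinearly resized.
#' @param shuffle_seed Seed for the final shuffle.
#' @return A tibble with columns `image` (list of `[x, t]` matrices,
#'   radians), `v_true` (m/s), `config_id`, `depth_index`.
#' @export
make_training_set <- function(configs, depths_per_volume = 100,
                              image_size = NULL, shuffle_seed = 0) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  rows <- purrr::imap(configs, function(cfg, ci) {
    stopifnot(inherits(cfg, "sim_config"))
    usable <- cfg$shape[1] - max(cfg$surface)
    if (depths_per_volume > usable) {
      stop_sawoce(sprintf(
        "depths_per_volume = %d exceeds usable depth range %d",
        depths_per_volume, usable), "sawoce_config")
    }
    vol <- simulate_volume(cfg)
    flat <- flatten_volume(vol, cfg$surface)
    stack <- extract_phase_stack(flat, n_depths = depths_per_volume)
    truth <- true_profile(cfg, n_depths = depths_per_volume)
    imgs <- purrr::map(seq_len(depths_per_volume), function(z) {
      img <- stack$phase[z, , ]
      if (!is.null(image_size)) {
        img <- resize_bilinear(img, image_size[1], image_size[2])
      }
      img
    })
    tibble(image = imgs, v_true = truth$v_true, config_id = ci,
           depth_index = truth$depth_index)
  })
  out <- dplyr::bind_rows(rows)
  perm <- with_seed(shuffle_seed, sample.int(nrow(out)))
  out[perm, ]
}
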