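#' NSA configuration
#'
#' Settings for the numerical spectral analysis estimator. Each depth layer
#' is transformed to the frequency-wavenumber (f, k) plane; spectra of
#' `2 * depth_radius + 1` neighbouring layers are magnitude-averaged for
#' stability, and the phase velocity is read off as the ratio of the
#' energy-weighted centroid coordinates, `c = f_c / k_c` (k in cycles per
#' metre, so no 2 pi factor is involved).
#'
#' The (k, f) region of interest is either given explicitly (`roi_f`,
#' `roi_k`) or derived from the excitation frequency and a velocity search
#' band via [auto_roi()]. The defaults (`band = 0.5`, `c` in 1-20 m/s)
#' bracket soft-tissue and agar surface-wave speeds. `energy_floor` keeps
#' only the central spectral energy — bins at or above that fraction of the
#' averaged map's peak — so the broadband noise floor cannot drag the
#' centroid toward the ROI centre.
#'
#' @param depth_radius Layers averaged each side of the target depth
#'   (default 2).
#' @param pad_factor FFT zero-padding multiplier applied on top of
#'   next-power-of-two sizing (default 2); finer bins reduce centroid
#'   quantization.
#' @param roi_f,roi_k Optional explicit ROI, `(min, max)` in Hz and
#'   cycles/m.
#' @param c_min,c_max Velocity search band for the automatic ROI, m/s.
#' @param band Relative half-width of the frequency ROI around `f0`.
#' @param energy_floor Fraction of the peak magnitude below which bins are
#'   zeroed (default 0.5).
#' @param smooth_window rLOESS window, samples (default 30); consumed by
#'   [rloess_smooth()].
#' @return A list of class `nsa_config`.
#' @export
nsa_config <- function(depth_radius = 2, pad_factor = 2, roi_f = NULL,
                       roi_k = NULL, c_min = 1, c_max = 20, band = 0.5,
                       energy_floor = 0.5, smooth_window = 30) {
  stopifnot(depth_radius >= 0, pad_factor >= 1,
            energy_floor >= 0, energy_floor < 1, smooth_window >= 2)
  if (is.null(roi_f) != is.null(roi_k) ||
      (!is.null(roi_f) && (length(roi_f) != 2 || length(roi_k) != 2))) {
    stop_sawoce("give both roi_f and roi_k as (min, max), or neither",
                "sawoce_config")
  }
  if (!is.null(roi_f)) {
    stopifnot(roi_f[1] > 0, roi_f[1] < roi_f[2],
              roi_k[1] > 0, roi_k[1] < roi_k[2])
  }
  structure(list(depth_radius = as.integer(depth_radius),
                 pad_factor = pad_factor, roi_f = roi_f, roi_k = roi_k,
                 c_min = c_min, c_max = c_max, band = band,
                 energy_floor = energy_floor,
                 smooth_window = as.integer(smooth_window)),
            class = "nsa_config")
}

#' Derive a spectral ROI from the excitation frequency
#'
#' The frequency window brackets the excitation at `f0 * (1 -/+ band)`; the
#' wavenumber window is the image of that window under the velocity search
#' band: `k` from `f_min / c_max` to `f_max / c_min`.
#'
#' @param f0 Excitation frequency, Hz.
#' @param c_min,c_max Velocity search band, m/s (`0 < c_min < c_max`).
#' @param band Relative half-width, `0 < band < 1`.
#' @return List with `roi_f` and `roi_k`, each `(min, max)`.
#' @examples
#' auto_roi(4000, 1, 20, 0.5)
#' @export
auto_roi <- function(f0, c_min, c_max, band = 0.5) {
  stopifnot(f0 > 0, c_min > 0, band > 0, band < 1)
  if (c_min >= c_max) {
    stop_sawoce("require 0 < c_min < c_max", "sawoce_config")
  }
  roi_f <- c(f0 * (1 - band), f0 * (1 + band))
  list(roi_f = roi_f, roi_k = c(roi_f[1] / c_max, roi_f[2] / c_min))
}

# Resolve the ROI for a stack (explicit or automatic from f0).
resolve_roi <- function(config, f0) {
  if (!is.null(config$roi_f)) {
    return(list(roi_f = config$roi_f, roi_k = config$roi_k))
  }
  if (is.null(f0)) {
    stop_sawoce(
      "no explicit ROI and no excitation frequency available; pass `f0` or set roi_f/roi_k",
      "sawoce_config")
  }
  auto_roi(f0, config$c_min, config$c_max, config$band)
}

# Magnitude spectra of phase slices restricted to the ROI, both k-sign
# halves, for a range of depth layers. Returns per-slice ROI submatrices
# and their total energies, plus the physical bin axes.
nsa_slice_maps <- function(stack, zs, config, f0 = NULL) {
  stopifnot(inherits(stack, "phase_stack"))
  ph <- stack$phase
  X <- dim(ph)[2]; Tm <- dim(ph)[3]
  px <- config$pad_factor * next_pow2(X)
  pt <- config$pad_factor * next_pow2(Tm)
  roi <- resolve_roi(config, f0 %||% stack$meta$f0)
  dx_m <- stack$dx * 1e-6
  k_all <- (1:(px / 2)) / (px * dx_m)          # positive bins, ascending
  f_all <- (0:(pt / 2)) / (pt * stack$dt)
  ksel <- which(k_all >= roi$roi_k[1] & k_all <= roi$roi_k[2])
  fsel <- which(f_all >= roi$roi_f[1] & f_all <= roi$roi_f[2])
  if (!length(ksel) || !length(fsel)) {
    stop_sawoce("spectral ROI narrower than one padded bin", "sawoce_config")
  }
  rows_pos <- ksel + 1L          # R index j = jx + 1
  rows_neg <- px - ksel + 1L     # |k| identical, mirrored bins
  cols_f <- fsel                 # jf = 0 .. pt/2 -> R index jf + 1; fsel is 1-based over f_all
  win <- outer(hann_window(X), hann_window(Tm))
  pos <- array(0, c(length(ksel), length(fsel), length(zs)))
  neg <- pos
  for (i in seq_along(zs)) {
    s <- ph[zs[i], , ]
    s <- (s - mean(s)) * win
    padded <- matrix(0, px, pt)
    padded[1:X, 1:Tm] <- s
    mag <- Mod(fft(padded))
    pos[, , i] <- mag[rows_pos, cols_f]
    neg[, , i] <- mag[rows_neg, cols_f]
  }
  list(pos = pos, neg = neg, k_axis = k_all[ksel], f_axis = f_all[fsel],
       roi = c(k_min = roi$roi_k[1], k_max = roi$roi_k[2],
               f_min = roi$roi_f[1], f_max = roi$roi_f[2]))
}

# Average a window of per-slice maps, pick the dominant k-sign half, apply
# the energy floor, and assemble a spectral_map object.
assemble_map <- function(maps, idx, energy_floor) {
  avg_pos <- apply(maps$pos[, , idx, drop = FALSE], c(1, 2), mean)
  avg_neg <- apply(maps$neg[, , idx, drop = FALSE], c(1, 2), mean)
  S <- if (sum(avg_pos) >= sum(avg_neg)) avg_pos else avg_neg
  if (energy_floor > 0) {
    S[S < energy_floor * max(S)] <- 0
  }
  structure(list(S = S, k_axis = maps$k_axis, f_axis = maps$f_axis,
                 roi = maps$roi),
            class = "spectral_map")
}

#' Depth-resolved spectral energy map
#'
#' Builds the stabilized frequency-wavenumber energy map for one depth
#' layer: each phase-difference slice in `[z - r, z + r]` (truncated at the
#' stack edges) has its mean removed, is apodized with a separable symmetric
#' Hann window in (x, t), zero-padded, and 2-D Fourier transformed; the
#' magnitude spectra are averaged across the depth window. The map is
#' restricted to the configured ROI after selecting the wavenumber-sign
#' half-plane carrying more ROI energy (a wave travelling one way along x
#' concentrates its energy in one half), and bins below `energy_floor` of
#' the peak are zeroed.
#'
#' @param stack A [extract_phase_stack()] result.
#' @param z 1-based depth layer within the stack.
#' @param config An [nsa_config()].
#' @param f0 Excitation frequency, Hz; defaults to the stack metadata.
#' @return A `spectral_map`: list with `S` (nonnegative matrix, k by f),
#'   `k_axis` (cycles/m), `f_axis` (Hz) and `roi`.
#' @export
spectral_map <- function(stack, z, config = nsa_config(), f0 = NULL) {
  n <- dim(stack$phase)[1]
  stopifnot(z >= 1, z <= n)
  zs <- max(1L, z - config$depth_radius):min(n, z + config$depth_radius)
  if (!length(zs)) stop_sawoce("empty depth window", "sawoce_config")
  maps <- nsa_slice_maps(stack, zs, config, f0)
  assemble_map(maps, seq_along(zs), config$energy_floor)
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d k-bins x %d f-bins, peak at (k = %.0f cycles/m, f = %.0f Hz)\n",
              nrow(x$S), ncol(x$S),
              x$k_axis[which(x$S == max(x$S), arr.ind = TRUE)[1, 1]],
              x$f_axis[which(x$S == max(x$S), arr.ind = TRUE)[1, 2]]))
  invisible(x)
}

#' Weighted spectral centroid phase velocity
#'
#' The energy-weighted centroid of the map gives the dominant spectral
#' coordinates `f_c = sum(f S) / sum(S)` and `k_c = sum(k S) / sum(S)`; the
#' phase velocity is their ratio `c = f_c / k_c` in metres per second
#' (wavenumber in cycles per metre, so the ratio needs no 2 pi factor).
#'
#' @param smap A [spectral_map()].
#' @return Phase velocity, m/s.
#' @examples
#' m <- structure(list(S = matrix(c(0, 1), 1), k_axis = 1000,
#'                     f_axis = c(2000, 4000)), class = "spectral_map")
#' centroid_velocity(m)  # 4 m/s
#' @export
centroid_velocity <- function(smap) {
  S <- smap$S
  tot <- sum(S)
  if (!is.finite(tot) || tot <= 0) {
    stop_sawoce("undefined velocity: zero total energy in ROI",
                "sawoce_degenerate")
  }
  f_c <- sum(sweep(S, 2, smap$f_axis, `*`)) / tot
  k_c <- sum(S * smap$k_axis) / tot
  if (k_c == 0) {
    stop_sawoce("degenerate spectrum: centroid wavenumber is zero",
                "sawoce_degenerate")
  }
  f_c / k_c
}

#' Depth-resolved NSA velocity profile
#'
#' Runs [spectral_map()] and [centroid_velocity()] at every depth layer of a
#' phase stack. Depths whose centroid is undefined (no ROI energy) are
#' recorded as missing; if more than half the depths fail the whole profile
#' is considered unusable and an error is raised.
#'
#' @param stack A [extract_phase_stack()] result.
#' @param config An [nsa_config()].
#' @param f0 Excitation frequency, Hz; defaults to stack metadata.
#' @param smooth If `TRUE`, also populate `v_smooth` via [rloess_smooth()]
#'   with `config$smooth_window`.
#' @return A [velocity_profile()] with `v_raw` (and optionally `v_smooth`).
#' @export
nsa_profile <- function(stack, config = nsa_config(), f0 = NULL,
                        smooth = FALSE) {
  n <- dim(stack$phase)[1]
  maps <- nsa_slice_maps(stack, seq_len(n), config, f0)
  r <- config$depth_radius
  v <- vapply(seq_len(n), function(z) {
    idx <- max(1L, z - r):min(n, z + r)
    tryCatch(centroid_velocity(assemble_map(maps, idx, config$energy_floor)),
             sawoce_degenerate = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(v)) > 0.5) {
    stop_sawoce(sprintf("NSA failed at %d of %d depths", sum(is.na(v)), n),
                "sawoce_pipeline")
  }
  prof <- velocity_profile(stack$depth_offset + 0:(n - 1L), dz = stack$dz,
                           v_raw = v)
  if (smooth) prof <- rloess_smooth(prof, window = config$smooth_window)
  prof
}
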