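#' Detect the sample surface in an OCE volume
#'
#' For each lateral position the surface is the shallowest depth whose
#' time-averaged signal magnitude exceeds a noise-adaptive threshold
#' `noise_mean + k_sigma * noise_sd`, where the noise floor is estimated
#' from the top `noise_frac` fraction of depth rows (air above the sample).
#' The per-column result is median-filtered to suppress speckle outliers.
#'
#' @param vol An [oce_volume()].
#' @param k_sigma Threshold multiplier on the noise-floor std (default 5).
#' @param noise_frac Fraction of the shallowest rows used to estimate the
#'   noise floor (default 0.05).
#' @param median_window Odd window length of the lateral median filter
#'   (default 11).
#' @return Integer vector, one 1-based axial surface index per lateral
#'   position.
#' @export
detect_surface <- function(vol, k_sigma = 5, noise_frac = 0.05,
                           median_window = 11) {
  stopifnot(inherits(vol, "oce_volume"))
  d <- dim(vol)
  Z <- d[1]; X <- d[2]; Tn <- d[3]
  m <- matrix(0, Z, X)
  for (t in seq_len(Tn)) m <- m + Mod(unclass(vol)[, , t])
  m <- m / Tn
  n_noise <- max(1L, as.integer(ceiling(noise_frac * Z)))
  floor_vals <- m[seq_len(n_noise), , drop = FALSE]
  thr <- mean(floor_vals) + k_sigma * sd(floor_vals)
  if (!is.finite(thr)) thr <- mean(floor_vals)
  surf <- apply(m > thr, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  bad <- which(is.na(surf))
  if (length(bad)) {
    stop_sawoce(sprintf(
      "no super-threshold voxel in %d lateral column(s): %s",
      length(bad), paste(head(bad, 10), collapse = ", ")),
      "sawoce_surface")
  }
  if (X >= median_window) {
    surf <- as.integer(round(runmed(surf, median_window)))
  }
  surf
}

#' Axially flatten a volume on a detected surface
#'
#' Shifts every lateral column up by an integer number of pixels so the
#' surface sits at the first depth row; rows vacated at the bottom are
#' zero-filled. Integer shifts (no sub-pixel interpolation) preserve the
#' complex speckle statistics the spectral analysis consumes. The applied
#' shifts are recorded in the volume metadata.
#'
#' @param vol An [oce_volume()].
#' @param surface Integer vector of 1-based surface indices per lateral
#'   position, e.g. from [detect_surface()].
#' @param margin Air rows left above the flattened surface (default 0: the
#'   surface lands on the first depth row). A nonzero margin keeps the
#'   flattened volume detectable by [detect_surface()], which estimates its
#'   noise floor from the topmost rows.
#' @return A flattened [oce_volume()].
#' @export
flatten_volume <- function(vol, surface, margin = 0L) {
  stopifnot(inherits(vol, "oce_volume"))
  d <- dim(vol)
  Z <- d[1]; X <- d[2]
  surface <- as.integer(surface)
  margin <- as.integer(margin)
  stopifnot(length(surface) == X, all(surface >= 1), all(surface <= Z),
            margin >= 0, margin < Z)
  out <- unclass(vol)
  for (x in seq_len(X)) {
    shift <- surface[x] - 1L - margin
    if (shift != 0) {
      src <- max(1L, 1L + shift):min(Z, Z + shift)
      dst <- src - shift
      out[, x, ] <- 0i
      out[dst, x, ] <- unclass(vol)[src, x, ]
    }
  }
  meta <- vol_meta(vol)
  meta$flatten_shifts <- surface - 1L - margin
  oce_volume(out, dz = vol_dz(vol), dx = vol_dx(vol), dt = vol_dt(vol),
             meta = meta)
}

#' Extract a lag-1 phase-difference stack
#'
#' Computes Kasai-style lag-1 phase differences
#' `arg(data[z, x, t+1] * Conj(data[z, x, t]))`, wrapped to `[-pi, pi)`, for
#' `n_depths` consecutive depth layers starting `depth_offset` layers below
#' the (flattened) surface. The conjugate product is wrap-safe, unlike
#' subtracting frame-wise phases. Each retained depth layer yields one
#' lateral-temporal phase image; these feed both the spectral estimator and
#' the regression network.
#'
#' @param vol A flattened [oce_volume()].
#' @param n_depths Number of depth layers to retain (default 100).
#' @param depth_offset 0-based index of the first retained layer below the
#'   surface (default 0: the surface layer itself).
#' @param unwrap_time If `TRUE`, apply 1-D temporal phase unwrapping per
#'   pixel after wrapping (stress-test option; defaults keep `|dphi| < pi`
#'   so it is off by default).
#' @param type `"difference"` (default) stores lag-1 phase differences;
#'   `"complex"` stores the raw complex slices instead, for running the
#'   spectral analysis on the complex field directly.
#' @return A `phase_stack`: list with `phase` (`[z, x, t-1]` array of
#'   radians, or `[z, x, t]` complex for `type = "complex"`), axis spacings
#'   `dz`, `dx`, `dt`, `depth_offset`, and the source `meta`.
#' @export
extract_phase_stack <- function(vol, n_depths = 100, depth_offset = 0,
                                unwrap_time = FALSE,
                                type = c("difference", "complex")) {
  stopifnot(inherits(vol, "oce_volume"))
  type <- match.arg(type)
  if (n_depths < 1) stop_sawoce("n_depths must be >= 1", "sawoce_config")
  d <- dim(vol)
  Z <- d[1]; Tn <- d[3]
  zmax <- depth_offset + n_depths
  if (zmax > Z) {
    stop_sawoce(sprintf(
      "n_depths + depth_offset = %d exceeds depth extent %d", zmax, Z),
      "sawoce_config")
  }
  rows <- (depth_offset + 1L):zmax
  a <- unclass(vol)[rows, , , drop = FALSE]
  if (type == "complex") {
    ph <- a
  } else {
    ph <- Arg(a[, , -1L, drop = FALSE] * Conj(a[, , -Tn, drop = FALSE]))
    ph <- wrap_phase(ph)
    if (unwrap_time) {
      ph <- aperm(apply(ph, c(1, 2), unwrap_1d), c(2, 3, 1))
    }
  }
  structure(list(phase = ph, dz = vol_dz(vol), dx = vol_dx(vol),
                 dt = vol_dt(vol), depth_offset = as.integer(depth_offset),
                 type = type, meta = vol_meta(vol)),
            class = "phase_stack")
}

# Cumulative 1-D phase unwrap along a vector.
unwrap_1d <- function(p) {
  p + cumsum(c(0, -2 * pi * round(diff(p) / (2 * pi))))
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(
    "<phase_stack> %d depths x %d lateral x %d frames (offset %d)\n",
    d[1], d[2], d[3], x$depth_offset))
  invisible(x)
}
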