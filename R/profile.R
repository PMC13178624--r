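#' Depth-resolved velocity profile
#'
#' A velocity profile is a tibble with one row per retained depth layer and
#' columns `depth_index` (0-based layer index below the sample surface),
#' `depth_um` (physical depth, micrometres, `depth_index * dz`), `v_raw`
#' (estimated phase velocity, m/s), `v_smooth` (robust-LOESS smoothed
#' velocity, m/s; `NA` until smoothing) and `v_true` (simulator ground
#' truth, m/s; `NA` for measured data). The axial spacing `dz` is carried in
#' the `dz_um` attribute.
#'
#' @param depth_index Integer vector of 0-based depth indices (strictly
#'   increasing).
#' @param dz Axial spacing in micrometres.
#' @param v_raw,v_smooth,v_true Optional numeric channels, m/s. Channels that
#'   are present must match `depth_index` in length; `v_raw`/`v_true` must be
#'   positive where defined.
#' @return A tibble of class `velocity_profile`.
#' @examples
#' velocity_profile(0:9, dz = 4.7, v_true = rep(3.2, 10))
#' @export
velocity_profile <- function(depth_index, dz, v_raw = NULL, v_smooth = NULL,
                             v_true = NULL) {
  depth_index <- as.integer(depth_index)
  n <- length(depth_index)
  if (n == 0) stop_sawoce("profile must be non-empty", "sawoce_invariant")
  if (any(diff(depth_index) <= 0)) {
    stop_sawoce("depth_index must be strictly increasing", "sawoce_invariant")
  }
  if (!is.numeric(dz) || dz <= 0) {
    stop_sawoce("`dz` must be positive", "sawoce_invariant")
  }
  chan <- function(v, nm, positive) {
    if (is.null(v)) return(rep(NA_real_, n))
    if (length(v) != n) {
      stop_sawoce(sprintf("channel '%s' has length %d, expected %d",
                          nm, length(v), n), "sawoce_invariant")
    }
    if (positive && any(!is.na(v) & v <= 0)) {
      stop_sawoce(sprintf("channel '%s' must be > 0 where defined", nm),
                  "sawoce_invariant")
    }
    as.numeric(v)
  }
  out <- tibble(
    depth_index = depth_index,
    depth_um = depth_index * dz,
    v_raw = chan(v_raw, "v_raw", TRUE),
    v_smooth = chan(v_smooth, "v_smooth", FALSE),
    v_true = chan(v_true, "v_true", TRUE)
  )
  attr(out, "dz_um") <- dz
  class(out) <- c("velocity_profile", class(out))
  out
}

profile_dz <- function(profile) {
  attr(profile, "dz_um") %||%
    {
      d <- diff(profile$depth_um) / diff(profile$depth_index)
      d[1]
    }
}

#' Convert a depth index to physical depth
#'
#' Depth layers are spaced `dz` micrometres apart, so layer `z` (0-based)
#' sits at `z * dz / 1000` millimetres below the surface. With the system
#' default `dz = 4.7` um, index 35 corresponds to 0.165 mm and index 15 to
#' 0.071 mm (3-decimal rounding).
#'
#' @param z Depth index (0-based), vectorised.
#' @param dz Axial spacing, micrometres.
#' @return Depth in millimetres.
#' @examples
#' round(index_to_depth(35, 4.7), 3)
#' @export
index_to_depth <- function(z, dz) {
  stopifnot(all(z >= 0), dz > 0)
  z * dz / 1000
}

#' Write a velocity profile (and optional bilinear fit) to disk
#'
#' Writes a CSV with columns `depth_index`, `depth_um`, `v_raw`, `v_smooth`,
#' `v_true` (absent channels are left blank). When a bilinear interface fit
#' is supplied it is serialized as a JSON sidecar next to the CSV
#' (`<path>.fit.json`) with keys `a1, b1, a2, b2, z_break, jump, sse,
#' sse_single`.
#'
#' @param profile A [velocity_profile()].
#' @param path Output CSV path.
#' @param fit Optional [fit_bilinear()] result.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, fit = NULL) {
  if (!nrow(profile)) stop_sawoce("profile must be non-empty", "sawoce_invariant")
  lens <- lengths(profile[c("depth_index", "depth_um", "v_raw", "v_smooth",
                            "v_true")])
  if (length(unique(lens)) != 1) {
    stop_sawoce("profile channels have mismatched lengths", "sawoce_invariant")
  }
  readr::write_csv(
    as_tibble(profile)[, c("depth_index", "depth_um", "v_raw", "v_smooth",
                           "v_true")],
    path, na = "")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "bilinear_fit"))
    jsonlite::write_json(
      fit[c("a1", "b1", "a2", "b2", "z_break", "jump", "sse", "sse_single")],
      paste0(path, ".fit.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a velocity profile CSV
#'
#' @param path CSV written by [write_profile()].
#' @return A [velocity_profile()].
#' @export
read_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  dz <- if (nrow(df) >= 2) {
    diff(df$depth_um[1:2]) / diff(df$depth_index[1:2])
  } else if (df$depth_index[1] > 0) {
    df$depth_um[1] / df$depth_index[1]
  } else {
    stop_sawoce("cannot recover dz from a single depth-0 row", "sawoce_schema")
  }
  velocity_profile(df$depth_index, dz = dz, v_raw = df$v_raw,
                   v_smooth = df$v_smooth, v_true = df$v_true)
}
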