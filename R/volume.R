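#' Complex OCE volume
#'
#' Container for a 3-D complex-valued optical coherence elastography (OCE)
#' acquisition, indexed `[z, x, t]` (axial depth, lateral position, time),
#' together with its physical axis spacings. This is the raw observable every
#' downstream stage consumes: the complex field carries the optical phase
#' modulation imprinted by a propagating surface acoustic wave.
#'
#' @param data 3-D complex (or numeric) array indexed `[z, x, t]`. Numeric
#'   input is promoted to complex. All values must be finite.
#' @param dz Axial pixel spacing in micrometres (> 0).
#' @param dx Lateral pixel spacing in micrometres (> 0).
#' @param dt Frame (M-scan repetition) interval in seconds (> 0).
#' @param meta Named list of free-form provenance (excitation frequency `f0`
#'   in Hz, simulation seed, configuration hash, ...).
#'
#' @return An object of class `oce_volume`: the array with attributes
#'   `dz`, `dx`, `dt` (physical spacings) and `meta`.
#' @examples
#' vol <- oce_volume(array(complex(real = 1), c(4, 4, 4)),
#'                   dz = 4.7, dx = 8.6, dt = 1e-5)
#' dim(vol)
#' @export
oce_volume <- function(data, dz, dx, dt, meta = list()) {
  if (length(dim(data)) != 3) {
    stop_sawoce("`data` must have exactly 3 axes [z, x, t]", "sawoce_invariant")
  }
  if (!is.complex(data)) {
    if (!is.numeric(data)) {
      stop_sawoce("`data` must be complex or numeric", "sawoce_invariant")
    }
    storage.mode(data) <- "double"
    data <- data + 0i
  }
  if (anyNA(data) || any(!is.finite(Re(data))) || any(!is.finite(Im(data)))) {
    stop_sawoce("volume contains non-finite values", "sawoce_invariant")
  }
  for (nm in c("dz", "dx", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop_sawoce(sprintf("`%s` must be a single positive number", nm),
                  "sawoce_invariant")
    }
  }
  structure(data, dz = dz, dx = dx, dt = dt, meta = meta,
            class = "oce_volume")
}

#' @export
print.oce_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<oce_volume> %d x %d x %d (z, x, t)  dz=%.3g um  dx=%.3g um  dt=%.3g s\n",
    d[1], d[2], d[3], attr(x, "dz"), attr(x, "dx"), attr(x, "dt")))
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), collapse = ", "), "\n")
  }
  invisible(x)
}

vol_dz <- function(vol) attr(vol, "dz")
vol_dx <- function(vol) attr(vol, "dx")
vol_dt <- function(vol) attr(vol, "dt")
vol_meta <- function(vol) attr(vol, "meta") %||% list()

#' Write a complex OCE volume to HDF5
#'
#' Stores the complex field as paired double-precision datasets `/real` and
#' `/imag` (shape Z x X x T) with root attributes `dz_um`, `dx_um`, `dt_s`
#' and `meta_json` (provenance serialized as one JSON string). The layout is
#' portable across HDF5 consumers and round-trips bit-exactly.
#'
#' @param vol An [oce_volume()].
#' @param path Output file path; an existing file is overwritten.
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oce_volume"))
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) {
    stop_sawoce(sprintf("cannot create HDF5 file at '%s'", path), "sawoce_io")
  }
  rhdf5::h5write(Re(unclass(vol)), path, "real")
  rhdf5::h5write(Im(unclass(vol)), path, "imag")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(vol_dz(vol), fid, "dz_um")
  rhdf5::h5writeAttribute(vol_dx(vol), fid, "dx_um")
  rhdf5::h5writeAttribute(vol_dt(vol), fid, "dt_s")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(vol_meta(vol), auto_unbox = TRUE, digits = NA)),
    fid, "meta_json")
  invisible(path)
}

#' Read a complex OCE volume from HDF5
#'
#' Inverse of [write_volume()]. Validates the schema (datasets `/real`,
#' `/imag`; attributes `dz_um`, `dx_um`, `dt_s`) and reconstructs an
#' [oce_volume()], enforcing all its invariants.
#'
#' @param path Path to a file produced by [write_volume()].
#' @return An [oce_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_sawoce(sprintf("no such file: '%s'", path), "sawoce_io")
  }
  contents <- rhdf5::h5ls(path)
  for (ds in c("real", "imag")) {
    if (!ds %in% contents$name) {
      stop_sawoce(sprintf("HDF5 schema error: missing dataset '/%s'", ds),
                  "sawoce_schema")
    }
  }
  att <- rhdf5::h5readAttributes(path, "/")
  for (a in c("dz_um", "dx_um", "dt_s")) {
    if (is.null(att[[a]])) {
      stop_sawoce(sprintf("HDF5 schema error: missing attribute '%s'", a),
                  "sawoce_schema")
    }
  }
  re <- rhdf5::h5read(path, "real")
  im <- rhdf5::h5read(path, "imag")
  meta <- list()
  if (!is.null(att$meta_json)) {
    meta <- jsonlite::fromJSON(att$meta_json, simplifyVector = TRUE)
  }
  oce_volume(complex(real = re, imaginary = im) |> array(dim = dim(re)),
             dz = as.numeric(att$dz_um), dx = as.numeric(att$dx_um),
             dt = as.numeric(att$dt_s), meta = meta)
}
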