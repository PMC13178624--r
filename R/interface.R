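#' Robust LOESS smoothing of a velocity profile
#'
#' Smooths the raw depth-resolved velocity with robust locally weighted
#' regression: local linear fits with tricube distance weights over a
#' `window`-sample neighbourhood, iteratively re-weighted with Tukey
#' bisquare weights on the residuals so isolated outliers are discounted
#' while depth-wise trends are preserved. Backed by [stats::loess()] with
#' `family = "symmetric"` (degree 1, window converted to a span fraction).
#'
#' @param profile A [velocity_profile()] with `v_raw`.
#' @param window Smoothing window, samples (default 30).
#' @param channel Column to smooth (default `v_raw`).
#' @return The profile with `v_smooth` populated at every depth.
#' @export
rloess_smooth <- function(profile, window = 30, channel = "v_raw") {
  stopifnot(inherits(profile, "velocity_profile"))
  y <- profile[[channel]]
  x <- profile$depth_index
  ok <- !is.na(y)
  if (sum(ok) < window) {
    stop_sawoce(sprintf(
      "need at least %d non-missing points for a %d-sample window, have %d",
      window, window, sum(ok)), "sawoce_config")
  }
  span <- min(1, window / sum(ok))
  df <- data.frame(x = x[ok], y = y[ok])
  # Depth-window averaging can make the raw profile locally constant;
  # loess then warns about degenerate local geometry (pseudoinverse /
  # zero-radius neighbourhoods) while still returning the correct local
  # fit. Those specific warnings are expected here and muffled.
  degenerate <- paste("pseudoinverse|neighborhood|condition number",
                      "singularities|boundary|radius|at *[0-9.]+$",
                      sep = "|")
  fit <- withCallingHandlers(
    loess(y ~ x, data = df, span = span, degree = 1, family = "symmetric",
          control = loess.control(surface = "direct", iterations = 6)),
    warning = function(w) {
      if (grepl(degenerate, conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  profile$v_smooth <- withCallingHandlers(
    as.numeric(predict(fit, newdata = data.frame(x = x))),
    warning = function(w) {
      if (grepl(degenerate, conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  profile
}

#' Bilinear interface fit of a velocity profile
#'
#' Models the depth-resolved phase velocity as two independent line
#' segments separated by a free transition depth, allowing a velocity jump
#' (discontinuity) at the interface between mechanically distinct layers:
#' `v(z) = a1 z + b1` for `z <= z_break` and `a2 z + b2` above it. The
#' breakpoint is found by exhaustive search over all admissible splits,
#' fitting each segment by ordinary least squares and keeping the split
#' with the global minimum total sum of squared errors (SSE); ties break
#' toward the shallowest breakpoint. A single-line OLS fit over all points
#' provides the reference `sse_single`, which can never beat the bilinear
#' fit.
#'
#' A homogeneous medium has no interface: the fit is flagged
#' `has_interface = FALSE` when the jump is below `jump_threshold` or the
#' bilinear fit improves on the single line by less than `ratio_threshold`.
#'
#' @param profile A [velocity_profile()].
#' @param min_segment Minimum points per segment (default 5, keeping each
#'   per-segment regression well-posed).
#' @param channel `"auto"` (smoothed when available, else raw), `"smooth"`
#'   or `"raw"`.
#' @param jump_threshold Minimum |velocity jump| in m/s to declare an
#'   interface (default 0.3).
#' @param ratio_threshold Minimum `sse_single / sse` improvement factor
#'   (default 1.05).
#' @return A `bilinear_fit`: list with slopes/intercepts `a1, b1, a2, b2`
#'   (m/s per index, m/s), `z_break` (depth index of the first point of the
#'   lower segment), `jump` (m/s), `sse`, `sse_single`, `has_interface`,
#'   `n`, `channel`.
#' @export
fit_bilinear <- function(profile, min_segment = 5,
                         channel = c("auto", "smooth", "raw"),
                         jump_threshold = 0.3, ratio_threshold = 1.05) {
  stopifnot(inherits(profile, "velocity_profile"))
  channel <- match.arg(channel)
  use_smooth <- switch(channel,
    auto = any(!is.na(profile$v_smooth)),
    smooth = TRUE,
    raw = FALSE)
  y <- if (use_smooth) profile$v_smooth else profile$v_raw
  x <- as.numeric(profile$depth_index)
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  min_segment <- as.integer(min_segment)
  if (min_segment < 2) {
    stop_sawoce("min_segment must be >= 2", "sawoce_config")
  }
  if (n < 2 * min_segment) {
    stop_sawoce(sprintf("need at least %d points, have %d",
                        2 * min_segment, n), "sawoce_config")
  }
  cs <- function(v) cumsum(v)
  Sx <- cs(x); Sy <- cs(y); Sxx <- cs(x^2); Sxy <- cs(x * y); Syy <- cs(y^2)
  tot <- c(Sx[n], Sy[n], Sxx[n], Sxy[n], Syy[n])
  seg_fit <- function(m, sx, sy, sxx, sxy, syy) {
    den <- m * sxx - sx^2
    a <- (m * sxy - sx * sy) / den
    b <- (sy - a * sx) / m
    sse <- pmax(syy - b * sy - a * sxy, 0)
    list(a = a, b = b, sse = sse)
  }
  splits <- min_segment:(n - min_segment)
  up <- seg_fit(splits, Sx[splits], Sy[splits], Sxx[splits], Sxy[splits],
                Syy[splits])
  lo <- seg_fit(n - splits, tot[1] - Sx[splits], tot[2] - Sy[splits],
                tot[3] - Sxx[splits], tot[4] - Sxy[splits],
                tot[5] - Syy[splits])
  sse_total <- up$sse + lo$sse
  best <- which.min(sse_total)            # ties -> smallest z_break
  p <- splits[best]
  single <- seg_fit(n, tot[1], tot[2], tot[3], tot[4], tot[5])
  z_break <- x[p + 1]
  a1 <- up$a[best]; b1 <- up$b[best]
  a2 <- lo$a[best]; b2 <- lo$b[best]
  jump <- abs((a2 * z_break + b2) - (a1 * z_break + b1))
  sse <- sse_total[best]
  ratio <- if (sse > 0) single$sse / sse else Inf
  structure(list(
    a1 = a1, b1 = b1, a2 = a2, b2 = b2, z_break = z_break, jump = jump,
    sse = sse, sse_single = single$sse,
    has_interface = is.finite(jump) && jump >= jump_threshold &&
      (ratio >= ratio_threshold || (sse == 0 && single$sse > 0)),
    n = n, channel = if (use_smooth) "smooth" else "raw"
  ), class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat(sprintf(
    "<bilinear_fit> break at depth index %g (jump %.3g m/s), SSE %.4g vs single-line %.4g\n",
    x$z_break, x$jump, x$sse, x$sse_single))
  cat(sprintf("  upper: v = %.4g + %.4g z   lower: v = %.4g + %.4g z   interface: %s\n",
              x$b1, x$a1, x$b2, x$a2,
              if (x$has_interface) "yes" else "no"))
  invisible(x)
}

#' @describeIn fit_bilinear One row per fitted segment (slope, intercept).
#' @param x A `bilinear_fit`.
#' @param ... Unused.
#' @export
tidy.bilinear_fit <- function(x, ...) {
  tibble(segment = c("upper", "lower"),
         slope = c(x$a1, x$a2),
         intercept = c(x$b1, x$b2))
}

#' @describeIn fit_bilinear One-row model summary.
#' @export
glance.bilinear_fit <- function(x, ...) {
  tibble(z_break = x$z_break, jump = x$jump, sse = x$sse,
         sse_single = x$sse_single, has_interface = x$has_interface,
         n = x$n, channel = x$channel)
}
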