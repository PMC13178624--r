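#' Plot a depth-resolved velocity profile
#'
#' Raw estimates as points, the robust-LOESS smooth and the simulated
#' ground truth (when present) as lines; an optional bilinear fit adds the
#' detected interface depth.
#'
#' @param object A [velocity_profile()].
#' @param fit Optional [fit_bilinear()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_profile <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_index)) +
    ggplot2::labs(x = "depth index", y = "phase velocity (m/s)")
  if (any(!is.na(df$v_raw))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$v_raw,
                                              colour = "raw"),
                                 alpha = 0.6, size = 1)
  }
  if (any(!is.na(df$v_smooth))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$v_smooth,
                                             colour = "smoothed"),
                                linewidth = 0.8)
  }
  if (any(!is.na(df$v_true))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$v_true,
                                             colour = "truth"),
                                linetype = "dashed")
  }
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$z_break,
                                 linetype = "dotted", colour = "red")
  }
  p + ggplot2::scale_colour_manual(
    NULL, values = c(raw = "grey40", smoothed = "#2166ac", truth = "#b2182b"))
}

#' Plot a frequency-wavenumber spectral energy map
#'
#' Tile map of the ROI-restricted spectral energy with the weighted
#' centroid marked; the centroid coordinates' ratio is the phase velocity.
#'
#' @param object A [spectral_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_map <- function(object, ...) {
  df <- expand.grid(k = object$k_axis, f = object$f_axis)
  df$S <- as.vector(object$S)
  tot <- sum(object$S)
  kc <- sum(object$S * object$k_axis) / tot
  fc <- sum(sweep(object$S, 2, object$f_axis, `*`)) / tot
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$f,
                                   fill = .data$S)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = kc, y = fc, colour = "red", shape = 3,
                      size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "wavenumber (cycles/m)", y = "frequency (Hz)",
                  fill = "|S|",
                  subtitle = sprintf("centroid velocity %.2f m/s", fc / kc))
}

#' Plot a PVNet training history
#'
#' @param object A `pvnet_fit` from [train_pvnet()].
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.pvnet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (standardized targets)",
                  colour = NULL)
}
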