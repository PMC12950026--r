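#' Raster plot of a joint encoding
#'
#' Spike raster of the sensory layer (coloured by field) with the driving
#' joint-angle time course overlaid, plus interneuron spike rows, in the style
#' of a hair-plate raster figure.
#'
#' @param object A [encode_joint()] result.
#' @param masked_only Show only position-wired hairs?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_encoding <- function(object, masked_only = FALSE, ...) {
  sp <- object$sensory
  if (masked_only) sp <- sp[sp$masked, , drop = FALSE]
  rng <- range(object$trace$theta)
  n_rows <- max(object$sensory$hair)
  scale01 <- function(x) (x - rng[1]) / max(diff(rng), 1e-9) * n_rows
  ggplot2::ggplot() +
    ggplot2::geom_point(data = sp,
                        ggplot2::aes(x = .data$time / 1000, y = .data$hair,
                                     colour = .data$field),
                        shape = ".", show.legend = TRUE) +
    ggplot2::geom_line(data = object$trace,
                       ggplot2::aes(x = .data$t / 1000,
                                    y = scale01(.data$theta)),
                       linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(neg = "#c0392b", pos = "#2c6fbb")) +
    ggplot2::labs(x = "time (s)", y = "hair index",
                  colour = "field",
                  title = "Hair-plate raster with joint-angle overlay") +
    ggplot2::theme_minimal()
}

#' Heatmap of a calibration grid search
#'
#' @param object A `grid_search` from [grid_search_adex()] or
#'   [grid_search_position()].
#' @param ... Unused.
#' @return A ggplot tile map of the error surface with the argmin marked.
#' @export
autoplot.grid_search <- function(object, ...) {
  p1 <- object$params[1]; p2 <- object$params[2]
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data[[p1]]),
                               y = factor(.data[[p2]]),
                               fill = .data[[object$value]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$argmin, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = p1, y = p2, fill = object$value) +
    ggplot2::theme_minimal()
}

#' Rate-velocity curve with its linear fit
#'
#' @param object An [fit_rate_velocity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$speed, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "angular velocity (deg/s)", y = "mean IN rate (Hz)",
                  subtitle = sprintf("slope %.3g 1/deg, r^2 = %.3f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Model vs reference signal comparison
#'
#' Overlays the z-normalised decoded signal on the z-normalised reference
#' (joint angle or angular velocity).
#'
#' @param error A [position_error()] or [velocity_error()] result.
#' @return A ggplot.
#' @export
plot_signal_comparison <- function(error) {
  df <- dplyr::bind_rows(
    dplyr::mutate(error$reference, series = "reference"),
    dplyr::mutate(error$signal, series = "model"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 1000, y = .data$signal,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "signal (z-units)",
                  subtitle = sprintf("MSE = %.4g", error$mse)) +
    ggplot2::theme_minimal()
}
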