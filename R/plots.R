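# Concentration axes are drawn in deployment order: high concentrations
# (just after application) on the left, decaying rightwards.
transform_revlog10 <- function() {
  scales::trans_new(
    "revlog10",
    transform = function(x) -log10(x),
    inverse = function(x) 10^(-x),
    breaks = function(x) rev(scales::log_breaks()(x)),
    domain = c(1e-100, Inf))
}

scale_x_deployment <- function(axis_kind) {
  if (axis_kind == "concentration") {
    ggplot2::scale_x_continuous(
      name = "concentration (deployment order → decaying)",
      trans = transform_revlog10())
  } else {
    ggplot2::scale_x_continuous(name = "time since deployment")
  }
}

#' Plot a mortality curve
#'
#' Per-arm mortality (percent) against the deployment axis: log10
#' concentration drawn high-to-low, or linear time.
#'
#' @param object A [mortality_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mortality_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$mortality), ],
                  ggplot2::aes(x = .data$axis, y = 100 * .data$mortality,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    scale_x_deployment(curve_axis_kind(object)) +
    ggplot2::labs(y = "mortality (%)", colour = "arm") +
    ggplot2::theme_minimal()
}

#' Plot a window report
#'
#' Shades the open region of the window over the per-point open flags and
#' marks the interpolated boundaries.
#'
#' @param object A [window_report()] with per-point flags.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.window_report <- function(object, ...) {
  flags <- object$flags
  p <- ggplot2::ggplot(flags,
                       ggplot2::aes(x = .data$axis,
                                    y = as.numeric(.data$open))) +
    ggplot2::geom_step() +
    scale_x_deployment(object$axis_kind) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("closed", "open")) +
    ggplot2::labs(y = NULL,
                  title = sprintf("window of %s", object$kind)) +
    ggplot2::theme_minimal()
  if (!object$no_window) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(object$open_at, object$close_at),
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a dominance profile
#'
#' @param object A [dominance_profile()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.dominance_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$dominance), ],
                  ggplot2::aes(x = .data$axis, y = .data$dominance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$clamped)) +
    scale_x_deployment(attr(object, "axis_kind")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "dominance of resistance (h)") +
    ggplot2::theme_minimal()
}

#' Plot a selective-advantage profile
#'
#' @param object A [selection_profile()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.selection_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$z), ],
                  ggplot2::aes(x = .data$axis, y = .data$z,
                               colour = factor(.data$p0))) +
    ggplot2::geom_line() +
    scale_x_deployment(attr(object, "axis_kind")) +
    ggplot2::labs(y = "selective advantage per generation (z)",
                  colour = "starting frequency") +
    ggplot2::theme_minimal()
}

#' Plot a time-to-resistance profile
#'
#' Censored points (threshold not reached within the generation cap) are
#' drawn as hollow triangles pinned at the cap.
#'
#' @param object A [resistance_time_profile()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.resistance_profile <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$censored), ]
  cap <- attr(object, "max_generations")
  df$shown <- ifelse(df$censored, cap, df$generations)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$shown,
                                   colour = factor(.data$p0))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2)) +
    scale_x_deployment(attr(object, "axis_kind")) +
    ggplot2::labs(y = "generations to resistance threshold",
                  colour = "starting frequency", shape = "censored") +
    ggplot2::theme_minimal()
}
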