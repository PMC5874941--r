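#' Plot a gantry-angle trajectory
#'
#' Angle versus time for the `ok` samples.
#'
#' @param object a `gantry_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gantry_trajectory <- function(object, ...) {
  df <- object[object$ok, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$gantry_deg)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time (s)", y = "gantry angle (deg)",
      title = sprintf("Gantry angle vs time (%s)", attr(object, "source"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory comparison
#'
#' Absolute circular deviation versus time, with the mean deviation marked.
#'
#' @param object a `gantry_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gantry_comparison <- function(object, ...) {
  ggplot2::ggplot(object$deviations,
                  ggplot2::aes(x = .data$time_s, y = .data$dev_deg)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$stats$mean_abs_dev_deg,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = "time (s)", y = "|deviation| (deg)",
      title = object$stats$pair_label,
      subtitle = sprintf("mean %.3f deg, 1 SD %.3f deg, max %.3f deg",
                         object$stats$mean_abs_dev_deg,
                         object$stats$sd_dev_deg,
                         object$stats$max_abs_dev_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay two trajectories on one axis
#'
#' @param a,b `gantry_trajectory` objects.
#' @return a ggplot.
#' @export
plot_trajectory_overlay <- function(a, b) {
  df <- dplyr::bind_rows(
    tibble(time_s = a$time_s[a$ok], gantry_deg = a$gantry_deg[a$ok],
           source = attr(a, "source") %||% "a"),
    tibble(time_s = b$time_s[b$ok], gantry_deg = b$gantry_deg[b$ok],
           source = attr(b, "source") %||% "b")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$gantry_deg,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "gantry angle (deg)") +
    ggplot2::theme_minimal()
}
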