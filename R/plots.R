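#' Raster plot of a synchrony grid
#'
#' Windows on the x-axis, directed pairs stacked on the y-axis, significant
#' windows filled; episode boundaries (when a track is attached or supplied)
#' drawn as vertical lines.
#'
#' @param object A [sync_grid()].
#' @param episodes Optional [episode_track()] overriding the attached one.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sync_grid <- function(object, episodes = NULL, ...) {
  df <- as_tibble(object) |>
    mutate(direction = paste0(.data$leader, "→", .data$pacer))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$window_index, y = .data$direction, fill = .data$significant
  )) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "white", `TRUE` = "#2166ac"),
      name = "significant"
    ) +
    ggplot2::labs(
      x = "window index", y = NULL,
      title = sprintf("Synchrony windows, session '%s'",
                      grid_meta(object, "session_id"))
    ) +
    ggplot2::theme_minimal()
  ep <- episodes %||% grid_meta(object, "episodes")
  if (!is.null(ep)) {
    cfg <- grid_meta(object, "config")
    p <- p + ggplot2::geom_vline(
      xintercept = c(ep$start_s, ep$end_s) / cfg$window_length_s - 0.5,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Leading-role network plot
#'
#' Bar chart of windows led and paced per participant, annotated with the
#' balance index.
#'
#' @param object A `network_summary` from [leading_network()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.network_summary <- function(object, ...) {
  df <- object$participants |>
    pivot_longer(c("windows_leading", "windows_pacing"),
                 names_to = "role", values_to = "n_windows") |>
    mutate(role = ifelse(.data$role == "windows_leading", "leading", "pacing"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$participant_id, y = .data$n_windows, fill = .data$role
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "windows",
      title = sprintf("Leading/pacing roles (balance = %.2f)", object$balance)
    ) +
    ggplot2::theme_minimal()
}

#' Calibration curve plot
#'
#' @param object A `calibration_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(object$per_length, ggplot2::aes(
    x = .data$window_length_s, y = .data$mean_fp_fraction
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$tolerance, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$chosen_length_s,
                        colour = "#2166ac") +
    ggplot2::labs(
      x = "window length (s)", y = "false-positive fraction",
      title = "Window-length calibration on null data"
    ) +
    ggplot2::theme_minimal()
}

#' Arousal trace plot for a session
#'
#' @param recording A [session_recording()].
#' @return A ggplot object with one line per participant.
#' @export
plot_session <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  ggplot2::ggplot(as_tibble(recording), ggplot2::aes(
    x = .data$time_s, y = .data$value, colour = .data$participant_id
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "arousal (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}
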