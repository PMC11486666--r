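#' Plot track paths in the xy-plane
#'
#' @param tracks A track table.
#' @param colour_by Optional condition column used for colouring; defaults
#'   to the first condition column, or the track id when none exists.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, colour_by = NULL) {
  cb <- colour_by %||% track_conditions(tracks)[1]
  if (is.null(cb) || is.na(cb)) cb <- "track_id"
  ggplot2::ggplot(as_tibble(tracks),
                  ggplot2::aes(.data$x_um, .data$y_um, group = .data$track_id,
                               colour = .data[[cb]])) +
    ggplot2::geom_path(alpha = 0.7, show.legend = cb != "track_id") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = cb) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prw_fit <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(.data$step, .data$q_hat,
                               group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "frame", y = expression(hat(q)[t])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prw_contours <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$q_mid, .data$a_mid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mass)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mass),
                          breaks = object$thresholds$threshold,
                          colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "persistence q", y = "activity a (µm/min)",
                  fill = "mass") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of merged sub-population proportions
#'
#' @param x A labelled `cluster_report` or a `bootstrap_result` (bars then
#'   carry the bootstrap SD of each proportion).
#' @return A ggplot object.
#' @export
plot_proportions <- function(x) {
  if (inherits(x, "cluster_report")) {
    df <- x$proportions
    ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$proportion,
                                     fill = .data$tag)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "proportion of cells", fill = NULL) +
      ggplot2::theme_minimal()
  } else if (inherits(x, "bootstrap_result")) {
    df <- x$summary
    ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$mean_proportion,
                                     fill = .data$tag)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_cumsum - .data$sd_proportion,
        ymax = .data$mean_cumsum + .data$sd_proportion), width = 0.2) +
      ggplot2::labs(x = NULL, y = "proportion of cells (bootstrap)",
                    fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    abort("`x` must be a cluster_report or bootstrap_result")
  }
}
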