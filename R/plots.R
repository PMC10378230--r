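# ggplot2 views: sagittal-projection plots of the tracks and a mean +/- SD
# dot plot for cohort comparisons.

segment_df <- function(lines, half_len = 80) {
  dplyr::bind_rows(lapply(names(lines), function(nm) {
    l <- lines[[nm]]
    tibble(plane = nm,
           x = l$point[1] - half_len * l$direction[1],
           y = l$point[2] - half_len * l$direction[2],
           xend = l$point[1] + half_len * l$direction[1],
           yend = l$point[2] + half_len * l$direction[2])
  }))
}

trace2d <- function(plane, section) {
  tr <- plane_trace_on_plane(plane, section)
  list(point = project_sagittal(tr$point),
       direction = unit2(project_sagittal(tr$direction)))
}

#' Plot a 2D track
#'
#' Sagittal view (x = anterior, y = posterior-to-anterior in mm) of the
#' four individual lines and, optionally, the neutral lines over the
#' landmarks.
#'
#' @param object An `individual_track_2d` or `neutral_track_2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.individual_track_2d <- function(object, ...) {
  lm <- object$landmarks
  segs <- segment_df(object[c("MCF", "PM", "MR", "FOP")])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$plane)) +
    ggplot2::geom_point(data = lm,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = lm,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior (mm)", y = "superior (mm)",
                  colour = "line", title = "Individual track (2D)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.individual_track_2d
#' @export
autoplot.neutral_track_2d <- function(object, ...) {
  lm <- object$landmarks
  segs <- segment_df(object[c("MCFn", "PMn", "MRn", "FOPn")])
  pts <- tibble(name = c("SEn", "Gon"),
                x = c(object$SEn[1], object$Gon[1]),
                y = c(object$SEn[2], object$Gon[2]))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$plane)) +
    ggplot2::geom_point(data = lm,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 17, colour = "blue") +
    ggplot2::geom_text(data = pts,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -0.8, size = 3, colour = "blue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior (mm)", y = "superior (mm)",
                  colour = "line", title = "Neutral track (2D)") +
    ggplot2::theme_minimal()
}

#' Sagittal view of individual versus neutral 3D tracks
#'
#' Projects the traces of the individual (solid) and neutral (dashed)
#' planes on the mid-sagittal section, mirroring the side-by-side
#' comparison a clinician reads rotational factors from.
#'
#' @param individual An `individual_track_3d`.
#' @param neutral A `neutral_track_3d` from the same landmark set.
#' @return A ggplot object.
#' @export
plot_track_comparison <- function(individual, neutral) {
  stopifnot(inherits(individual, "individual_track_3d"),
            inherits(neutral, "neutral_track_3d"))
  sec <- neutral$section
  ind <- lapply(individual[c("MCF", "PM", "MR", "FOP")], trace2d, section = sec)
  neu <- lapply(neutral[c("MCFn", "PMn", "MRn", "FOPn")], trace2d,
                section = sec)
  segs <- dplyr::bind_rows(
    dplyr::mutate(segment_df(ind), track = "individual"),
    dplyr::mutate(segment_df(neu), track = "neutral")
  )
  ggplot2::ggplot(segs,
                  ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend, colour = .data$plane,
                               linetype = .data$track)) +
    ggplot2::geom_segment() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior (mm)", y = "superior (mm)",
                  title = "Individual vs neutral track (sagittal traces)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.individual_track_2d
#' @export
autoplot.cohort_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(variable = object$variable, mode = "2D",
           mean = object$mean_2d, sd = object$sd_2d),
    tibble(variable = object$variable, mode = "3D",
           mean = object$mean_3d, sd = object$sd_3d)
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$variable, y = .data$mean,
                               colour = .data$mode)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "angle (degrees)",
                  title = "2D vs 3D angle agreement (mean ± SD)") +
    ggplot2::theme_minimal()
}
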