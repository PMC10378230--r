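# broom-style tidiers for the track and comparison objects.

#' Tidy track and comparison objects
#'
#' `tidy()` returns one row per measured quantity; `glance()` a one-row
#' summary.
#'
#' @param x An `individual_track_3d`, `individual_track_2d`,
#'   `neutral_track_3d`, `neutral_track_2d`, `track_report` or
#'   `cohort_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @name track-tidiers
NULL

#' @rdname track-tidiers
#' @export
tidy.individual_track_3d <- function(x, ...) {
  measure_angles_3d(x)
}

#' @rdname track-tidiers
#' @export
tidy.individual_track_2d <- function(x, ...) {
  measure_angles_2d(x)
}

#' @rdname track-tidiers
#' @export
tidy.neutral_track_3d <- function(x, ...) {
  neutral_self_check(x)
}

#' @rdname track-tidiers
#' @export
tidy.neutral_track_2d <- function(x, ...) {
  neutral_self_check(x)
}

#' @rdname track-tidiers
#' @export
tidy.track_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$angles, kind = "individual"),
    tibble(angle = names(x$self_check),
           value = unlist(x$self_check),
           convention = NA_character_,
           kind = "self_check"),
    if (!is.null(x$deltas)) {
      tibble(angle = paste0("delta_", names(x$deltas)),
             value = unlist(x$deltas),
             convention = NA_character_,
             kind = "delta")
    }
  )
}

#' @rdname track-tidiers
#' @export
glance.track_report <- function(x, ...) {
  tibble(subject = x$subject, mode = x$mode,
         mcf_pm = x$angles$value[x$angles$angle == "MCF^PM"],
         mcf_mr = x$angles$value[x$angles$angle == "MCF^MR"],
         neutral_angle = x$config$neutral_angle,
         input_digest = x$input_digest)
}

#' @rdname track-tidiers
#' @export
tidy.cohort_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @rdname track-tidiers
#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(n_variables = nrow(x),
         alpha = attr(x, "alpha") %||% 0.05,
         any_significant = any(x$significant, na.rm = TRUE))
}
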