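# End-to-end subject analysis: individual + neutral track, diagnostic
# angles, neutral self-check, rotational-factor deltas, provenance.

#' Analyze one subject
#'
#' Builds the individual and neutral tracks from a landmark set, measures
#' the diagnostic angles (MCF^PM, MCF^MR), recomputes the neutral
#' self-check identities, and (3D) the individual-versus-neutral plane
#' deltas. The resolved configuration, package version and an input digest
#' are embedded for provenance, so a report fully determines its own
#' reproduction.
#'
#' @param lm A `landmarks_3d` or `landmarks_2d` tibble.
#' @param subject Subject identifier recorded in the report.
#' @param config A [track_config()].
#' @return A `track_report` object: fields `subject`, `mode`, `angles`
#'   (tibble), `self_check`, `deltas` (3D only), `points`, `config`,
#'   `input_digest`.
#' @examples
#' rep <- analyze_subject(as_landmarks_3d(template_landmarks()), "template")
#' rep$angles
#' @export
analyze_subject <- function(lm, subject = "subject", config = track_config()) {
  if (inherits(lm, "landmarks_3d")) {
    findings <- validate_landmarks(lm)
    if (any(findings$severity == "error")) {
      abort(paste("Landmark validation failed:",
                  paste(findings$message[findings$severity == "error"],
                        collapse = " ")),
            class = "trk_error_degenerate")
    }
    ind <- build_individual_track_3d(lm)
    nt <- build_neutral_track_3d(lm, config)
    angles <- measure_angles_3d(ind, convention = config$angle_convention)
    sc <- neutral_self_check(nt)
    deltas <- track_delta(ind, nt)
    points <- list(MCFx = nt$MCFx, SEn = nt$SEn, rSEn = nt$rSEn,
                   lSEn = nt$lSEn, rGon = nt$rGon, lGon = nt$lGon)
    mode <- "3d"
  } else if (inherits(lm, "landmarks_2d")) {
    ind <- build_individual_track_2d(lm)
    nt <- build_neutral_track_2d(lm, config)
    angles <- measure_angles_2d(ind)
    sc <- neutral_self_check(nt)
    deltas <- NULL
    points <- list(SEn = nt$SEn, Gon = nt$Gon)
    mode <- "2d"
  } else {
    abort("`lm` must be a landmarks_3d or landmarks_2d object.",
          class = "trk_error_malformed")
  }
  structure(
    list(
      subject = as.character(subject),
      mode = mode,
      angles = angles,
      self_check = stats::setNames(as.list(sc$value), sc$check),
      deltas = if (!is.null(deltas)) {
        stats::setNames(as.list(deltas$delta), deltas$plane)
      },
      points = points,
      config = config,
      input_digest = rlang::hash(lm)
    ),
    class = "track_report"
  )
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf("<track_report> subject '%s' (%s)\n", x$subject, x$mode))
  print(x$angles)
  cat("neutral self-check:\n")
  for (nm in names(x$self_check)) {
    cat(sprintf("  %-9s %10.4f deg\n", nm, x$self_check[[nm]]))
  }
  invisible(x)
}

#' Analyze a full paired cohort
#'
#' Convenience wrapper around [cohort_angle_table()] and
#' [compare_2d_3d_cohort()]: measures every subject in both 2D and 3D and
#' returns the method-agreement table.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (list-columns
#'   `lm3d`, `lm2d`).
#' @param config A [track_config()].
#' @return A `cohort_comparison` tibble.
#' @examples
#' analyze_cohort(generate_cohort(n = 6, seed = 3))
#' @export
analyze_cohort <- function(cohort, config = track_config()) {
  tab <- cohort_angle_table(cohort, convention = config$angle_convention)
  n_ok <- length(unique(tab$subject))
  if (n_ok < 2) {
    abort("Fewer than 2 analyzable subjects; cannot run the paired comparison.",
          class = "trk_error_insufficient_data")
  }
  if (n_ok < nrow(cohort)) {
    warn(sprintf("%d of %d subjects skipped.", nrow(cohort) - n_ok,
                 nrow(cohort)))
  }
  compare_2d_3d_cohort(tab, alpha = config$alpha)
}
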