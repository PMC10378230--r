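#' Analysis configuration
#'
#' A single configuration object carried through every track construction
#' and embedded verbatim in analysis reports for provenance.
#'
#' @param angle_convention How 3D inter-plane angles are reported.
#'   `"trace"` (default) measures the angle between the planes' traces on
#'   the mid-sagittal section, with anatomical orientation hints, so values
#'   are directly comparable to 2D cephalogram vertex angles. `"dihedral"`
#'   reports the classical dihedral angle between plane normals.
#' @param mcfn_mode Placement rule for the lateral helper points rSEn/lSEn
#'   that define the neutral middle-cranial-floor plane. `"tangent"`
#'   (default) offsets SEn laterally along the sagittal normal, which makes
#'   the plane contain the Ba--SEn ray exactly and the neutral cranial-base
#'   angle hold to machine precision, independent of `delta`. `"on_sphere"`
#'   keeps the helper points on the construction sphere at SEn's level
#'   (an axial circle), with a small, `delta`-dependent deviation of the
#'   trace angle.
#' @param delta Lateral half-distance between rSEn and lSEn, in mm.
#'   Must be at least 0.1 mm.
#' @param neutral_angle The neutral cranial-base angle in degrees. The
#'   clinical constant is 40.3; it is exposed for sensitivity analyses only.
#' @param frame Coordinate convention of input landmark files: `"RAS"`
#'   (x = right, y = anterior, z = superior; the internal frame) or
#'   `"LPS"` (x = left, y = posterior, z = superior).
#' @param alpha Significance level for cohort comparisons.
#' @param tol_degenerate Geometric degeneracy tolerance (mm or mm^2).
#' @param tol_angle Angle assertion tolerance in degrees.
#'
#' @return A list with class `"track_config"`.
#' @examples
#' track_config()
#' track_config(angle_convention = "dihedral", delta = 10)
#' @export
track_config <- function(angle_convention = c("trace", "dihedral"),
                         mcfn_mode = c("tangent", "on_sphere"),
                         delta = 5,
                         neutral_angle = 40.3,
                         frame = c("RAS", "LPS"),
                         alpha = 0.05,
                         tol_degenerate = 1e-9,
                         tol_angle = 1e-6) {
  angle_convention <- match.arg(angle_convention)
  mcfn_mode <- match.arg(mcfn_mode)
  frame <- match.arg(frame)
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0.1) {
    abort("`delta` must be a single number >= 0.1 mm.",
          class = "trk_error_degenerate")
  }
  if (!is.numeric(neutral_angle) || neutral_angle <= 0 || neutral_angle >= 90) {
    abort("`neutral_angle` must lie strictly between 0 and 90 degrees.",
          class = "trk_error_degenerate")
  }
  structure(
    list(
      angle_convention = angle_convention,
      mcfn_mode = mcfn_mode,
      delta = delta,
      neutral_angle = neutral_angle,
      frame = frame,
      alpha = alpha,
      tol_degenerate = tol_degenerate,
      tol_angle = tol_angle,
      version = as.character(utils::packageVersion("neutraltrack"))
    ),
    class = "track_config"
  )
}

#' @export
print.track_config <- function(x, ...) {
  cat("<track_config>\n")
  for (nm in setdiff(names(x), "version")) {
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
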