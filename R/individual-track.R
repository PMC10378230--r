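# The subject's individual track: the four structural planes (3D) or lines
# (2D) and the two diagnostic angles MCF^PM and MCF^MR.

#' Build the 3D individual track
#'
#' Constructs the four subject planes by the "plane through three points"
#' rule: MCF through rMCF, lMCF and Ba; PM through lMCF, rMCF and PNS; MR
#' through mCo, rGo and lGo; FOP through rPoc, lPoc and mAoc. The
#' estimated mid-sagittal section is attached for trace-angle measurement.
#'
#' @param lm A `landmarks_3d` tibble.
#' @return An object of class `individual_track_3d`: the four
#'   `track_plane`s, the mid-sagittal section, and the landmark set.
#' @examples
#' trk <- build_individual_track_3d(as_landmarks_3d(template_landmarks()))
#' measure_angles_3d(trk)
#' @export
build_individual_track_3d <- function(lm) {
  stopifnot(inherits(lm, "landmarks_3d"))
  defs <- list(
    MCF = c("rMCF", "lMCF", "Ba"),
    PM  = c("lMCF", "rMCF", "PNS"),
    MR  = c("mCo", "rGo", "lGo"),
    FOP = c("rPoc", "lPoc", "mAoc")
  )
  planes <- lapply(names(defs), function(nm) {
    pts <- lapply(defs[[nm]], function(n) lmk(lm, n))
    tryCatch(plane_from_points(pts[[1]], pts[[2]], pts[[3]]),
             trk_error_degenerate = function(e) {
               abort(sprintf("%s plane degenerate: defining landmarks %s are collinear or coincident.",
                             nm, paste(defs[[nm]], collapse = ", ")),
                     class = "trk_error_degenerate")
             })
  })
  names(planes) <- names(defs)
  structure(
    c(planes, list(section = midsagittal_plane(lm), landmarks = lm)),
    class = "individual_track_3d"
  )
}

#' Build the 2D individual track
#'
#' The four cephalogram lines: MCF = SE--Ar, PM = SE--Ptm, MR = Ar--Go,
#' FOP = Poc--Aoc.
#'
#' @param lm A `landmarks_2d` tibble.
#' @return An object of class `individual_track_2d`.
#' @export
build_individual_track_2d <- function(lm) {
  stopifnot(inherits(lm, "landmarks_2d"))
  defs <- list(MCF = c("SE", "Ar"), PM = c("SE", "Ptm"),
               MR = c("Ar", "Go"), FOP = c("Poc", "Aoc"))
  lines <- lapply(names(defs), function(nm) {
    tryCatch(line2_through(lmk(lm, defs[[nm]][1]), lmk(lm, defs[[nm]][2])),
             trk_error_degenerate = function(e) {
               abort(sprintf("%s line degenerate: %s and %s coincide.",
                             nm, defs[[nm]][1], defs[[nm]][2]),
                     class = "trk_error_degenerate")
             })
  })
  names(lines) <- names(defs)
  structure(c(lines, list(landmarks = lm)), class = "individual_track_2d")
}

#' Measure the individual-track angles in 3D
#'
#' Reports MCF^PM and MCF^MR. Under the default `"trace"` convention the
#' planes are cut by the mid-sagittal section and the traces are oriented
#' anatomically: for MCF^PM (the anterior cranial-base angle, vertex at the
#' sagittal crossing MCFx of the rMCF--lMCF chord) the MCF trace points
#' toward Ba and the PM trace toward PNS; for MCF^MR (the posterior,
#' typically obtuse angle) the MCF trace points from Ba toward the cranial
#' end and the MR trace from condylar toward gonial level. These values are
#' directly comparable with 2D cephalogram vertex angles. `"dihedral"`
#' reports classical inter-normal angles instead.
#'
#' @param track An `individual_track_3d`.
#' @param convention `"trace"` (default) or `"dihedral"`.
#' @return A tibble with columns `angle` (`"MCF^PM"`, `"MCF^MR"`),
#'   `value` (degrees) and `convention`.
#' @export
measure_angles_3d <- function(track, convention = c("trace", "dihedral")) {
  stopifnot(inherits(track, "individual_track_3d"))
  convention <- match.arg(convention)
  lm <- track$landmarks
  if (convention == "dihedral") {
    vals <- c(dihedral_angle(track$MCF, track$PM),
              dihedral_angle(track$MCF, track$MR))
  } else {
    sag <- track$section
    mcfx <- segment_plane_intersection(lmk(lm, "rMCF"), lmk(lm, "lMCF"), sag)
    ba <- lmk(lm, "Ba")
    pns <- lmk(lm, "PNS")
    mgo <- (lmk(lm, "rGo") + lmk(lm, "lGo")) / 2
    mco <- lmk(lm, "mCo")
    vals <- c(
      oriented_trace_angle(track$MCF, track$PM, sag,
                           orient_a = ba - mcfx, orient_b = pns - mcfx),
      oriented_trace_angle(track$MCF, track$MR, sag,
                           orient_a = mcfx - ba, orient_b = mgo - mco)
    )
  }
  tibble(angle = c("MCF^PM", "MCF^MR"), value = vals,
         convention = convention)
}

#' Measure the individual-track angles in 2D
#'
#' MCF^PM is the vertex angle at SE between the rays SE to Ar and SE to
#' Ptm; MCF^MR is the vertex angle at Ar between the rays Ar to SE and Ar
#' to Go (the posterior, typically obtuse angle).
#'
#' @param track An `individual_track_2d`.
#' @return A tibble with columns `angle`, `value`, `convention`
#'   (`"vertex"`).
#' @export
measure_angles_2d <- function(track) {
  stopifnot(inherits(track, "individual_track_2d"))
  lm <- track$landmarks
  tibble(
    angle = c("MCF^PM", "MCF^MR"),
    value = c(angle_at_vertex(lmk(lm, "Ar"), lmk(lm, "SE"), lmk(lm, "Ptm")),
              angle_at_vertex(lmk(lm, "SE"), lmk(lm, "Ar"), lmk(lm, "Go"))),
    convention = "vertex"
  )
}

#' @export
print.individual_track_3d <- function(x, ...) {
  cat("<individual_track_3d> planes: MCF, PM, MR, FOP (+ mid-sagittal section)\n")
  print(measure_angles_3d(x))
  invisible(x)
}

#' @export
print.individual_track_2d <- function(x, ...) {
  cat("<individual_track_2d> lines: MCF (SE-Ar), PM (SE-Ptm), MR (Ar-Go), FOP (Poc-Aoc)\n")
  print(measure_angles_2d(x))
  invisible(x)
}
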