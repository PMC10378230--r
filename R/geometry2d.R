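# Planar counterparts for the lateral-cephalogram analysis.
# 2D frame: x = anterior, y = superior (the subject faces +x); this is the
# (y, z) sagittal section of the 3D frame, so 3D landmarks project to 2D
# by dropping x.

check_point2 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 2 || !all(is.finite(p))) {
    abort(sprintf("A 2D %s must be a finite numeric vector of length 2.", what),
          class = "trk_error_degenerate")
  }
  unname(as.numeric(p))
}

unit2 <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < tol) {
    abort("Cannot normalize a (near-)zero 2D vector.",
          class = "trk_error_degenerate")
  }
  v / n
}

# Counter-clockwise rotation of a 2D vector by `deg` degrees.
rot2 <- function(v, deg) {
  a <- deg / DEG
  c(cos(a) * v[1] - sin(a) * v[2],
    sin(a) * v[1] + cos(a) * v[2])
}

#' Infinite 2D line through a point
#'
#' Cephalogram "lines" (MCF = SE--Ar, PM = SE--Ptm, ...) are infinite lines
#' through two landmarks; constructions such as parallels and
#' perpendiculars need the infinite extent.
#'
#' @param point Numeric length-2 point (mm).
#' @param direction Numeric length-2 direction; normalized internally.
#' @return An object of class `"track_line2"`.
#' @export
new_line2 <- function(point, direction) {
  structure(list(point = check_point2(point, "line point"),
                 direction = unit2(check_point2(direction, "line direction"))),
            class = "track_line2")
}

line2_through <- function(a, b) {
  a <- check_point2(a); b <- check_point2(b)
  if (sqrt(sum((b - a)^2)) < 1e-12) {
    abort("Degenerate geometry: the two points defining a line coincide.",
          class = "trk_error_degenerate")
  }
  new_line2(a, b - a)
}

#' Vertex angle between two rays
#'
#' The classical cephalometric angle at a vertex `v` between the rays
#' `v -> a` and `v -> b`, in degrees, in `[0, 180]`.
#'
#' @param a,v,b Numeric length-2 points; `a` and `b` must differ from `v`.
#' @return Angle in degrees.
#' @examples
#' angle_at_vertex(c(1, 0), c(0, 0), c(0, 1))
#' @export
angle_at_vertex <- function(a, v, b) {
  a <- check_point2(a); v <- check_point2(v); b <- check_point2(b)
  ra <- a - v
  rb <- b - v
  if (sqrt(sum(ra^2)) < 1e-12 || sqrt(sum(rb^2)) < 1e-12) {
    abort("Degenerate vertex: a ray endpoint coincides with the vertex.",
          class = "trk_error_degenerate")
  }
  ua <- unit2(ra)
  ub <- unit2(rb)
  atan2(abs(ua[1] * ub[2] - ua[2] * ub[1]), sum(ua * ub)) * DEG
}

#' Point on a 2D circle at a given angle from a reference direction
#'
#' Among the two circle points whose ray from the centre makes `angle` with
#' `ref_dir`, the branch selector picks one. This realizes the 2D SEn rule:
#' the point of a circumference centred in Ar at which the required
#' cranial-base angle is obtained.
#'
#' @param center Circle centre (mm).
#' @param radius Circle radius (mm), positive.
#' @param ref_dir Reference unit direction.
#' @param angle Angle from `ref_dir` in degrees, in `(0, 180)`; the
#'   boundary values 0 and 180 leave a single candidate and are accepted.
#' @param branch Numeric length-2 preference direction, or one of
#'   `"anterior"`, `"posterior"`, `"superior"`, `"inferior"` (combinable as
#'   e.g. `"anterior-superior"`). The candidate maximizing the dot product
#'   with the preference direction wins; a tie raises a branch-ambiguity
#'   error.
#' @return The selected point.
#' @examples
#' circle_point_at_angle_2d(c(0, 0), 50, c(0, 1), 40.3, "anterior")
#' @export
circle_point_at_angle_2d <- function(center, radius, ref_dir, angle, branch) {
  center <- check_point2(center)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number.",
          class = "trk_error_degenerate")
  }
  if (!is.numeric(angle) || length(angle) != 1 || angle < 0 || angle > 180) {
    abort("`angle` must lie in [0, 180] degrees.",
          class = "trk_error_degenerate")
  }
  d0 <- unit2(check_point2(ref_dir, "reference direction"))
  dirs <- dedupe_points(list(rot2(d0, angle), rot2(d0, -angle)), tol = 1e-9)
  pts <- lapply(dirs, function(d) center + radius * d)
  hint <- branch_hint2(branch)
  scores <- vapply(dirs, function(d) sum(d * hint), 0)
  ord <- order(scores, decreasing = TRUE)
  if (length(ord) > 1 && scores[ord[1]] - scores[ord[2]] < 1e-9) {
    abort("Branch selector does not isolate a single candidate point.",
          class = "trk_error_branch_ambiguity")
  }
  pts[[ord[1]]]
}

branch_hint2 <- function(branch) {
  if (is.numeric(branch)) return(unit2(check_point2(branch, "branch hint")))
  axes <- list(anterior = c(1, 0), posterior = c(-1, 0),
               superior = c(0, 1), inferior  = c(0, -1))
  parts <- strsplit(branch, "-", fixed = TRUE)[[1]]
  if (!all(parts %in% names(axes))) {
    abort(sprintf("Unknown branch selector '%s'.", branch),
          class = "trk_error_branch_ambiguity")
  }
  unit2(Reduce(`+`, axes[parts]))
}

#' Perpendicular distance from a point to a 2D line
#'
#' @param p Numeric length-2 point.
#' @param l A `track_line2`.
#' @return Unsigned distance in mm.
#' @export
distance_point_line_2d <- function(p, l) {
  stopifnot(inherits(l, "track_line2"))
  abs(signed_distance_line2(p, l))
}

# Signed distance: positive on the side of the left-hand normal
# (direction rotated +90 degrees).
signed_distance_line2 <- function(p, l) {
  p <- check_point2(p)
  n <- c(-l$direction[2], l$direction[1])
  sum((p - l$point) * n)
}
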