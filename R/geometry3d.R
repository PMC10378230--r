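# 3D geometric primitives for the track constructions. Points and
# directions are plain numeric length-3 vectors in the internal frame
# (x = subject's right, y = anterior, z = superior; millimetres).

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    abort("Cannot normalize a (near-)zero vector.",
          class = "trk_error_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two unit vectors in degrees, accurate near 0 and 180
# (atan2 of cross-product norm and dot product; acos loses ~1e-8 rad of
# precision exactly where the parallelism identities are asserted).
unit_angle3 <- function(a, b) {
  atan2(vnorm(cross3(a, b)), sum(a * b)) * DEG
}

check_point3 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3 || !all(is.finite(p))) {
    abort(sprintf("A %s must be a finite numeric vector of length 3.", what),
          class = "trk_error_degenerate")
  }
  unname(as.numeric(p))
}

#' Geometric construction elements
#'
#' Constructors for the plane, sphere, circle and line objects used by the
#' track builders. A plane is stored as an anchor point plus a unit normal;
#' membership and signed distance follow from `(p - anchor) . normal`.
#'
#' @param anchor,center,point Numeric length-3 point (mm).
#' @param normal,direction,plane_normal Numeric length-3 vector; normalized
#'   internally.
#' @param radius Positive radius in mm.
#' @return An object of class `"track_plane"`, `"track_sphere"`,
#'   `"track_circle"` or `"track_line"`.
#' @examples
#' new_plane(c(0, 0, 0), c(0, 0, 1))
#' new_sphere(c(0, 0, 0), 48.5)
#' @name geometry-constructors
NULL

#' @rdname geometry-constructors
#' @export
new_plane <- function(anchor, normal) {
  structure(list(anchor = check_point3(anchor, "plane anchor"),
                 normal = unit(check_point3(normal, "plane normal"))),
            class = "track_plane")
}

#' @rdname geometry-constructors
#' @export
new_sphere <- function(center, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    abort("Sphere radius must be a single positive number.",
          class = "trk_error_degenerate")
  }
  structure(list(center = check_point3(center, "sphere center"),
                 radius = as.numeric(radius)),
            class = "track_sphere")
}

#' @rdname geometry-constructors
#' @export
new_circle <- function(center, radius, plane_normal) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("Circle radius must be a single positive number.",
          class = "trk_error_degenerate")
  }
  structure(list(center = check_point3(center, "circle center"),
                 radius = as.numeric(radius),
                 plane_normal = unit(check_point3(plane_normal))),
            class = "track_circle")
}

#' @rdname geometry-constructors
#' @export
new_line3 <- function(point, direction) {
  structure(list(point = check_point3(point, "line point"),
                 direction = unit(check_point3(direction, "line direction"))),
            class = "track_line")
}

#' @export
print.track_plane <- function(x, ...) {
  cat(sprintf("<plane> anchor (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Plane through three points
#'
#' The fundamental construction rule of the 3D track: every individual and
#' neutral plane is a "plane passing through 3 points". The normal is
#' oriented by the right-hand rule on `(p2 - p1, p3 - p1)`.
#'
#' @param p1,p2,p3 Numeric length-3 points (mm).
#' @param tol Degeneracy tolerance: triangle area below `tol` mm^2 errors.
#' @return A `track_plane` containing all three points.
#' @examples
#' plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' @export
plane_from_points <- function(p1, p2, p3, tol = 1e-9) {
  p1 <- check_point3(p1); p2 <- check_point3(p2); p3 <- check_point3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) / 2 < tol) {
    abort("Degenerate geometry: the three points are collinear or coincident.",
          class = "trk_error_degenerate")
  }
  new_plane(p1, n)
}

#' Parallel plane through a point
#'
#' Used for the construction planes CPBa (through Ba parallel to PM) and
#' CPCo (through mCo parallel to PMn).
#'
#' @param ref A `track_plane`.
#' @param p Numeric length-3 point the result must contain.
#' @return A `track_plane` with the same (same-sign) normal as `ref`.
#' @export
plane_parallel_through <- function(ref, p) {
  stopifnot(inherits(ref, "track_plane"))
  new_plane(check_point3(p), ref$normal)
}

#' Plane through a chord, perpendicular to a reference plane
#'
#' Used for the gonion plane GoP (through rGo and lGo, normal to PMn) and
#' the neutral occlusal plane FOPn (through rPoc and lPoc, perpendicular
#' to PMn).
#'
#' @param ref A `track_plane` the result must be perpendicular to.
#' @param a,b Endpoints of the chord the result must contain.
#' @param tol Degeneracy tolerance on the chord-normal cross product.
#' @return A `track_plane` containing `a` and `b`, at 90 degrees to `ref`;
#'   its normal is proportional to `ref$normal x (b - a)`.
#' @export
plane_perpendicular_through_chord <- function(ref, a, b, tol = 1e-9) {
  stopifnot(inherits(ref, "track_plane"))
  a <- check_point3(a); b <- check_point3(b)
  n <- cross3(ref$normal, b - a)
  if (vnorm(n) < tol) {
    abort("Degenerate geometry: chord is parallel to the reference normal.",
          class = "trk_error_degenerate")
  }
  new_plane(a, n)
}

#' Dihedral angle between two planes
#'
#' The arc-cosine of the normals' dot product, in degrees, in `[0, 180]`.
#' Orientation-sensitive through the normals' signs (parallel same-sign
#' planes give 0); symmetric in its arguments.
#'
#' @param a,b `track_plane` objects.
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(new_plane(c(0, 0, 0), c(0, 0, 1)),
#'                new_plane(c(0, 0, 0), c(0, 1, 0)))
#' @export
dihedral_angle <- function(a, b) {
  stopifnot(inherits(a, "track_plane"), inherits(b, "track_plane"))
  unit_angle3(a$normal, b$normal)
}

#' Signed distance from a point to a plane
#'
#' `(p - anchor) . normal`, in mm; the sign follows the plane normal.
#'
#' @param p Numeric length-3 point.
#' @param plane A `track_plane`.
#' @return Signed distance in mm.
#' @export
signed_distance <- function(p, plane) {
  stopifnot(inherits(plane, "track_plane"))
  sum((check_point3(p) - plane$anchor) * plane$normal)
}

#' Trace of a plane on a section plane
#'
#' The intersection line of two non-parallel planes. All sagittal-view
#' constructions and trace-angle measurements operate on such traces.
#'
#' @param p,section `track_plane` objects.
#' @param tol Parallelism tolerance on the normals' cross product.
#' @return A `track_line` lying in both planes, with direction
#'   proportional to `p$normal x section$normal`.
#' @export
plane_trace_on_plane <- function(p, section, tol = 1e-9) {
  stopifnot(inherits(p, "track_plane"), inherits(section, "track_plane"))
  d <- cross3(p$normal, section$normal)
  if (vnorm(d) < tol) {
    abort("Degenerate geometry: planes are parallel, no trace line.",
          class = "trk_error_degenerate")
  }
  # Point on both planes: linear combination of the normals.
  b1 <- sum(p$normal * p$anchor)
  b2 <- sum(section$normal * section$anchor)
  n12 <- sum(p$normal * section$normal)
  det <- 1 - n12^2
  c1 <- (b1 - b2 * n12) / det
  c2 <- (b2 - b1 * n12) / det
  new_line3(c1 * p$normal + c2 * section$normal, d)
}

#' Oriented angle between two plane traces on a section
#'
#' The 3D analogue of a 2D cephalometric vertex angle: both planes are cut
#' by the section (normally the mid-sagittal plane), each trace direction is
#' flipped to have a positive dot product with its anatomical orientation
#' hint, and the angle between the oriented directions is returned. When all
#' defining landmarks lie in `section` this reduces exactly to the 2D
#' vertex angle.
#'
#' @param a,b `track_plane` objects, neither parallel to `section`.
#' @param section The cutting `track_plane`.
#' @param orient_a,orient_b Numeric length-3 orientation hints; each must
#'   not be perpendicular to its trace.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
oriented_trace_angle <- function(a, b, section, orient_a, orient_b) {
  ta <- plane_trace_on_plane(a, section)
  tb <- plane_trace_on_plane(b, section)
  da <- orient_direction(ta$direction, orient_a)
  db <- orient_direction(tb$direction, orient_b)
  unit_angle3(da, db)
}

orient_direction <- function(d, hint, tol = 1e-12) {
  hint <- check_point3(hint, "orientation hint")
  s <- sum(d * hint)
  if (abs(s) < tol) {
    abort("Orientation hint is perpendicular to the trace direction.",
          class = "trk_error_degenerate")
  }
  if (s < 0) -d else d
}

#' Intersection of a segment with a plane
#'
#' Locates e.g. MCFx, the crossing of the rMCF--lMCF chord with the
#' mid-sagittal plane.
#'
#' @param a,b Segment endpoints (mm).
#' @param plane A `track_plane`.
#' @param tol Tolerance for "endpoint on plane".
#' @return The intersection point, on the segment and on the plane.
#' @export
segment_plane_intersection <- function(a, b, plane, tol = 1e-9) {
  a <- check_point3(a); b <- check_point3(b)
  da <- signed_distance(a, plane)
  db <- signed_distance(b, plane)
  if (abs(da) < tol && abs(db) < tol) {
    abort("Degenerate geometry: segment lies in the plane.",
          class = "trk_error_degenerate")
  }
  if (da * db > 0 && abs(da) > tol && abs(db) > tol) {
    abort("No intersection: both segment endpoints are strictly on the same side of the plane.",
          class = "trk_error_no_intersection")
  }
  t <- da / (da - db)
  a + t * (b - a)
}

#' Intersection of a sphere with a plane
#'
#' The construction sphere centred in Ba, cut by the sagittal plane, gives
#' the circumference on which SEn is sought.
#'
#' @param s A `track_sphere`.
#' @param plane A `track_plane`.
#' @return A `track_circle`; its centre is the orthogonal projection of the
#'   sphere centre onto the plane and its radius is `sqrt(r^2 - d^2)`.
#'   Tangency or a miss raises a no-intersection error.
#' @export
sphere_plane_intersection <- function(s, plane) {
  stopifnot(inherits(s, "track_sphere"), inherits(plane, "track_plane"))
  d <- signed_distance(s$center, plane)
  if (abs(d) >= s$radius) {
    abort("No intersection: the plane misses (or is tangent to) the sphere.",
          class = "trk_error_no_intersection")
  }
  new_circle(s$center - d * plane$normal,
             sqrt(s$radius^2 - d^2),
             plane$normal)
}

# Drop candidates that coincide within tolerance (boundary angles generate
# the same point from two parameter values).
dedupe_points <- function(pts, tol) {
  keep <- list()
  for (p in pts) {
    dup <- any(vapply(keep, function(q) sqrt(sum((p - q)^2)) < tol, TRUE))
    if (!dup) keep[[length(keep) + 1]] <- p
  }
  keep
}

branch_hint3 <- function(branch) {
  if (is.numeric(branch)) return(unit(check_point3(branch, "branch hint")))
  axes <- list(anterior  = c(0, 1, 0),  posterior = c(0, -1, 0),
               superior  = c(0, 0, 1),  inferior  = c(0, 0, -1),
               right     = c(1, 0, 0),  left      = c(-1, 0, 0))
  parts <- strsplit(branch, "-", fixed = TRUE)[[1]]
  if (!all(parts %in% names(axes))) {
    abort(sprintf("Unknown branch selector '%s'.", branch),
          class = "trk_error_branch_ambiguity")
  }
  unit(Reduce(`+`, axes[parts]))
}

#' Point on a circle at a given angle to a reference plane
#'
#' Realizes the "build an angle on the construction plane so that one side
#' lies on the plane and the other intersects the circumference" step of
#' the neutral-track construction. The angle is drawn in the circle's own
#' plane (the sagittal slice): one side lies along the trace of `ref` on
#' that plane, the other is the ray from the centre to the returned point.
#' Measuring against the trace rather than the 3D elevation keeps the
#' constructed trace angle exact even when `ref` is tilted relative to the
#' slice, as it is for asymmetric subjects.
#'
#' @param c A `track_circle` whose centre lies on `ref`.
#' @param ref The reference (construction) `track_plane`; must not be
#'   parallel to the circle plane.
#' @param angle Angle from the trace line, degrees, in `(0, 90]`.
#' @param branch Either a numeric length-3 preference direction (the
#'   candidate maximizing the dot product of centre-to-candidate with it is
#'   returned) or an anatomical selector string such as
#'   `"anterior-superior"`.
#' @param tol Geometric tolerance.
#' @return The selected point on the circle. A branch-ambiguity error is
#'   raised when the selector ties between materially different candidates.
#' @export
point_on_circle_at_angle <- function(c, ref, angle, branch, tol = 1e-9) {
  stopifnot(inherits(c, "track_circle"), inherits(ref, "track_plane"))
  if (!is.numeric(angle) || length(angle) != 1 || angle <= 0 || angle > 90) {
    abort("`angle` must lie in (0, 90] degrees.",
          class = "trk_error_degenerate")
  }
  if (abs(signed_distance(c$center, ref)) > 1e-6) {
    abort("The circle centre must lie on the reference plane.",
          class = "trk_error_degenerate")
  }
  nc <- c$plane_normal
  tr <- cross3(ref$normal, nc)   # trace of ref on the circle plane
  if (vnorm(tr) < tol) {
    abort("Degenerate geometry: the reference plane is parallel to the circle plane.",
          class = "trk_error_degenerate")
  }
  e1 <- unit(tr)
  e2 <- cross3(nc, e1)
  ca <- cos(angle / DEG)
  sa <- sin(angle / DEG)
  pts <- list(c$center + c$radius * (ca * e1 + sa * e2),
              c$center + c$radius * (ca * e1 - sa * e2),
              c$center + c$radius * (-ca * e1 + sa * e2),
              c$center + c$radius * (-ca * e1 - sa * e2))
  pts <- dedupe_points(pts, tol = 1e-9 * max(1, c$radius))
  hint <- branch_hint3(branch)
  scores <- vapply(pts, function(p) sum(unit(p - c$center) * hint), 0)
  ord <- order(scores, decreasing = TRUE)
  if (length(ord) > 1 && scores[ord[1]] - scores[ord[2]] < 1e-9 &&
      vnorm(pts[[ord[1]]] - pts[[ord[2]]]) > 1e-6 * max(1, c$radius)) {
    abort("Branch selector does not isolate a single candidate point.",
          class = "trk_error_branch_ambiguity")
  }
  pts[[ord[1]]]
}
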