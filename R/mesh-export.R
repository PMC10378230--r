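# Export track planes as mesh patches for 3D review: each plane is clipped
# against an axis-aligned bounding box, triangulated, named and coloured by
# track (individual planes white, neutral planes blue). ASCII PLY carries
# per-face colour; STL is binary little-endian.

#' Export track planes as a mesh
#'
#' @param planes A named list of `track_plane` objects (e.g.
#'   `list(MCF = ..., MCFn = ...)`).
#' @param bounds Numeric length 6: `c(xmin, xmax, ymin, ymax, zmin, zmax)`
#'   in mm, with positive extent on every axis.
#' @param path Output file path.
#' @param format `"ply"` (ASCII, per-face colour) or `"stl"` (binary
#'   little-endian).
#' @param group Character vector parallel to `planes` with values
#'   `"individual"` or `"neutral"`; by default neutral is inferred from a
#'   trailing `n` in the plane name (MCFn, PMn, MRn, FOPn).
#' @return `path`, invisibly.
#' @examples
#' \dontrun{
#' nt <- build_neutral_track_3d(as_landmarks_3d(template_landmarks()))
#' export_planes_mesh(list(PMn = nt$PMn, MCFn = nt$MCFn),
#'                    bounds = c(-60, 60, -20, 80, -70, 50),
#'                    path = tempfile(fileext = ".ply"))
#' }
#' @export
export_planes_mesh <- function(planes, bounds, path,
                               format = c("ply", "stl"), group = NULL) {
  format <- match.arg(format)
  if (!length(planes)) {
    abort("Empty plane list: nothing to export.", class = "trk_error_empty_input")
  }
  if (!is.numeric(bounds) || length(bounds) != 6 ||
      any(bounds[c(2, 4, 6)] <= bounds[c(1, 3, 5)])) {
    abort("`bounds` must be c(xmin, xmax, ymin, ymax, zmin, zmax) with positive extent.",
          class = "trk_error_degenerate")
  }
  nms <- names(planes) %||% paste0("plane", seq_along(planes))
  if (is.null(group)) {
    group <- ifelse(grepl("n$", nms), "neutral", "individual")
  }
  patches <- lapply(seq_along(planes), function(i) {
    poly <- clip_plane_to_box(planes[[i]], bounds)
    list(name = nms[i], group = group[i], vertices = poly,
         normal = planes[[i]]$normal)
  })
  if (format == "ply") write_ply_patches(patches, path)
  else write_stl_patches(patches, path)
  invisible(path)
}

# Convex polygon of plane-box intersection: intersect the plane with the 12
# box edges, add box corners lying on the plane, order around the centroid.
clip_plane_to_box <- function(plane, bounds, tol = 1e-9) {
  corners <- as.matrix(expand.grid(x = bounds[1:2], y = bounds[3:4],
                                   z = bounds[5:6]))
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  d <- apply(corners, 1, signed_distance, plane = plane)
  pts <- list()
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (abs(d[i]) < tol) pts[[length(pts) + 1]] <- corners[i, ]
    if (abs(d[j]) < tol) pts[[length(pts) + 1]] <- corners[j, ]
    if (d[i] * d[j] < 0) {
      t <- d[i] / (d[i] - d[j])
      pts[[length(pts) + 1]] <- corners[i, ] + t * (corners[j, ] - corners[i, ])
    }
  }
  pts <- dedupe_points(pts, tol = 1e-7)
  if (length(pts) < 3) {
    abort("Plane does not intersect the bounding box.",
          class = "trk_error_no_intersection")
  }
  ctr <- Reduce(`+`, pts) / length(pts)
  u <- unit(pts[[1]] - ctr)
  v <- cross3(plane$normal, u)
  ang <- vapply(pts, function(p) {
    atan2(sum((p - ctr) * v), sum((p - ctr) * u))
  }, 0)
  do.call(rbind, pts[order(ang)])
}

fan_triangles <- function(nvert) {
  if (nvert < 3) return(matrix(integer(), ncol = 3))
  cbind(1L, 2:(nvert - 1), 3:nvert)
}

GROUP_COLORS <- list(individual = c(255L, 255L, 255L),
                     neutral = c(0L, 0L, 255L))

write_ply_patches <- function(patches, path) {
  all_verts <- do.call(rbind, lapply(patches, `[[`, "vertices"))
  tri_list <- list()
  offset <- 0L
  for (p in patches) {
    tris <- fan_triangles(nrow(p$vertices)) + offset
    col <- GROUP_COLORS[[p$group]] %||% c(128L, 128L, 128L)
    tri_list[[length(tri_list) + 1]] <-
      cbind(tris, matrix(col, nrow(tris), 3, byrow = TRUE))
    offset <- offset + nrow(p$vertices)
  }
  tris <- do.call(rbind, tri_list)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("comment planes:",
          paste(vapply(patches, function(p) sprintf("%s(%s)", p$name, p$group), ""),
                collapse = " ")),
    sprintf("element vertex %d", nrow(all_verts)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(tris)),
    "property list uchar int vertex_indices",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header"
  ), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     all_verts[, 1], all_verts[, 2], all_verts[, 3]), con)
  writeLines(sprintf("3 %d %d %d %d %d %d",
                     tris[, 1] - 1L, tris[, 2] - 1L, tris[, 3] - 1L,
                     tris[, 4], tris[, 5], tris[, 6]), con)
  invisible(path)
}

write_stl_patches <- function(patches, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  ntri <- sum(vapply(patches, function(p) nrow(p$vertices) - 2L, 0L))
  header <- charToRaw(sprintf("%-80s", "neutraltrack plane export"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  for (p in patches) {
    tris <- fan_triangles(nrow(p$vertices))
    for (k in seq_len(nrow(tris))) {
      writeBin(as.numeric(p$normal), con, size = 4, endian = "little")
      for (vi in tris[k, ]) {
        writeBin(as.numeric(p$vertices[vi, ]), con, size = 4,
                 endian = "little")
      }
      writeBin(0L, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
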