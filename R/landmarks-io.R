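# Landmark file readers and analysis-report serialization.
#
# Three dialects are supported:
#   * CSV  — header `name,x,y,z` (2D: `name,x,y`), comma separator, dot decimal
#   * JSON — flat object name -> [x, y, z]
#   * FCSV — 3D Slicer markups fiducial v4.x ("# Markups fiducial file
#            version" header, columns id,x,y,z,...,label); coordinates are
#            taken as RAS unless the header declares LPS.

#' Read landmark files
#'
#' Parse a 3D (CSV/JSON/FCSV) or 2D (CSV/JSON) landmark file into a
#' validated landmark set in the internal frame. `frame` names the
#' convention of the file's coordinates; `"LPS"` input has its x and y
#' signs flipped on entry (the conversion is involutive). An FCSV header
#' that declares its own coordinate system overrides `frame`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"json"` or `"fcsv"`.
#' @param frame `"RAS"` (default) or `"LPS"`.
#' @return A `landmarks_3d` / `landmarks_2d` tibble.
#' @export
read_landmarks_3d <- function(path, format = c("auto", "csv", "json", "fcsv"),
                              frame = c("RAS", "LPS")) {
  format <- match.arg(format)
  frame <- match.arg(frame)
  if (!file.exists(path)) {
    abort(sprintf("Landmark file not found: %s", path), class = "trk_error_io")
  }
  if (format == "auto") format <- guess_format(path)
  df <- switch(format,
    csv = read_landmark_csv(path, ncoord = 3),
    json = read_landmark_json(path, ncoord = 3),
    fcsv = {
      res <- read_landmark_fcsv(path)
      frame <- res$frame %||% frame
      res$df
    }
  )
  df[c("x", "y")] <- convert_frame(df$x, df$y, from = frame)
  as_landmarks_3d(df)
}

#' @rdname read_landmarks_3d
#' @export
read_landmarks_2d <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Landmark file not found: %s", path), class = "trk_error_io")
  }
  if (format == "auto") format <- guess_format(path)
  df <- switch(format,
    csv = read_landmark_csv(path, ncoord = 2),
    json = read_landmark_json(path, ncoord = 2),
    abort("2D landmarks support only CSV and JSON.", class = "trk_error_io")
  )
  as_landmarks_2d(df)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", json = "json", fcsv = "fcsv",
    abort(sprintf("Cannot guess landmark format from extension '.%s'.", ext),
          class = "trk_error_io")
  )
}

convert_frame <- function(x, y, from) {
  if (from == "LPS") list(x = -x, y = -y) else list(x = x, y = y)
}

read_landmark_csv <- function(path, ncoord) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    abort(sprintf("Malformed landmark file %s: empty file.", path),
          class = "trk_error_malformed")
  }
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  want <- c("name", "x", "y", if (ncoord == 3) "z")
  if (!identical(tolower(trimws(header))[seq_along(want)], want)) {
    abort(sprintf("Malformed landmark file %s (line 1): expected header '%s'.",
                  path, paste(want, collapse = ",")),
          class = "trk_error_malformed")
  }
  rows <- lines[-1]
  rows <- rows[nzchar(trimws(rows))]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], ",")[[1]]
    if (length(fields) < ncoord + 1) {
      abort(sprintf("Malformed landmark file %s (line %d): %d field(s), expected %d.",
                    path, i + 1, length(fields), ncoord + 1),
            class = "trk_error_malformed")
    }
    coords <- suppressWarnings(as.numeric(fields[2:(ncoord + 1)]))
    if (anyNA(coords)) {
      abort(sprintf("Malformed landmark file %s (line %d): non-numeric coordinate.",
                    path, i + 1),
            class = "trk_error_malformed")
    }
    out[[i]] <- c(list(name = trimws(fields[1])),
                  stats::setNames(as.list(coords), c("x", "y", "z")[1:ncoord]))
  }
  dplyr::bind_rows(out)
}

read_landmark_json <- function(path, ncoord) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Malformed landmark file %s: %s",
                                  path, conditionMessage(e)),
                          class = "trk_error_malformed")
                  })
  if (!is.list(obj) && !is.matrix(obj)) {
    abort(sprintf("Malformed landmark file %s: expected a name -> coordinates object.", path),
          class = "trk_error_malformed")
  }
  nms <- names(obj)
  if (is.null(nms)) {
    abort(sprintf("Malformed landmark file %s: unnamed JSON entries.", path),
          class = "trk_error_malformed")
  }
  rows <- lapply(nms, function(nm) {
    v <- as.numeric(obj[[nm]])
    if (length(v) != ncoord || anyNA(v)) {
      abort(sprintf("Malformed landmark file %s: entry '%s' is not %d finite numbers.",
                    path, nm, ncoord),
            class = "trk_error_malformed")
    }
    c(list(name = nm), stats::setNames(as.list(v), c("x", "y", "z")[1:ncoord]))
  })
  dplyr::bind_rows(rows)
}

read_landmark_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  if (!any(grepl("Markups fiducial file version", header, fixed = TRUE))) {
    abort(sprintf("Malformed landmark file %s (line 1): missing Slicer markups header.",
                  path),
          class = "trk_error_malformed")
  }
  frame <- NULL
  cs <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs)) {
    val <- trimws(sub(".*=", "", cs[1]))
    frame <- if (val %in% c("LPS", "1")) "LPS" else "RAS"
  }
  rows <- lines[!startsWith(lines, "#")]
  rows <- rows[nzchar(trimws(rows))]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], ",")[[1]]
    if (length(fields) < 12) {
      abort(sprintf("Malformed landmark file %s (line %d): FCSV row has %d fields, expected >= 12.",
                    path, which(lines == rows[i])[1], length(fields)),
            class = "trk_error_malformed")
    }
    coords <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(coords)) {
      abort(sprintf("Malformed landmark file %s (line %d): non-numeric coordinate.",
                    path, which(lines == rows[i])[1]),
            class = "trk_error_malformed")
    }
    out[[i]] <- list(name = trimws(fields[12]),
                     x = coords[1], y = coords[2], z = coords[3])
  }
  list(df = dplyr::bind_rows(out), frame = frame)
}

#' Write landmark files
#'
#' Serialize a landmark set back to CSV or JSON (primary landmarks only;
#' derived midpoints are recomputed on read). The round trip is lossless
#' to full double precision.
#'
#' @param lm A `landmarks_3d` or `landmarks_2d` tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, format = c("csv", "json")) {
  format <- match.arg(format)
  is3d <- inherits(lm, "landmarks_3d")
  df <- if (is3d) lm[!lm$derived, , drop = FALSE] else lm
  if (format == "csv") {
    cols <- if (is3d) c("x", "y", "z") else c("x", "y")
    lines <- c(paste(c("name", cols), collapse = ","),
               vapply(seq_len(nrow(df)), function(i) {
                 paste(c(df$name[i],
                         format(unlist(df[i, cols]), digits = 17)),
                       collapse = ",")
               }, ""))
    writeLines(lines, path)
  } else {
    obj <- lapply(seq_len(nrow(df)), function(i) {
      if (is3d) c(df$x[i], df$y[i], df$z[i]) else c(df$x[i], df$y[i])
    })
    names(obj) <- df$name
    jsonlite::write_json(obj, path, digits = NA)
  }
  invisible(path)
}

#' Serialize an analysis report
#'
#' Reports round-trip losslessly through JSON; a report containing
#' non-finite angles is refused.
#'
#' @param report A `track_report` object from [analyze_subject()].
#' @param path Output path.
#' @return `path`, invisibly (for `write_report`); the reconstructed
#'   `track_report` (for `read_report`).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "track_report"))
  nums <- unlist(report$angles[sapply(report$angles, is.numeric)])
  nums <- c(nums, unlist(report$self_check), unlist(report$deltas))
  if (any(!is.finite(nums))) {
    abort("Refusing to serialize a report with non-finite angles.",
          class = "trk_error_validation")
  }
  payload <- unclass(report)
  payload$config <- unclass(payload$config)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    TRUE
  }, error = function(e) {
    abort(sprintf("Failed to write report: %s", conditionMessage(e)),
          class = "trk_error_io")
  })
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Report file not found: %s", path), class = "trk_error_io")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$angles <- as_tibble(obj$angles)
  obj$points <- lapply(obj$points, as.numeric)
  obj$self_check <- lapply(obj$self_check, as.numeric)
  if (!is.null(obj$deltas)) obj$deltas <- lapply(obj$deltas, as.numeric)
  obj$config <- structure(obj$config, class = "track_config")
  structure(obj, class = "track_report")
}
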