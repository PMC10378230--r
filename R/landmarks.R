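# Landmark set containers. Landmark sets are tibbles (name, x, y, z[, derived])
# carrying a class tag, so they pipe through dplyr naturally while the
# constructors enforce completeness and compute the derived midpoints.

LMK3D_REQUIRED <- c("rMCF", "lMCF", "Ba", "rCo", "lCo", "rGo", "lGo",
                    "PNS", "rPoc", "lPoc", "rAoc", "lAoc")
LMK3D_DERIVED <- c("mCo", "mAoc")
LMK2D_REQUIRED <- c("SE", "Ar", "Ptm", "Go", "Poc", "Aoc")

# Versioned synonym table: lower-cased alias -> canonical short name.
LMK_SYNONYMS <- c(
  "basion" = "Ba",
  "posterior nasal spine" = "PNS",
  "middle cranial floor right side" = "rMCF",
  "middle cranial floor left side" = "lMCF",
  "right condylion" = "rCo",
  "left condylion" = "lCo",
  "right gonion" = "rGo",
  "left gonion" = "lGo",
  "posterior occlusal contact right side" = "rPoc",
  "posterior occlusal contact left side" = "lPoc",
  "anterior occlusal contact right side" = "rAoc",
  "anterior occlusal contact left side" = "lAoc",
  "sphenoethmoidal junction" = "SE",
  "articulare" = "Ar",
  "pterygomaxillary fissure" = "Ptm",
  "gonion" = "Go",
  "posterior occlusal contact" = "Poc",
  "anterior occlusal contact" = "Aoc"
)

canonical_names <- function(names, required) {
  lower_req <- tolower(required)
  out <- character(length(names))
  for (i in seq_along(names)) {
    key <- tolower(trimws(names[i]))
    if (key %in% lower_req) {
      out[i] <- required[match(key, lower_req)]
    } else if (key %in% names(LMK_SYNONYMS)) {
      out[i] <- unname(LMK_SYNONYMS[key])
    } else {
      out[i] <- trimws(names[i])
    }
  }
  out
}

#' Landmark set constructors
#'
#' Coerce a data frame of named coordinates into a validated landmark set.
#' 3D sets require the twelve primary landmarks rMCF, lMCF, Ba, rCo, lCo,
#' rGo, lGo, PNS, rPoc, lPoc, rAoc and lAoc (mm, internal frame: x = right,
#' y = anterior, z = superior); the condylar and anterior-occlusal midpoints
#' mCo and mAoc are (re)computed and appended as derived rows. 2D sets
#' require SE, Ar, Ptm, Go, Poc and Aoc (x = anterior, y = superior).
#' Names are matched case-insensitively through a synonym table
#' ("Basion" resolves to Ba); unknown names are kept with a warning,
#' duplicates are an error.
#'
#' @param x A data frame with columns `name`, `x`, `y` and (3D) `z`.
#' @return A tibble of class `landmarks_3d` or `landmarks_2d` with a
#'   logical `derived` column.
#' @examples
#' as_landmarks_3d(template_landmarks())
#' @export
as_landmarks_3d <- function(x) {
  df <- coerce_landmark_df(x, c("name", "x", "y", "z"))
  df$name <- canonical_names(df$name, LMK3D_REQUIRED)
  df <- df[!df$name %in% LMK3D_DERIVED, , drop = FALSE]
  check_landmark_names(df$name, LMK3D_REQUIRED)
  df$derived <- FALSE
  mids <- tibble(
    name = LMK3D_DERIVED,
    x = c(mean(df$x[df$name %in% c("rCo", "lCo")]),
          mean(df$x[df$name %in% c("rAoc", "lAoc")])),
    y = c(mean(df$y[df$name %in% c("rCo", "lCo")]),
          mean(df$y[df$name %in% c("rAoc", "lAoc")])),
    z = c(mean(df$z[df$name %in% c("rCo", "lCo")]),
          mean(df$z[df$name %in% c("rAoc", "lAoc")])),
    derived = TRUE
  )
  out <- dplyr::bind_rows(as_tibble(df), mids)
  class(out) <- c("landmarks_3d", class(tibble()))
  out
}

#' @rdname as_landmarks_3d
#' @export
as_landmarks_2d <- function(x) {
  df <- coerce_landmark_df(x, c("name", "x", "y"))
  df$name <- canonical_names(df$name, LMK2D_REQUIRED)
  check_landmark_names(df$name, LMK2D_REQUIRED)
  out <- as_tibble(df)
  class(out) <- c("landmarks_2d", class(tibble()))
  out
}

coerce_landmark_df <- function(x, cols) {
  if (!is.data.frame(x)) {
    abort("Landmarks must be supplied as a data frame.",
          class = "trk_error_malformed")
  }
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(sprintf("Landmark table lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "trk_error_malformed")
  }
  df <- as.data.frame(x)[cols]
  df$name <- as.character(df$name)
  for (cc in setdiff(cols, "name")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (anyNA(df[[cc]]) || any(!is.finite(df[[cc]]))) {
      abort(sprintf("Non-finite coordinate in column '%s'.", cc),
            class = "trk_error_malformed")
    }
  }
  df
}

check_landmark_names <- function(names, required) {
  dup <- names[duplicated(names) & names %in% required]
  if (length(dup)) {
    abort(sprintf("Duplicate landmark(s): %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "trk_error_duplicate_landmark")
  }
  absent <- setdiff(required, names)
  if (length(absent)) {
    abort(sprintf("Missing landmark(s): %s.", paste(absent, collapse = ", ")),
          class = "trk_error_missing_landmark")
  }
  unknown <- setdiff(names, required)
  if (length(unknown)) {
    warn(sprintf("Unknown landmark name(s) kept but unused: %s.",
                 paste(unknown, collapse = ", ")),
         class = "trk_warning_unknown_landmark")
  }
  invisible(names)
}

#' Extract one landmark's coordinates
#'
#' @param lm A `landmarks_3d` or `landmarks_2d` tibble.
#' @param name Canonical landmark name (e.g. `"Ba"`, `"mCo"`, `"SE"`).
#' @return A numeric vector of length 3 (or 2).
#' @export
lmk <- function(lm, name) {
  i <- match(name, lm$name)
  if (is.na(i)) {
    abort(sprintf("Missing landmark(s): %s.", name),
          class = "trk_error_missing_landmark")
  }
  if (inherits(lm, "landmarks_2d")) {
    c(lm$x[i], lm$y[i])
  } else {
    c(lm$x[i], lm$y[i], lm$z[i])
  }
}

#' Validate a 3D landmark set
#'
#' Screens a parsed landmark set for conditions that would break or bias
#' the track constructions. Errors: non-finite coordinates; coincident or
#' collinear points that make a required plane degenerate. Warnings:
#' inverted left/right laterality; inter-landmark distances outside a
#' plausible 5--200 mm band. Findings are returned, never thrown.
#'
#' @param lm A `landmarks_3d` tibble.
#' @return A tibble with columns `severity`, `code`, `message`; zero rows
#'   when the set is clean.
#' @export
validate_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmarks_3d"))
  findings <- list()
  add <- function(severity, code, message) {
    findings[[length(findings) + 1]] <<- tibble(
      severity = severity, code = code, message = message)
  }
  planes <- list(
    MCF = c("rMCF", "lMCF", "Ba"),
    PM  = c("lMCF", "rMCF", "PNS"),
    MR  = c("mCo", "rGo", "lGo"),
    FOP = c("rPoc", "lPoc", "mAoc")
  )
  for (nm in names(planes)) {
    pts <- lapply(planes[[nm]], function(n) lmk(lm, n))
    ok <- tryCatch({
      plane_from_points(pts[[1]], pts[[2]], pts[[3]])
      TRUE
    }, trk_error_degenerate = function(e) FALSE)
    if (!ok) add("error", "degenerate_plane",
                 sprintf("%s plane degenerate: %s are collinear or coincident.",
                         nm, paste(planes[[nm]], collapse = ", ")))
  }
  pairs <- list(c("rMCF", "lMCF"), c("rCo", "lCo"), c("rGo", "lGo"),
                c("rPoc", "lPoc"), c("rAoc", "lAoc"))
  for (pr in pairs) {
    if (lmk(lm, pr[1])[1] < lmk(lm, pr[2])[1]) {
      add("warning", "laterality",
          sprintf("Laterality looks inverted: %s has smaller x than %s.",
                  pr[1], pr[2]))
    }
  }
  prim <- lm[!lm$derived, , drop = FALSE]
  xyz <- as.matrix(prim[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  bad <- which(upper.tri(d) & (d < 5 | d > 200), arr.ind = TRUE)
  if (nrow(bad)) {
    for (k in seq_len(nrow(bad))) {
      add("warning", "implausible_distance",
          sprintf("Distance %s-%s = %.1f mm outside the plausible 5-200 mm band.",
                  prim$name[bad[k, 1]], prim$name[bad[k, 2]],
                  d[bad[k, 1], bad[k, 2]]))
    }
  }
  if (length(findings)) dplyr::bind_rows(findings) else
    tibble(severity = character(), code = character(), message = character())
}

# Project a 3D landmark (internal frame) onto the 2D sagittal frame:
# 2D x = anterior (3D y), 2D y = superior (3D z).
project_sagittal <- function(p) c(p[2], p[3])
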