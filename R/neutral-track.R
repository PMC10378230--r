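# The neutral-track construction. The neutral track is the idealized
# configuration of the four structural planes, rebuilt from the subject's
# own dimensions with the cranial-base angle fixed at its neutral value
# (40.3 degrees): a sphere centred in Ba with radius Ba--MCFx fixes the
# scale, the neutral SE point is placed on its sagittal circumference at
# the neutral angle from the construction plane through Ba, and the
# remaining planes follow by parallel/perpendicular rules.

#' Estimated mid-sagittal plane
#'
#' The plane through Ba whose normal is the normalized sum of the unit
#' left-to-right vectors of the three bilateral pairs lMCF-rMCF, lCo-rCo
#' and lGo-rGo. For a perfectly mirror-symmetric set this is the exact
#' symmetry plane; the estimator replaces any assumption of scanner
#' alignment. Swapping a left/right pair can flip the normal's sign, which
#' no downstream result depends on.
#'
#' @param lm A `landmarks_3d` tibble.
#' @return A `track_plane` through Ba.
#' @export
midsagittal_plane <- function(lm) {
  stopifnot(inherits(lm, "landmarks_3d"))
  v <- unit(lmk(lm, "rMCF") - lmk(lm, "lMCF")) +
       unit(lmk(lm, "rCo") - lmk(lm, "lCo")) +
       unit(lmk(lm, "rGo") - lmk(lm, "lGo"))
  if (vnorm(v) < 1e-9) {
    abort("Degenerate geometry: bilateral direction vectors cancel; cannot estimate the mid-sagittal plane.",
          class = "trk_error_degenerate")
  }
  new_plane(lmk(lm, "Ba"), v)
}

#' Locate MCFx, the sagittal crossing of the cranial-floor chord
#'
#' The intersection of the rMCF--lMCF segment with the mid-sagittal plane;
#' the segment Ba--MCFx sets the radius of the construction sphere.
#'
#' @param lm A `landmarks_3d` tibble.
#' @param sagittal The mid-sagittal `track_plane`.
#' @return The crossing point (numeric length 3).
#' @export
locate_mcfx <- function(lm, sagittal) {
  segment_plane_intersection(lmk(lm, "rMCF"), lmk(lm, "lMCF"), sagittal)
}

#' Locate the neutral sphenoethmoidal point SEn
#'
#' Executes the first half of the neutral construction: the sphere centred
#' in Ba with radius |Ba - MCFx|; its circumference on the sagittal
#' section; the construction plane CPBa through Ba parallel to PM; and SEn,
#' the circle point whose ray from Ba makes the neutral angle with CPBa,
#' on the anterior-superior branch (the candidate maximizing the dot
#' product of Ba-to-candidate with Ba-to-MCFx).
#'
#' @param lm A `landmarks_3d` tibble.
#' @param sagittal Mid-sagittal `track_plane`.
#' @param pm The individual PM `track_plane`.
#' @param neutral_angle Neutral cranial-base angle in degrees.
#' @return A list with elements `sphere`, `circle`, `cpba` and `sen`.
#' @export
locate_sen <- function(lm, sagittal, pm, neutral_angle = 40.3) {
  ba <- lmk(lm, "Ba")
  mcfx <- locate_mcfx(lm, sagittal)
  radius <- vnorm(mcfx - ba)
  if (radius < 1e-9) {
    abort("Degenerate geometry: MCFx coincides with Ba (zero sphere radius).",
          class = "trk_error_degenerate")
  }
  sph <- new_sphere(ba, radius)
  circ <- sphere_plane_intersection(sph, sagittal)
  cpba <- plane_parallel_through(pm, ba)
  sen <- point_on_circle_at_angle(circ, cpba, neutral_angle,
                                  branch = mcfx - ba)
  list(sphere = sph, circle = circ, cpba = cpba, sen = sen)
}

#' Neutral pterygo-mandibular plane
#'
#' The plane through SEn parallel to the individual PM.
#'
#' @param pm The individual PM `track_plane`.
#' @param sen The SEn point.
#' @return A `track_plane`.
#' @export
build_pmn <- function(pm, sen) {
  plane_parallel_through(pm, sen)
}

#' Neutral middle-cranial-floor plane
#'
#' MCFn passes through Ba and the two lateral helper points rSEn/lSEn
#' flanking SEn. In `"tangent"` mode (default) the helpers sit at
#' `SEn +/- delta` along the sagittal normal, so the plane contains the
#' Ba--SEn ray exactly and its sagittal-trace angle with PMn equals the
#' neutral angle to machine precision, independent of `delta`. In
#' `"on_sphere"` mode the helpers stay on the construction sphere, on the
#' axial circle through SEn (axial direction taken from the functional
#' occlusal plane normal, oriented superiorly), reproducing the literal
#' axial-view reading with a small, delta-dependent trace-angle deviation
#' that vanishes as `delta` goes to 0.
#'
#' @param ba Ba point.
#' @param sen SEn point.
#' @param sagittal Mid-sagittal `track_plane`.
#' @param delta Lateral half-offset in mm (>= 0.1).
#' @param mode `"tangent"` or `"on_sphere"`.
#' @param axial_up Unit superior direction (required for `"on_sphere"`).
#' @return A list with `rsen`, `lsen` and `mcfn` (a `track_plane`).
#' @export
build_mcfn <- function(ba, sen, sagittal, delta = 5,
                       mode = c("tangent", "on_sphere"), axial_up = NULL) {
  mode <- match.arg(mode)
  ba <- check_point3(ba); sen <- check_point3(sen)
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0.1) {
    abort("`delta` must be a single number >= 0.1 mm.",
          class = "trk_error_degenerate")
  }
  if (vnorm(sen - ba) < 1e-9) {
    abort("Degenerate geometry: SEn coincides with Ba.",
          class = "trk_error_degenerate")
  }
  lat <- sagittal$normal
  if (mode == "tangent") {
    p_plus <- sen + delta * lat
    p_minus <- sen - delta * lat
  } else {
    if (is.null(axial_up)) {
      abort("`on_sphere` mode needs an `axial_up` direction.",
            class = "trk_error_degenerate")
    }
    s <- unit(check_point3(axial_up))
    radius <- vnorm(sen - ba)
    axial <- new_plane(sen, s)
    circ <- sphere_plane_intersection(new_sphere(ba, radius), axial)
    u0 <- unit(sen - circ$center)
    v0 <- cross3(circ$plane_normal, u0)
    if (delta / (2 * circ$radius) > 1) {
      abort("Degenerate geometry: `delta` exceeds the axial circle diameter.",
            class = "trk_error_degenerate")
    }
    beta <- 2 * asin(delta / (2 * circ$radius))
    p_plus <- circ$center + circ$radius * (cos(beta) * u0 + sin(beta) * v0)
    p_minus <- circ$center + circ$radius * (cos(beta) * u0 - sin(beta) * v0)
  }
  # Label the subject's right-side helper rSEn.
  if (sum((p_plus - sen) * lat) < 0) {
    tmp <- p_plus; p_plus <- p_minus; p_minus <- tmp
  }
  mcfn <- plane_from_points(ba, p_plus, p_minus)
  list(rsen = p_plus, lsen = p_minus, mcfn = mcfn)
}

#' Locate the neutral gonions
#'
#' Builds the two helper planes -- CPCo through mCo parallel to PMn, and
#' the gonion plane GoP through rGo and lGo perpendicular to PMn -- then
#' slides each gonion purely along the PMn normal to the mid-parallel
#' plane: each neutral gonion keeps its gonion's position within GoP
#' ("the same level as Go") and ends up halfway between PMn and CPCo.
#'
#' @param lm A `landmarks_3d` tibble.
#' @param pmn The neutral PM `track_plane`.
#' @return A list with `cpco`, `gop` (planes) and `rgon`, `lgon` (points).
#' @export
locate_gon <- function(lm, pmn) {
  mco <- lmk(lm, "mCo")
  if (abs(signed_distance(mco, pmn)) < 1e-9) {
    abort("Degenerate geometry: mCo lies on PMn; CPCo coincides with PMn.",
          class = "trk_error_degenerate")
  }
  cpco <- plane_parallel_through(pmn, mco)
  gop <- plane_perpendicular_through_chord(pmn, lmk(lm, "rGo"), lmk(lm, "lGo"))
  target <- signed_distance(mco, pmn) / 2
  n <- pmn$normal
  rgo <- lmk(lm, "rGo"); lgo <- lmk(lm, "lGo")
  list(
    cpco = cpco,
    gop = gop,
    rgon = rgo + (target - signed_distance(rgo, pmn)) * n,
    lgon = lgo + (target - signed_distance(lgo, pmn)) * n
  )
}

#' Build the full 3D neutral track
#'
#' Orchestrates the construction: mid-sagittal estimation, MCFx, the
#' Ba-centred sphere and its sagittal circumference, CPBa, SEn, PMn, MCFn
#' (with its rSEn/lSEn helpers), the CPCo/GoP helper planes, the neutral
#' gonions, MRn through mCo and the gonions, and FOPn through rPoc/lPoc
#' perpendicular to PMn. Errors are annotated with the failing stage.
#'
#' @param lm A `landmarks_3d` tibble.
#' @param config A [track_config()].
#' @return An object of class `neutral_track_3d` holding every
#'   construction object, the four neutral planes, the individual PM and
#'   the mid-sagittal section.
#' @examples
#' nt <- build_neutral_track_3d(as_landmarks_3d(template_landmarks()))
#' neutral_self_check(nt)
#' @export
build_neutral_track_3d <- function(lm, config = track_config()) {
  stopifnot(inherits(lm, "landmarks_3d"), inherits(config, "track_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Neutral-track stage '%s' failed: %s",
                    name, conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
  }
  sag <- stage("midsagittal_plane", midsagittal_plane(lm))
  pm <- stage("individual_pm",
              plane_from_points(lmk(lm, "lMCF"), lmk(lm, "rMCF"),
                                lmk(lm, "PNS")))
  mcfx <- stage("locate_mcfx", locate_mcfx(lm, sag))
  sen_parts <- stage("locate_sen",
                     locate_sen(lm, sag, pm, config$neutral_angle))
  pmn <- stage("build_pmn", build_pmn(pm, sen_parts$sen))
  fop <- stage("individual_fop",
               plane_from_points(lmk(lm, "rPoc"), lmk(lm, "lPoc"),
                                 lmk(lm, "mAoc")))
  up <- fop$normal
  if (sum(up * (mcfx - lmk(lm, "Ba"))) < 0) up <- -up
  mcfn_parts <- stage("build_mcfn",
                      build_mcfn(lmk(lm, "Ba"), sen_parts$sen, sag,
                                 delta = config$delta,
                                 mode = config$mcfn_mode, axial_up = up))
  gon_parts <- stage("locate_gon", locate_gon(lm, pmn))
  mrn <- stage("build_mrn",
               plane_from_points(lmk(lm, "mCo"), gon_parts$rgon,
                                 gon_parts$lgon))
  fopn <- stage("build_fopn",
                plane_perpendicular_through_chord(pmn, lmk(lm, "rPoc"),
                                                  lmk(lm, "lPoc")))
  structure(
    list(
      sphere = sen_parts$sphere,
      sagittal_circle = sen_parts$circle,
      CPBa = sen_parts$cpba,
      CPCo = gon_parts$cpco,
      GoP = gon_parts$gop,
      MCFx = mcfx,
      SEn = sen_parts$sen,
      rSEn = mcfn_parts$rsen,
      lSEn = mcfn_parts$lsen,
      rGon = gon_parts$rgon,
      lGon = gon_parts$lgon,
      MCFn = mcfn_parts$mcfn,
      PMn = pmn,
      MRn = mrn,
      FOPn = fopn,
      PM = pm,
      section = sag,
      neutral_angle = config$neutral_angle,
      landmarks = lm,
      config = config
    ),
    class = "neutral_track_3d"
  )
}

#' Build the 2D neutral track
#'
#' The lateral-cephalogram construction: a circle centred in Ar with
#' radius |Ar - SE|; SEn on that circle so that the angle at SEn between
#' the MCFn line (Ar--SEn) and the PMn line (parallel to PM through SEn)
#' equals the neutral angle, anterior-superior branch; Gon at Go's level,
#' equidistant from PMn and its parallel through Ar; MRn = Ar--Gon; FOPn
#' perpendicular to PMn through Poc.
#'
#' @param lm A `landmarks_2d` tibble.
#' @param config A [track_config()].
#' @return An object of class `neutral_track_2d`.
#' @export
build_neutral_track_2d <- function(lm, config = track_config()) {
  stopifnot(inherits(lm, "landmarks_2d"), inherits(config, "track_config"))
  se <- lmk(lm, "SE"); ar <- lmk(lm, "Ar"); ptm <- lmk(lm, "Ptm")
  go <- lmk(lm, "Go"); poc <- lmk(lm, "Poc")
  radius <- sqrt(sum((se - ar)^2))
  if (radius < 1e-9) {
    abort("Degenerate geometry: SE coincides with Ar (zero circle radius).",
          class = "trk_error_degenerate")
  }
  d_pm <- unit2(ptm - se)
  # Four candidate directions at the neutral angle from the PM *line*
  # (either orientation); the anterior-superior branch is the candidate
  # maximizing the dot product with Ar -> SE, mirroring the 3D rule.
  cand <- dedupe_points(list(rot2(d_pm, config$neutral_angle),
                             rot2(d_pm, -config$neutral_angle),
                             rot2(-d_pm, config$neutral_angle),
                             rot2(-d_pm, -config$neutral_angle)), tol = 1e-9)
  hint <- unit2(se - ar)
  scores <- vapply(cand, function(d) sum(d * hint), 0)
  ord <- order(scores, decreasing = TRUE)
  if (length(ord) > 1 && scores[ord[1]] - scores[ord[2]] < 1e-9) {
    abort("Branch selector does not isolate a single SEn candidate.",
          class = "trk_error_branch_ambiguity")
  }
  sen <- ar + radius * cand[[ord[1]]]
  pmn <- new_line2(sen, d_pm)
  mcfn <- line2_through(ar, sen)
  cp_ar <- new_line2(ar, d_pm)
  gon <- go + (signed_distance_line2(ar, pmn) / 2 -
                 signed_distance_line2(go, pmn)) *
    c(-d_pm[2], d_pm[1])
  mrn <- line2_through(ar, gon)
  fopn <- new_line2(poc, c(-d_pm[2], d_pm[1]))
  structure(
    list(circle = list(center = ar, radius = radius),
         SEn = sen, Gon = gon,
         MCFn = mcfn, PMn = pmn, MRn = mrn, FOPn = fopn,
         CPAr = cp_ar,
         PM = line2_through(se, ptm),
         neutral_angle = config$neutral_angle,
         landmarks = lm, config = config),
    class = "neutral_track_2d"
  )
}

#' Self-check angles of a neutral track
#'
#' Recomputes the three identities the construction must satisfy: the
#' cranial-base angle MCFn^PMn at SEn (the neutral constant), the
#' perpendicularity FOPn^PMn = 90 and the parallelism PMn^PM = 0.
#'
#' @param nt A `neutral_track_3d` or `neutral_track_2d`.
#' @return A tibble with columns `check` and `value` (degrees).
#' @export
neutral_self_check <- function(nt) {
  UseMethod("neutral_self_check")
}

#' @export
neutral_self_check.neutral_track_3d <- function(nt) {
  lm <- nt$landmarks
  mcfn_pmn <- oriented_trace_angle(
    nt$MCFn, nt$PMn, nt$section,
    orient_a = lmk(lm, "Ba") - nt$SEn,
    orient_b = lmk(lm, "PNS") - nt$MCFx
  )
  tibble(
    check = c("MCFn^PMn", "FOPn^PMn", "PMn^PM"),
    value = c(mcfn_pmn,
              dihedral_angle(nt$FOPn, nt$PMn),
              dihedral_angle(nt$PMn, nt$PM))
  )
}

#' @export
neutral_self_check.neutral_track_2d <- function(nt) {
  lm <- nt$landmarks
  ar <- lmk(lm, "Ar")
  mcfn_pmn <- angle_at_vertex(ar, nt$SEn, nt$SEn + nt$PMn$direction)
  line_angle <- function(a, b) {
    da <- a$direction; db <- b$direction
    atan2(abs(da[1] * db[2] - da[2] * db[1]), abs(sum(da * db))) * DEG
  }
  tibble(
    check = c("MCFn^PMn", "FOPn^PMn", "PMn^PM"),
    value = c(mcfn_pmn,
              line_angle(nt$FOPn, nt$PMn),
              line_angle(nt$PMn, nt$PM))
  )
}

#' Individual-versus-neutral plane deltas
#'
#' Quantifies the rotational factor: the oriented sagittal-trace angle
#' between each individual plane and its neutral counterpart. PM versus
#' PMn is 0 by construction and reported as such.
#'
#' @param individual An `individual_track_3d`.
#' @param neutral A `neutral_track_3d` built from the same landmark set.
#' @param sagittal Mid-sagittal `track_plane` (defaults to the track's).
#' @return A tibble with columns `plane` and `delta` (degrees).
#' @export
track_delta <- function(individual, neutral, sagittal = neutral$section) {
  stopifnot(inherits(individual, "individual_track_3d"),
            inherits(neutral, "neutral_track_3d"))
  lm <- neutral$landmarks
  ba <- lmk(lm, "Ba")
  mco <- lmk(lm, "mCo")
  mgo <- (lmk(lm, "rGo") + lmk(lm, "lGo")) / 2
  mgon <- (neutral$rGon + neutral$lGon) / 2
  mpoc <- (lmk(lm, "rPoc") + lmk(lm, "lPoc")) / 2
  ant <- lmk(lm, "mAoc") - mpoc
  tibble(
    plane = c("MCF", "PM", "MR", "FOP"),
    delta = c(
      oriented_trace_angle(individual$MCF, neutral$MCFn, sagittal,
                           orient_a = neutral$MCFx - ba,
                           orient_b = neutral$SEn - ba),
      0,
      oriented_trace_angle(individual$MR, neutral$MRn, sagittal,
                           orient_a = mgo - mco, orient_b = mgon - mco),
      oriented_trace_angle(individual$FOP, neutral$FOPn, sagittal,
                           orient_a = ant, orient_b = ant)
    )
  )
}

#' @export
print.neutral_track_3d <- function(x, ...) {
  cat(sprintf("<neutral_track_3d> neutral angle %.1f deg, sphere radius %.3f mm\n",
              x$neutral_angle, x$sphere$radius))
  print(neutral_self_check(x))
  invisible(x)
}

#' @export
print.neutral_track_2d <- function(x, ...) {
  cat(sprintf("<neutral_track_2d> neutral angle %.1f deg, circle radius %.3f mm\n",
              x$neutral_angle, x$circle$radius))
  print(neutral_self_check(x))
  invisible(x)
}
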