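# Deterministic generator of synthetic craniofacial landmark sets: a fixed
# bilaterally symmetric 3D template, per-subject deformations (size, two
# rotational-factor knobs, lateral asymmetry, isotropic noise) and the
# matching projected lateral-cephalogram (2D) set.

#' The fixed 3D landmark template
#'
#' A bilaterally mirror-symmetric landmark configuration with plausible
#' craniofacial magnitudes (mm), used as the seed of every synthetic
#' subject. Ba sits at the origin; the condylar midpoint is placed on the
#' Ba--MCFx line so that the 2D articulare emulation (Ar = projected mCo)
#' is exactly consistent with the 3D cranial-floor trace, making 2D and 3D
#' angle measurements agree exactly on noise-free subjects.
#'
#' @return A tibble with columns `name`, `x`, `y`, `z` (12 primary
#'   landmarks; pass through [as_landmarks_3d()] to add midpoints).
#' @examples
#' template_landmarks()
#' @export
template_landmarks <- function() {
  tibble(
    name = c("Ba", "rMCF", "lMCF", "PNS", "rCo", "lCo",
             "rGo", "lGo", "rPoc", "lPoc", "rAoc", "lAoc"),
    x = c(0, 25, -25, 0, 50, -50, 45, -45, 25, -25, 20, -20),
    y = c(0, 45, 45, 48, 8, 8, 25, 25, 45, 45, 70, 70),
    z = c(0, 18, 18, -18, 3.2, 3.2, -55, -55, -48, -48, -47, -47)
  )
}

#' Subject deformation parameters
#'
#' @param scale Global size factor (> 0).
#' @param ramus_angle_offset Degrees; rotates the gonions about the lateral
#'   axis through mCo. Positive values open the posterior angle: MCF^MR
#'   (trace convention) grows by exactly this amount on a noise-free
#'   subject.
#' @param cranial_base_offset Degrees; rotates Ba and the condyles about
#'   the lateral axis through the MCF mid-chord. Positive values grow
#'   MCF^PM by exactly this amount on a noise-free subject.
#' @param asymmetry Amplitude (mm) of seeded lateral (x-only) perturbations
#'   breaking mirror symmetry; they leave all sagittal projections and
#'   trace angles unchanged.
#' @param noise_sd SD (mm) of isotropic Gaussian landmark noise.
#' @param seed Integer RNG seed.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(scale = 1, ramus_angle_offset = 0,
                           cranial_base_offset = 0, asymmetry = 0,
                           noise_sd = 0, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("`scale` must be a single positive number.",
          class = "trk_error_degenerate")
  }
  if (noise_sd < 0 || asymmetry < 0) {
    abort("`noise_sd` and `asymmetry` must be non-negative.",
          class = "trk_error_degenerate")
  }
  structure(list(scale = scale,
                 ramus_angle_offset = ramus_angle_offset,
                 cranial_base_offset = cranial_base_offset,
                 asymmetry = asymmetry,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "subject_params")
}

# Rotate points (rows of m) about the x-parallel axis through `hinge` by
# `deg` degrees (counter-clockwise in the y-z plane seen from +x).
rotate_about_lateral_axis <- function(m, hinge, deg) {
  a <- deg / DEG
  yz <- sweep(m[, 2:3, drop = FALSE], 2, hinge[2:3])
  m[, 2] <- hinge[2] + cos(a) * yz[, 1] - sin(a) * yz[, 2]
  m[, 3] <- hinge[3] + sin(a) * yz[, 1] + cos(a) * yz[, 2]
  m
}

#' Generate one synthetic subject
#'
#' Applies, in order: the two rotational-factor rotations (cranial base:
#' Ba, rCo, lCo about the MCF mid-chord; ramus: rGo, lGo about mCo), the
#' global scale factor (about Ba), seeded lateral asymmetry, and seeded
#' isotropic noise. The paired 2D set is the exact mid-sagittal projection
#' of the (noisy) 3D set under the fixed rules SE = proj(MCF mid-chord),
#' Ar = proj(mCo), Ptm = proj(PNS), Go = proj(gonion mid-chord),
#' Poc/Aoc = proj(occlusal mid-chords). Output is deterministic given the
#' seed.
#'
#' @param params A [subject_params()].
#' @return A list with elements `lm3d` (`landmarks_3d`), `lm2d`
#'   (`landmarks_2d`) and `params`.
#' @examples
#' s <- generate_subject(subject_params(noise_sd = 0.5, seed = 7))
#' measure_angles_3d(build_individual_track_3d(s$lm3d))
#' @export
generate_subject <- function(params = subject_params()) {
  stopifnot(inherits(params, "subject_params"))
  tpl <- template_landmarks()
  m <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(m) <- tpl$name
  mcf_mid <- (m["rMCF", ] + m["lMCF", ]) / 2
  cranial <- c("Ba", "rCo", "lCo")
  m[cranial, ] <- rotate_about_lateral_axis(m[cranial, , drop = FALSE],
                                            mcf_mid,
                                            -params$cranial_base_offset)
  mco <- (m["rCo", ] + m["lCo", ]) / 2
  ramus <- c("rGo", "lGo")
  m[ramus, ] <- rotate_about_lateral_axis(m[ramus, , drop = FALSE],
                                          mco,
                                          -params$ramus_angle_offset)
  ba <- m["Ba", ]
  m <- sweep(sweep(m, 2, ba) * params$scale, 2, ba, FUN = "+")
  withr::with_seed(params$seed, {
    if (params$asymmetry > 0) {
      m[, 1] <- m[, 1] + runif(nrow(m), -params$asymmetry, params$asymmetry)
    }
    if (params$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = params$noise_sd),
                      nrow = nrow(m))
    }
  })
  lm3d <- as_landmarks_3d(tibble(name = rownames(m),
                                 x = m[, 1], y = m[, 2], z = m[, 3]))
  mid <- function(a, b) (lmk(lm3d, a) + lmk(lm3d, b)) / 2
  p <- function(v) project_sagittal(v)
  lm2d <- as_landmarks_2d(tibble(
    name = c("SE", "Ar", "Ptm", "Go", "Poc", "Aoc"),
    x = c(p(mid("rMCF", "lMCF"))[1], p(lmk(lm3d, "mCo"))[1],
          p(lmk(lm3d, "PNS"))[1], p(mid("rGo", "lGo"))[1],
          p(mid("rPoc", "lPoc"))[1], p(lmk(lm3d, "mAoc"))[1]),
    y = c(p(mid("rMCF", "lMCF"))[2], p(lmk(lm3d, "mCo"))[2],
          p(lmk(lm3d, "PNS"))[2], p(mid("rGo", "lGo"))[2],
          p(mid("rPoc", "lPoc"))[2], p(lmk(lm3d, "mAoc"))[2])
  ))
  list(lm3d = lm3d, lm2d = lm2d, params = params)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject deformation parameters from the cohort distribution
#' (defaults: noise_sd 0.5 mm; asymmetry amplitude uniform on 0 to 2 mm;
#' both rotational offsets normal with SD 3 degrees; scale log-normal with
#' 5 percent SD) and generates each subject with a seed derived
#' deterministically from the master seed and the subject index, so
#' cohorts are stable under reordering.
#'
#' @param n Number of subjects (>= 1); the validation cohort size is 18.
#' @param seed Master RNG seed.
#' @param noise_sd Landmark noise SD (mm) shared by all subjects.
#' @param asymmetry_max Upper bound of the uniform asymmetry amplitude (mm).
#' @param offset_sd SD (degrees) of the two rotational offsets.
#' @param scale_sd SD of `log(scale)`.
#' @return A tibble with one row per subject: `subject`, list-columns
#'   `lm3d`, `lm2d` and `params`.
#' @examples
#' cohort <- generate_cohort(n = 5, seed = 11)
#' @export
generate_cohort <- function(n = 18, seed = 1L, noise_sd = 0.5,
                            asymmetry_max = 2, offset_sd = 3,
                            scale_sd = 0.05) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single integer >= 1.", class = "trk_error_degenerate")
  }
  if (noise_sd < 0 || asymmetry_max < 0 || offset_sd < 0 || scale_sd < 0) {
    abort("Cohort distribution parameters must be non-negative.",
          class = "trk_error_degenerate")
  }
  n <- as.integer(n)
  subjects <- lapply(seq_len(n), function(i) {
    draw_seed <- subject_seed(seed, i, 0L)
    pars <- withr::with_seed(draw_seed, {
      subject_params(
        scale = exp(rnorm(1, 0, scale_sd)),
        ramus_angle_offset = rnorm(1, 0, offset_sd),
        cranial_base_offset = rnorm(1, 0, offset_sd),
        asymmetry = runif(1, 0, asymmetry_max),
        noise_sd = noise_sd,
        seed = subject_seed(seed, i, 1L)
      )
    })
    generate_subject(pars)
  })
  tibble(
    subject = seq_len(n),
    lm3d = lapply(subjects, `[[`, "lm3d"),
    lm2d = lapply(subjects, `[[`, "lm2d"),
    params = lapply(subjects, `[[`, "params")
  )
}

# Deterministic per-subject stream seed below 2^31, stable in i.
subject_seed <- function(master, i, salt) {
  as.integer((as.numeric(master) * 48271 + i * 1299709 + salt * 7919) %%
               2147483629)
}
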