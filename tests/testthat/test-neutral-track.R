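test_that("mid-sagittal estimation recovers the symmetry plane and is equivariant", {
  lm <- template_lm3d()
  sag <- midsagittal_plane(lm)
  expect_equal(abs(sag$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(sag$anchor, lmk(lm, "Ba"))

  # Rotation by 10 degrees about z rotates the normal identically.
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sag_r <- midsagittal_plane(transform_lm3d(lm, R))
  expect_equal(abs(sag_r$normal), abs(as.numeric(R %*% c(1, 0, 0))),
               tolerance = 1e-9)

  # Swapping one bilateral pair must not change downstream angles.
  tpl <- template_landmarks()
  i_r <- which(tpl$name == "rMCF"); i_l <- which(tpl$name == "lMCF")
  tpl$name[c(i_r, i_l)] <- c("lMCF", "rMCF")
  sc_swapped <- neutral_self_check(
    build_neutral_track_3d(suppressWarnings(as_landmarks_3d(tpl))))
  expect_equal(sc_swapped$value, c(40.3, 90, 0), tolerance = 1e-6)
})

test_that("MCFx is the sagittal crossing of the cranial-floor chord", {
  lm <- template_lm3d()
  sag <- midsagittal_plane(lm)
  expect_equal(locate_mcfx(lm, sag), c(0, 45, 18), tolerance = 1e-9)
  # Symmetric set: MCFx equals the chord midpoint.
  expect_equal(locate_mcfx(lm, sag),
               (lmk(lm, "rMCF") + lmk(lm, "lMCF")) / 2, tolerance = 1e-9)
  # Both chord ends on one side: no crossing.
  expect_error(locate_mcfx(lm, new_plane(c(100, 0, 0), c(1, 0, 0))),
               class = "trk_error_no_intersection")
})

test_that("SEn sits on the sphere at the neutral elevation from CPBa", {
  lm <- template_lm3d()
  sag <- midsagittal_plane(lm)
  pm <- plane_from_points(lmk(lm, "lMCF"), lmk(lm, "rMCF"), lmk(lm, "PNS"))
  parts <- locate_sen(lm, sag, pm)
  expect_equal(parts$sphere$radius, sqrt(45^2 + 18^2), tolerance = 1e-9)
  expect_equal(parts$sen, c(0, 28.1697, 39.4394), tolerance = 1e-4)
  expect_equal(vnorm_for_test(parts$sen - lmk(lm, "Ba")),
               parts$sphere$radius, tolerance = 1e-9)
  # Elevation of the Ba->SEn ray over CPBa is exactly the neutral angle.
  d <- (parts$sen - lmk(lm, "Ba")) / parts$sphere$radius
  elev <- asin(abs(sum(d * parts$cpba$normal))) * 180 / pi
  expect_equal(elev, 40.3, tolerance = 1e-9)
})

test_that("SEn agrees with the dense circle-sampling oracle", {
  lm <- template_lm3d()
  sag <- midsagittal_plane(lm)
  pm <- plane_from_points(lmk(lm, "lMCF"), lmk(lm, "rMCF"), lmk(lm, "PNS"))
  sen <- locate_sen(lm, sag, pm)$sen
  oracle <- sen_oracle(lm, n_samples = 1e6)
  expect_lt(vnorm_for_test(sen - oracle), 0.01)
})

test_that("tangent-mode MCFn is delta-independent and hits the neutral angle exactly", {
  lm <- template_lm3d()
  ref <- NULL
  for (delta in c(1, 5, 20)) {
    nt <- build_neutral_track_3d(lm, track_config(delta = delta))
    sc <- neutral_self_check(nt)
    expect_equal(sc$value[sc$check == "MCFn^PMn"], 40.3, tolerance = 1e-9)
    if (is.null(ref)) ref <- nt$MCFn
    expect_equal(abs(sum(nt$MCFn$normal * ref$normal)), 1, tolerance = 1e-9)
  }
  # Helper points flank SEn laterally and rSEn is on the subject's right.
  nt <- build_neutral_track_3d(lm)
  expect_gt(nt$rSEn[1], nt$lSEn[1])
  expect_equal((nt$rSEn + nt$lSEn) / 2, nt$SEn, tolerance = 1e-9)
})

test_that("on_sphere-mode MCFn keeps its helpers on the sphere with a small angle deviation shrinking with delta", {
  lm <- template_lm3d()
  devs <- vapply(c(5, 2, 0.5), function(delta) {
    nt <- build_neutral_track_3d(lm, track_config(mcfn_mode = "on_sphere",
                                                  delta = delta))
    expect_equal(vnorm_for_test(nt$rSEn - lmk(lm, "Ba")), nt$sphere$radius,
                 tolerance = 1e-9)
    expect_equal(vnorm_for_test(nt$lSEn - lmk(lm, "Ba")), nt$sphere$radius,
                 tolerance = 1e-9)
    sc <- neutral_self_check(nt)
    abs(sc$value[sc$check == "MCFn^PMn"] - 40.3)
  }, 0)
  expect_lt(devs[1], 0.5)          # delta = 5 mm
  expect_lt(devs[3], 0.01)         # delta = 0.5 mm
  expect_true(all(diff(devs) < 0)) # deviation shrinks with delta
})

test_that("PMn is parallel to PM through SEn and FOPn is perpendicular to PMn", {
  nt <- build_neutral_track_3d(template_lm3d())
  expect_lt(dihedral_angle(nt$PMn, nt$PM), 1e-9)
  expect_lt(abs(signed_distance(nt$SEn, nt$PMn)), 1e-9)
  expect_equal(dihedral_angle(nt$FOPn, nt$PMn), 90, tolerance = 1e-9)
  lm <- template_lm3d()
  expect_lt(abs(signed_distance(lmk(lm, "rPoc"), nt$FOPn)), 1e-9)
  expect_lt(abs(signed_distance(lmk(lm, "lPoc"), nt$FOPn)), 1e-9)
})

test_that("neutral gonions satisfy the halfway and same-level rules", {
  lm <- template_lm3d()
  nt <- build_neutral_track_3d(lm)
  for (side in c("rGon", "lGon")) {
    g <- nt[[side]]
    expect_equal(abs(signed_distance(g, nt$PMn)),
                 abs(signed_distance(g, nt$CPCo)), tolerance = 1e-9)
    expect_lt(abs(signed_distance(g, nt$GoP)), 1e-9)
  }
  # Displacement is purely along the PMn normal.
  shift <- nt$rGon - lmk(lm, "rGo")
  expect_equal(abs(sum(shift / vnorm_for_test(shift) * nt$PMn$normal)), 1,
               tolerance = 1e-9)
  # MRn passes through mCo and both gonions.
  for (p in list(lmk(lm, "mCo"), nt$rGon, nt$lGon)) {
    expect_lt(abs(signed_distance(p, nt$MRn)), 1e-9)
  }
})

test_that("2D neutral construction satisfies its defining identities", {
  nt <- build_neutral_track_2d(toy_lm2d())
  lm <- toy_lm2d()
  # Radius preservation and the derived SEn position (rotation oracle).
  expect_equal(vnorm_for_test(nt$SEn - lmk(lm, "Ar")), 50, tolerance = 1e-9)
  a <- 40.3 * pi / 180
  expect_equal(nt$SEn, c(50 * sin(a), 50 * cos(a)), tolerance = 1e-9)
  sc <- neutral_self_check(nt)
  expect_equal(sc$value[sc$check == "MCFn^PMn"], 40.3, tolerance = 1e-9)
  expect_equal(sc$value[sc$check == "FOPn^PMn"], 90, tolerance = 1e-9)
  expect_lt(sc$value[sc$check == "PMn^PM"], 1e-9)
  # Gon equidistant from PMn and its parallel through Ar, at Go's level.
  d_pmn <- distance_point_line_2d(nt$Gon, nt$PMn)
  d_cp <- distance_point_line_2d(nt$Gon, nt$CPAr)
  expect_equal(d_pmn, d_cp, tolerance = 1e-9)
  along <- sum((nt$Gon - lmk(lm, "Go")) * nt$PMn$direction)
  expect_lt(abs(along), 1e-9)
  expect_error(build_neutral_track_2d({
    bad <- toy_lm2d(); bad$x[bad$name == "SE"] <- 0
    bad$y[bad$name == "SE"] <- 0; bad
  }), class = "trk_error_degenerate")
})

test_that("2D and 3D neutral constructions share the self-check triple on any valid subject", {
  withr::with_seed(23, {
    for (i in 1:5) {
      s <- generate_subject(subject_params(
        scale = exp(rnorm(1, 0, 0.1)),
        ramus_angle_offset = rnorm(1, 0, 4),
        cranial_base_offset = rnorm(1, 0, 4),
        asymmetry = runif(1, 0, 2),
        noise_sd = runif(1, 0, 1.5),
        seed = 100 + i
      ))
      sc3 <- neutral_self_check(build_neutral_track_3d(s$lm3d))
      sc2 <- neutral_self_check(build_neutral_track_2d(s$lm2d))
      expect_equal(sc3$value, c(40.3, 90, 0), tolerance = 1e-6)
      expect_equal(sc2$value, c(40.3, 90, 0), tolerance = 1e-6)
    }
  })
})

test_that("full-pipeline angles survive rigid motion, scaling and mirror reflection", {
  lm <- template_lm3d()
  ref_ang <- measure_angles_3d(build_individual_track_3d(lm))$value
  ref_sc <- neutral_self_check(build_neutral_track_3d(lm))$value
  M <- diag(c(-1, 1, 1))   # mirror through the sagittal plane
  lm_m <- suppressWarnings(transform_lm3d(lm, M))
  expect_equal(measure_angles_3d(build_individual_track_3d(lm_m))$value,
               ref_ang, tolerance = 1e-6)
  expect_equal(neutral_self_check(build_neutral_track_3d(lm_m))$value,
               ref_sc, tolerance = 1e-6)
  withr::with_seed(29, {
    for (i in 1:10) {
      lm_t <- transform_lm3d(lm, random_rotation(), rnorm(3, sd = 80),
                             exp(rnorm(1, sd = 0.3)))
      expect_equal(measure_angles_3d(build_individual_track_3d(lm_t))$value,
                   ref_ang, tolerance = 1e-6)
      expect_equal(neutral_self_check(build_neutral_track_3d(lm_t))$value,
                   ref_sc, tolerance = 1e-6)
    }
  })
})

test_that("track deltas quantify the rotational factor consistently", {
  lm <- template_lm3d()
  ind <- build_individual_track_3d(lm)
  nt <- build_neutral_track_3d(lm)
  deltas <- track_delta(ind, nt)
  expect_setequal(deltas$plane, c("MCF", "PM", "MR", "FOP"))
  expect_equal(deltas$delta[deltas$plane == "PM"], 0)
  # MCF delta equals the difference between the individual MCF^PM and the
  # neutral constant, up to orientation.
  ang <- measure_angles_3d(ind)$value
  expect_equal(deltas$delta[deltas$plane == "MCF"], abs(ang[1] - 40.3),
               tolerance = 1e-6)
  # A subject whose cranial base is pre-rotated to 40.3 has zero MCF delta.
  off <- 40.3 - ang[1]
  s <- generate_subject(subject_params(cranial_base_offset = off))
  d2 <- track_delta(build_individual_track_3d(s$lm3d),
                    build_neutral_track_3d(s$lm3d))
  expect_lt(d2$delta[d2$plane == "MCF"], 1e-6)
})

test_that("degenerate neutral constructions fail with stage-attributed errors", {
  tpl <- template_landmarks()
  # MCFx collapsing onto Ba gives a zero-radius sphere.
  tpl[tpl$name == "rMCF", c("x", "y", "z")] <- list(25, 0, 0)
  tpl[tpl$name == "lMCF", c("x", "y", "z")] <- list(-25, 0, 0)
  err <- tryCatch(build_neutral_track_3d(as_landmarks_3d(tpl)),
                  error = function(e) e)
  expect_s3_class(err, "trk_error_degenerate")
  expect_match(conditionMessage(err), "stage")
})
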