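test_that("plane_from_points contains its generators and orients by the right-hand rule", {
  p <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(p$anchor, c(0, 0, 0))
  expect_equal(p$normal, c(0, 0, 1))

  p2 <- plane_from_points(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(p2$normal, c(1, 0, 0))

  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "trk_error_degenerate")

  # Membership of all three generators, random cases.
  withr::with_seed(11, {
    for (i in 1:25) {
      pts <- lapply(1:3, function(k) rnorm(3, sd = 30))
      pl <- plane_from_points(pts[[1]], pts[[2]], pts[[3]])
      for (q in pts) expect_lt(abs(signed_distance(q, pl)), 1e-9)
    }
  })
})

test_that("parallel and perpendicular plane constructions obey their contracts", {
  z0 <- new_plane(c(0, 0, 0), c(0, 0, 1))
  p <- plane_parallel_through(z0, c(0, 0, 5))
  expect_equal(signed_distance(c(0, 0, 5), p), 0)
  expect_equal(p$normal, z0$normal)

  ident <- plane_parallel_through(z0, c(3, -2, 0))
  expect_equal(dihedral_angle(ident, z0), 0)
  expect_lt(abs(signed_distance(c(0, 0, 0), ident)), 1e-12)

  pm_like <- new_plane(c(0, 0, 0), c(0, -0.99654, -0.08304))
  q <- c(0, 28.17, 39.44)
  par <- plane_parallel_through(pm_like, q)
  expect_lt(abs(signed_distance(q, par)), 1e-12)
  expect_lt(dihedral_angle(par, pm_like), 1e-9)

  perp <- plane_perpendicular_through_chord(z0, c(-10, 0, -5), c(10, 0, -5))
  expect_equal(abs(perp$normal), c(0, 1, 0))
  expect_equal(dihedral_angle(perp, z0), 90)
  expect_lt(abs(signed_distance(c(-10, 0, -5), perp)), 1e-12)
  expect_lt(abs(signed_distance(c(10, 0, -5), perp)), 1e-12)

  expect_error(
    plane_perpendicular_through_chord(z0, c(0, 0, 0), c(0, 0, 5)),
    class = "trk_error_degenerate")

  # Hand cross-product case: normal prop to (0,0,1) x (1,1,0) = (-1,1,0)/sqrt(2).
  p3 <- plane_perpendicular_through_chord(z0, c(0, 0, 0), c(1, 1, 0))
  expect_equal(p3$normal, c(-1, 1, 0) / sqrt(2))
  expect_equal(dihedral_angle(p3, z0), 90)
})

test_that("dihedral_angle matches arccos of the normals' dot product and the reflection identity", {
  z0 <- new_plane(c(0, 0, 0), c(0, 0, 1))
  y0 <- new_plane(c(0, 0, 0), c(0, 1, 0))
  expect_equal(dihedral_angle(z0, y0), 90)
  expect_equal(dihedral_angle(z0, z0), 0)
  a <- 40.3 * pi / 180
  tilted <- new_plane(c(0, 0, 0), c(0, sin(a), cos(a)))
  expect_equal(dihedral_angle(z0, tilted), 40.3)
  expect_equal(dihedral_angle(tilted, z0), dihedral_angle(z0, tilted))

  # Reflecting b's normal through a complements the dihedral to 180.
  withr::with_seed(21, {
    for (i in 1:20) {
      na <- rnorm(3); nb <- rnorm(3)
      a_pl <- new_plane(rnorm(3), na)
      b_pl <- new_plane(rnorm(3), nb)
      nbu <- b_pl$normal
      refl <- nbu - 2 * sum(nbu * a_pl$normal) * a_pl$normal
      b_refl <- new_plane(b_pl$anchor, refl)
      expect_equal(dihedral_angle(a_pl, b_pl) + dihedral_angle(a_pl, b_refl),
                   180, tolerance = 1e-6)
    }
  })
})

test_that("plane traces lie in both planes and oriented trace angles follow their hints", {
  y0 <- new_plane(c(0, 0, 0), c(0, 1, 0))
  x0 <- new_plane(c(0, 0, 0), c(1, 0, 0))
  tr <- plane_trace_on_plane(y0, x0)
  expect_equal(abs(tr$direction), c(0, 0, 1))
  expect_lt(abs(signed_distance(tr$point, y0)), 1e-9)
  expect_lt(abs(signed_distance(tr$point, x0)), 1e-9)

  expect_error(plane_trace_on_plane(
    new_plane(c(0, 0, 0), c(0, 0, 1)), new_plane(c(0, 0, 5), c(0, 0, 1))),
    class = "trk_error_degenerate")

  # MCF-like plane sectioned at x = 0 passes through (0,45,18) and origin.
  mcf <- plane_from_points(c(25, 45, 18), c(-25, 45, 18), c(0, 0, 0))
  tr2 <- plane_trace_on_plane(mcf, x0)
  for (q in list(c(0, 45, 18), c(0, 0, 0))) {
    w <- q - tr2$point
    expect_lt(vnorm_for_test(w - sum(w * tr2$direction) * tr2$direction), 1e-9)
  }

  a <- plane_from_points(c(10, 50, 0), c(-10, 50, 0), c(0, 0, 0))
  b <- plane_from_points(c(10, 50, 0), c(-10, 50, 0), c(0, 50, -20))
  expect_equal(
    oriented_trace_angle(a, b, x0, c(0, -1, 0), c(0, 0, -1)), 90)
  expect_equal(
    oriented_trace_angle(a, a, x0, c(0, -1, 0), c(0, -1, 0)), 0)
  expect_error(
    oriented_trace_angle(a, b, x0, c(1, 0, 0), c(0, 0, -1)),
    class = "trk_error_degenerate")
})

test_that("signed distances and segment-plane intersections follow the sign convention", {
  z0 <- new_plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(signed_distance(c(0, 0, 5), z0), 5)
  expect_equal(signed_distance(c(3, 4, 0), z0), 0)
  expect_equal(signed_distance(c(0, 0, -5), z0), -5)

  x0 <- new_plane(c(0, 0, 0), c(1, 0, 0))
  expect_equal(segment_plane_intersection(c(-25, 45, 18), c(25, 45, 18), x0),
               c(0, 45, 18))
  expect_equal(segment_plane_intersection(c(-1, 0, 0), c(3, 0, 0), x0),
               c(0, 0, 0))
  expect_error(segment_plane_intersection(c(1, 0, 0), c(2, 0, 0), x0),
               class = "trk_error_no_intersection")
  expect_error(segment_plane_intersection(c(0, 1, 0), c(0, 2, 0), x0),
               class = "trk_error_degenerate")
})

test_that("sphere-plane intersection returns the projected circle", {
  s <- new_sphere(c(0, 0, 0), 10)
  z0 <- new_plane(c(0, 0, 0), c(0, 0, 1))
  c1 <- sphere_plane_intersection(s, z0)
  expect_equal(c1$center, c(0, 0, 0))
  expect_equal(c1$radius, 10)

  c2 <- sphere_plane_intersection(s, new_plane(c(0, 0, 6), c(0, 0, 1)))
  expect_equal(c2$center, c(0, 0, 6))
  expect_equal(c2$radius, 8)

  expect_error(
    sphere_plane_intersection(s, new_plane(c(0, 0, 11), c(0, 0, 1))),
    class = "trk_error_no_intersection")
  expect_error(
    sphere_plane_intersection(s, new_plane(c(0, 0, 10), c(0, 0, 1))),
    class = "trk_error_no_intersection")
})

test_that("point_on_circle_at_angle places the point on the circle at the exact elevation", {
  circ <- new_circle(c(0, 0, 0), 70, c(1, 0, 0))
  z0 <- new_plane(c(0, 0, 0), c(0, 0, 1))
  a <- 40.3 * pi / 180
  p <- point_on_circle_at_angle(circ, z0, 40.3, "anterior-superior")
  expect_equal(p, c(0, 70 * cos(a), 70 * sin(a)), tolerance = 1e-9)
  expect_equal(vnorm_for_test(p - circ$center), 70)

  # Boundary: angle 90 collapses to the pole.
  p90 <- point_on_circle_at_angle(circ, z0, 90, "superior")
  expect_equal(p90, c(0, 0, 70), tolerance = 1e-6)

  # Small-angle limit approaches the in-plane direction.
  p_small <- point_on_circle_at_angle(circ, z0, 1e-6, "anterior")
  expect_equal(p_small, c(0, 70, 0), tolerance = 1e-4)

  # Each of the four quadrant selectors isolates a distinct candidate.
  branches <- c("anterior-superior", "anterior-inferior",
                "posterior-superior", "posterior-inferior")
  pts <- lapply(branches, function(b) point_on_circle_at_angle(circ, z0, 40.3, b))
  expect_equal(length(unique(lapply(pts, round, 6))), 4)

  # A hint along the circle normal cannot separate candidates.
  expect_error(point_on_circle_at_angle(circ, z0, 40.3, c(1, 0, 0)),
               class = "trk_error_branch_ambiguity")
})

test_that("angle operations are invariant under rigid motions and scaling", {
  withr::with_seed(31, {
    base_pts <- list(a1 = c(2, 1, 0), a2 = c(-3, 4, 1), a3 = c(0, -2, 5),
                     b1 = c(1, 1, 1), b2 = c(4, -2, 0), b3 = c(-1, 0, 3))
    pa <- plane_from_points(base_pts$a1, base_pts$a2, base_pts$a3)
    pb <- plane_from_points(base_pts$b1, base_pts$b2, base_pts$b3)
    ref <- dihedral_angle(pa, pb)
    for (i in 1:20) {
      R <- random_rotation()
      t <- rnorm(3, sd = 50)
      s <- exp(rnorm(1, sd = 0.4))
      tp <- lapply(base_pts, function(p) s * as.numeric(R %*% p) + t)
      qa <- plane_from_points(tp$a1, tp$a2, tp$a3)
      qb <- plane_from_points(tp$b1, tp$b2, tp$b3)
      expect_equal(dihedral_angle(qa, qb), ref, tolerance = 1e-6)
    }
  })
})
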