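# Shared fixtures and independent oracles built in code.

vnorm_for_test <- function(v) sqrt(sum(v^2))

rot2_for_test <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

template_lm3d <- function() as_landmarks_3d(template_landmarks())

# 2D landmark fixture with simple integer geometry.
toy_lm2d <- function() {
  as_landmarks_2d(data.frame(
    name = c("Ar", "SE", "Ptm", "Go", "Poc", "Aoc"),
    x = c(0, 40, 40, 0, 30, 55),
    y = c(0, 30, 10, -50, -40, -38)
  ))
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply p -> scale * R p + t to every landmark of a 3D set.
transform_lm3d <- function(lm, R = diag(3), t = c(0, 0, 0), scale = 1) {
  prim <- lm[!lm$derived, , drop = FALSE]
  m <- scale * as.matrix(prim[, c("x", "y", "z")]) %*% t(R)
  m <- sweep(m, 2, t, FUN = "+")
  as_landmarks_3d(data.frame(name = prim$name,
                             x = m[, 1], y = m[, 2], z = m[, 3]))
}

# Brute-force SEn oracle: sample the sagittal circle densely, keep points
# achieving the target elevation from the construction plane (within the
# sampling resolution) and return the one maximizing the branch-hint dot
# product. Independent of point_on_circle_at_angle.
sen_oracle <- function(lm, n_samples = 1e6, angle = 40.3) {
  sag <- midsagittal_plane(lm)
  pm <- plane_from_points(lmk(lm, "lMCF"), lmk(lm, "rMCF"), lmk(lm, "PNS"))
  ba <- lmk(lm, "Ba")
  mcfx <- locate_mcfx(lm, sag)
  r <- sqrt(sum((mcfx - ba)^2))
  n <- sag$normal
  # Orthonormal basis of the sagittal plane.
  seed_vec <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed_vec - sum(seed_vec * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  th <- seq(0, 2 * pi, length.out = n_samples + 1)[-1]
  pts <- sweep(r * (outer(cos(th), u) + outer(sin(th), v)), 2, ba, FUN = "+")
  npm <- pm$normal
  elev <- asin(pmin(1, abs((pts %*% npm) - sum(ba * npm)) / r)) * 180 / pi
  near <- which(abs(elev - angle) < 0.001)
  hint <- mcfx - ba
  scores <- (pts[near, , drop = FALSE] %*% hint)
  pts[near[which.max(scores)], ]
}
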