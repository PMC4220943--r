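# Shared fixtures and independent oracles for the geometry tests.

# Uniform random rotation via a random unit quaternion — independent of the
# package's Rodrigues construction.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(points, R, t) {
  out <- points %*% t(R) + matrix(t, nrow(points), 3, byrow = TRUE)
  dimnames(out) <- dimnames(points)
  out
}

# The axis-aligned four-landmark configuration whose frame is the identity.
axis_aligned_points <- function() {
  rbind(MLWS = c(0, 2, 0), Na = c(0, 60, 0),
        S = c(0, 0, 0), Ba = c(0, -10, -30))
}

# A random non-degenerate landmark set: reference quadruple plus optional
# extra landmarks, in a random pose.
random_trial <- function(n_extra = 3, patient = "P1", trial = "T1") {
  pts <- axis_aligned_points()
  if (n_extra > 0) {
    extra <- matrix(runif(3 * n_extra, -80, 80), n_extra, 3)
    rownames(extra) <- paste0("L", seq_len(n_extra))
    pts <- rbind(pts, extra)
  }
  # jitter the reference quadruple so frames differ between random trials
  pts <- pts + matrix(rnorm(length(pts), 0, 2), nrow(pts), 3)
  pts <- apply_rigid(pts, random_rotation(), runif(3, -50, 50))
  landmark_set(pts, patient, trial)
}

# Independent frame-coordinate oracle: orthonormal basis from qr() on the
# span of (Na - S) and the component of (foot - Ba), signs fixed by dot
# products, coordinates by solving the basis system.
oracle_reoriented <- function(trial) {
  p <- trial$points
  y_dir <- p["Na", ] - p["S", ]
  yb <- p["Ba", ] - p["S", ]
  qr_dec <- qr(cbind(y_dir, yb))
  Q <- qr.Q(qr_dec)
  y <- Q[, 1] * sign(sum(Q[, 1] * y_dir))
  foot <- p["S", ] + sum((p["Ba", ] - p["S", ]) * y) * y
  zd <- foot - p["Ba", ]
  z <- zd / sqrt(sum(zd^2))
  x <- c(y[2] * z[3] - y[3] * z[2], y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  basis <- cbind(x, y, z)
  t(apply(p, 1, function(pt) solve(basis, pt - p["MLWS", ])))
}

expect_frame_valid <- function(frame, tol = 1e-9) {
  expect_equal(sum(frame$x_axis^2), 1, tolerance = tol)
  expect_equal(sum(frame$y_axis^2), 1, tolerance = tol)
  expect_equal(sum(frame$z_axis^2), 1, tolerance = tol)
  expect_lt(abs(sum(frame$x_axis * frame$y_axis)), tol)
  expect_lt(abs(sum(frame$x_axis * frame$z_axis)), tol)
  expect_lt(abs(sum(frame$y_axis * frame$z_axis)), tol)
  cr <- c(frame$y_axis[2] * frame$z_axis[3] - frame$y_axis[3] * frame$z_axis[2],
          frame$y_axis[3] * frame$z_axis[1] - frame$y_axis[1] * frame$z_axis[3],
          frame$y_axis[1] * frame$z_axis[2] - frame$y_axis[2] * frame$z_axis[1])
  expect_equal(unname(frame$x_axis), unname(cr), tolerance = tol)
}
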