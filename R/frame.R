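#' Build the 4-point anatomical reference frame
#'
#' Constructs the right-handed orthonormal coordinate system that the
#' plane-orientation method defines from four cranial-base landmarks:
#' the anteroposterior y axis is parallel to the sella--nasion line (positive
#' toward nasion), the vertical z axis points from basion toward its
#' perpendicular foot on that line (positive superior), the transverse x axis
#' completes the right-handed triad (x = y x z), and MLWS becomes the origin.
#'
#' @param trial a [landmark_set()] containing MLWS, Na, S and Ba.
#' @param tol degeneracy tolerance in mm: the frame is refused when
#'   |Na - S| or basion's perpendicular offset from the Na--S line falls
#'   below it. The default (1e-6 mm) sits far below digitization noise
#'   (~0.3 mm) and far above double-precision rounding.
#' @return An object of class `reference_frame` with fields `origin`,
#'   `x_axis`, `y_axis`, `z_axis` (unit 3-vectors, mm).
#' @examples
#' pts <- rbind(MLWS = c(0, 2, 0), Na = c(0, 60, 0),
#'              S = c(0, 0, 0), Ba = c(0, -10, -30))
#' build_reference_frame(landmark_set(pts))
#' @export
build_reference_frame <- function(trial, tol = 1e-6) {
  require_reference_landmarks(trial)
  na <- landmark_point(trial, "Na")
  s  <- landmark_point(trial, "S")
  ba <- landmark_point(trial, "Ba")
  mlws <- landmark_point(trial, "MLWS")

  v <- na - s
  nv <- sqrt(sum(v^2))
  if (nv < tol) {
    degenerate_frame("Na and S coincide: anteroposterior axis undefined")
  }
  y_axis <- v / nv

  foot <- s + sum((ba - s) * y_axis) * y_axis
  w <- foot - ba
  nw <- sqrt(sum(w^2))
  if (nw < tol) {
    degenerate_frame("Ba lies on the Na-S line: vertical axis undefined")
  }
  z_axis <- w / nw
  x_axis <- cross3(y_axis, z_axis)

  structure(
    list(origin = mlws, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis),
    class = "reference_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame>\n")
  cat("  origin:", format(x$origin, digits = 6), "\n")
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: %s\n", ax, paste(format(x[[ax]], digits = 6), collapse = " ")))
  }
  invisible(x)
}

#' Reorient a landmark set into a reference frame
#'
#' Expresses every landmark in the anatomical frame: for a point P the new
#' coordinates are the projections of (P - origin) onto the x, y and z axes.
#' The map is rigid, so all inter-landmark distances are preserved; when the
#' frame was built from the same trial, MLWS maps exactly to the origin
#' (0, 0, 0).
#'
#' @param trial a [landmark_set()].
#' @param frame a `reference_frame` from [build_reference_frame()].
#' @return A `landmark_set` whose points are frame coordinates; the
#'   `"frame_trial"` attribute records which trial defined the frame.
#' @export
reorient <- function(trial, frame) {
  stopifnot(inherits(frame, "reference_frame"))
  basis <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  pts <- sweep(trial$points, 2L, frame$origin) %*% basis
  dimnames(pts) <- list(rownames(trial$points), c("x", "y", "z"))
  out <- landmark_set(pts, trial$patient_id, trial$trial_id)
  attr(out, "frame_trial") <- frame
  out
}

#' Perpendicular distance from the reoriented x axis
#'
#' For frame coordinates (x, y, z) the transverse axis passes through the
#' origin along x, so the perpendicular distance is sqrt(y^2 + z^2).
#'
#' @param coords a numeric 3-vector, or a matrix with columns x, y, z.
#' @return Distance(s) in mm.
#' @examples
#' distance_from_x_axis(c(0, 3, 4))  # 5
#' @export
distance_from_x_axis <- function(coords) {
  if (is.matrix(coords)) {
    sqrt(coords[, 2]^2 + coords[, 3]^2)
  } else {
    sqrt(coords[2]^2 + coords[3]^2)
  }
}
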