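#' Locating error of a repeatedly digitized landmark
#'
#' Per-axis absolute coordinate differences and the Euclidean distance (Db)
#' between the two placements of a landmark, in the shared scanner frame,
#' before any reorientation.
#'
#' @param pair a [trial_pair()].
#' @param landmark landmark name.
#' @return Named numeric vector `c(dx_err, dy_err, dz_err, Db)` in mm.
#' @export
locating_error <- function(pair, landmark) {
  a <- landmark_point(pair$trial_a, landmark)
  b <- landmark_point(pair$trial_b, landmark)
  d <- a - b
  c(dx_err = abs(d[[1]]), dy_err = abs(d[[2]]), dz_err = abs(d[[3]]),
    Db = sqrt(sum(d^2)))
}

#' Reorientation error of a landmark
#'
#' Each trial is expressed in the frame built from its *own* four reference
#' landmarks; the reorientation error Y is the Euclidean distance between the
#' two reoriented positions. Because the reference landmarks themselves move
#' between digitizations, Y folds frame uncertainty on top of the landmark's
#' own locating error. MLWS is each trial's origin, so its Y is identically
#' zero.
#'
#' @inheritParams locating_error
#' @param tol degeneracy tolerance passed to [build_reference_frame()].
#' @return Y in mm.
#' @export
reorientation_error <- function(pair, landmark, tol = 1e-6) {
  fa <- build_reference_frame(pair$trial_a, tol)
  fb <- build_reference_frame(pair$trial_b, tol)
  pa <- frame_coords(landmark_point(pair$trial_a, landmark), fa)
  pb <- frame_coords(landmark_point(pair$trial_b, landmark), fb)
  sqrt(sum((pa - pb)^2))
}

frame_coords <- function(p, frame) {
  d <- p - frame$origin
  c(sum(d * frame$x_axis), sum(d * frame$y_axis), sum(d * frame$z_axis))
}

#' Sum of angle errors of the reference points (A3r)
#'
#' From the averaged position of a landmark (midpoint of its two placements,
#' scanner coordinates), each reference point Na, S, Ba subtends an angle
#' between its two placements; A3r is the sum of the three angles in degrees.
#' It measures how much the reference configuration shifted between the two
#' digitizations, as seen from that landmark.
#'
#' @inheritParams locating_error
#' @param tol minimum distance (mm) between the averaged landmark and a
#'   reference placement below which the angle is undefined.
#' @return A3r in degrees (0 when all three reference points were digitized
#'   identically).
#' @export
a3r <- function(pair, landmark, tol = 1e-6) {
  abar <- (landmark_point(pair$trial_a, landmark) +
           landmark_point(pair$trial_b, landmark)) / 2
  total <- 0
  for (ref in c("Na", "S", "Ba")) {
    u <- landmark_point(pair$trial_a, ref) - abar
    v <- landmark_point(pair$trial_b, ref) - abar
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < tol || nv < tol) {
      degenerate_angle(sprintf(
        "averaged landmark '%s' coincides with a placement of reference '%s'",
        landmark, ref))
    }
    cosang <- max(-1, min(1, sum(u * v) / (nu * nv)))
    total <- total + acos(cosang)
  }
  total * 180 / pi
}

# Pair-averaged trial: midpoint of the two placements of every landmark
# common to both trials, in scanner coordinates.
averaged_trial <- function(pair) {
  common <- intersect(rownames(pair$trial_a$points), rownames(pair$trial_b$points))
  pts <- (pair$trial_a$points[common, , drop = FALSE] +
          pair$trial_b$points[common, , drop = FALSE]) / 2
  landmark_set(pts, pair$patient_id, paste0("avg(", pair$pair_label, ")"))
}

#' Distance of the averaged landmark from the reoriented x axis (DX)
#'
#' A frame is built from the pair-averaged reference landmarks (midpoints of
#' MLWS, Na, S, Ba across the two trials); the averaged landmark is reoriented
#' into it and its perpendicular distance from the transverse x axis returned.
#'
#' @inheritParams reorientation_error
#' @return DX in mm.
#' @export
dx_metric <- function(pair, landmark, tol = 1e-6) {
  avg <- averaged_trial(pair)
  frame <- build_reference_frame(avg, tol)
  distance_from_x_axis(frame_coords(landmark_point(avg, landmark), frame))
}

#' Error records for a full cohort
#'
#' Computes, for every patient, every unordered pair of digitization trials
#' and every landmark common to the pair, the complete set of error
#' statistics: per-axis locating errors and Db; the reorientation error Y;
#' and the averaged-landmark geometry DX, DY, DZ, D0 (perpendicular distances
#' from the reoriented x, y, z axes and the distance from the origin, all
#' measured on the pair-averaged frame). A3r is reported for the 15
#' non-reference landmarks and NA for MLWS/Na/S/Ba, where the angle sum is
#' not meaningful.
#'
#' @param cohort a long coordinate data.frame (schema of
#'   [read_landmark_table()]) or a `synthetic_cohort`.
#' @param tol degeneracy tolerance forwarded to frame construction.
#' @return A data.frame with one row per (patient, pair, landmark) and
#'   columns `patient_id, pair, landmark, dxerr_mm, dyerr_mm, dzerr_mm,
#'   Db_mm, Y_mm, DX_mm, A3r_deg, DY_mm, DZ_mm, D0_mm`.
#' @export
error_records <- function(cohort, tol = 1e-6) {
  df <- as.data.frame(cohort)
  sets <- table_to_landmark_sets(df)
  out <- vector("list", 0L)
  for (pid in names(sets)) {
    trials <- sets[[pid]]
    if (length(trials) < 2L) {
      insufficient_data(sprintf("patient %s has fewer than 2 trials", pid))
    }
    idx <- utils::combn(length(trials), 2L)
    for (k in seq_len(ncol(idx))) {
      pair <- trial_pair(trials[[idx[1, k]]], trials[[idx[2, k]]])
      out[[length(out) + 1L]] <- pair_records(pair, tol)
    }
  }
  do.call(rbind, out)
}

# All statistics for one trial pair, vectorized over landmarks.
pair_records <- function(pair, tol = 1e-6) {
  a <- pair$trial_a; b <- pair$trial_b
  common <- intersect(rownames(a$points), rownames(b$points))
  pa <- a$points[common, , drop = FALSE]
  pb <- b$points[common, , drop = FALSE]

  d <- pa - pb
  db <- sqrt(rowSums(d^2))

  fa <- build_reference_frame(a, tol)
  fb <- build_reference_frame(b, tol)
  ra <- reorient(a, fa)$points[common, , drop = FALSE]
  rb <- reorient(b, fb)$points[common, , drop = FALSE]
  y <- sqrt(rowSums((ra - rb)^2))

  avg <- averaged_trial(pair)
  favg <- build_reference_frame(avg, tol)
  ravg <- reorient(avg, favg)$points[common, , drop = FALSE]
  dx <- sqrt(ravg[, 2]^2 + ravg[, 3]^2)
  dy <- sqrt(ravg[, 1]^2 + ravg[, 3]^2)
  dz <- sqrt(ravg[, 1]^2 + ravg[, 2]^2)
  d0 <- sqrt(rowSums(ravg^2))

  abar <- avg$points[common, , drop = FALSE]
  ang <- rep(0, length(common))
  for (ref in c("Na", "S", "Ba")) {
    u <- sweep(-abar, 2L, a$points[ref, ], FUN = "+")
    v <- sweep(-abar, 2L, b$points[ref, ], FUN = "+")
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosang <- pmax(-1, pmin(1, rowSums(u * v) / (nu * nv)))
    ang <- ang + acos(cosang)
  }
  a3r_deg <- ang * 180 / pi
  a3r_deg[common %in% REFERENCE_LANDMARKS] <- NA_real_

  data.frame(
    patient_id = pair$patient_id, pair = pair$pair_label, landmark = common,
    dxerr_mm = abs(d[, 1]), dyerr_mm = abs(d[, 2]), dzerr_mm = abs(d[, 3]),
    Db_mm = db, Y_mm = y, DX_mm = dx, A3r_deg = a3r_deg,
    DY_mm = dy, DZ_mm = dz, D0_mm = d0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Intraclass correlation per landmark coordinate
#'
#' ICC(3,1) -- two-way mixed effects, single rater, consistency -- computed
#' for each landmark and each scanner axis across patients, treating the
#' repeated digitization trials as raters. This matches the study design of a
#' single observer re-digitizing fixed images.
#'
#' @param cohort long coordinate data.frame or `synthetic_cohort` with at
#'   least 2 patients and 2 trials per patient.
#' @return A data.frame `landmark, axis, icc`.
#' @export
icc_per_coordinate <- function(cohort) {
  df <- as.data.frame(cohort)
  patients <- unique(df$patient_id)
  trials <- unique(df$trial_id)
  if (length(patients) < 2L || length(trials) < 2L) {
    insufficient_data("ICC needs at least 2 patients and 2 trials")
  }
  axes <- c(x = "x_mm", y = "y_mm", z = "z_mm")
  out <- expand.grid(landmark = unique(df$landmark), axis = names(axes),
                     stringsAsFactors = FALSE)
  out$icc <- NA_real_
  for (i in seq_len(nrow(out))) {
    sub <- df[df$landmark == out$landmark[i], c("patient_id", "trial_id", axes[[out$axis[i]]])]
    m <- matrix(NA_real_, length(patients), length(trials),
                dimnames = list(patients, trials))
    m[cbind(match(sub$patient_id, patients), match(sub$trial_id, trials))] <- sub[[3]]
    if (anyNA(m)) {
      insufficient_data(sprintf("incomplete trials for landmark %s", out$landmark[i]))
    }
    out$icc[i] <- icc31(m)
  }
  out
}

#' ICC(3,1) of a subjects-by-raters matrix
#'
#' Two-way mixed model, single measurement, consistency definition:
#' (MSB - MSE) / (MSB + (k - 1) MSE), with mean squares from the two-way
#' ANOVA of subjects and raters.
#'
#' @param m numeric matrix, rows = subjects, columns = raters/trials.
#' @return ICC value in \[-1, 1\].
#' @export
icc31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) insufficient_data("ICC needs >= 2 subjects and >= 2 raters")
  grand <- mean(m)
  ssb <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssb - ssc
  msb <- ssb / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msb + (k - 1) * mse == 0) return(NA_real_)  # all values identical
  (msb - mse) / (msb + (k - 1) * mse)
}

#' Per-landmark summary of error records
#'
#' Mean, sample SD (n-1 denominator) and quartiles (inclusive linear
#' interpolation between order statistics) of the reorientation error,
#' locating error, axis distance and angle sum, mirroring the layout of the
#' study's per-landmark error table.
#'
#' @param records output of [error_records()].
#' @return A data.frame keyed by landmark with columns
#'   `Y_mean, Y_sd, Y_q1, Y_q3, Db_mean, Db_sd, Db_q1, Db_q3, DX_mean,
#'   DX_sd, A3r_mean, A3r_sd`. SD is NA for a single record.
#' @export
summarize_records <- function(records) {
  if (nrow(records) == 0L) abort_class("no records to summarize", "validation_error")
  lms <- unique(records$landmark)
  lms <- lms[order(match(lms, ALL_LANDMARKS))]
  q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
  rows <- lapply(lms, function(lm) {
    r <- records[records$landmark == lm, ]
    data.frame(
      landmark = lm, n = nrow(r),
      Y_mean = mean(r$Y_mm), Y_sd = stats::sd(r$Y_mm),
      Y_q1 = q(r$Y_mm, 0.25), Y_q3 = q(r$Y_mm, 0.75),
      Db_mean = mean(r$Db_mm), Db_sd = stats::sd(r$Db_mm),
      Db_q1 = q(r$Db_mm, 0.25), Db_q3 = q(r$Db_mm, 0.75),
      DX_mean = mean(r$DX_mm), DX_sd = stats::sd(r$DX_mm),
      A3r_mean = if (all(is.na(r$A3r_deg))) NA_real_ else mean(r$A3r_deg, na.rm = TRUE),
      A3r_sd = if (all(is.na(r$A3r_deg))) NA_real_ else stats::sd(r$A3r_deg, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
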