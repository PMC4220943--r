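# Calibration constants for the synthetic cohort.
#
# .axis_locating_error: published per-axis mean absolute coordinate
# differences (mm) between two digitizations of the same landmark, used to
# calibrate the Gaussian placement-noise SDs.
# .axis_distance_target: published per-landmark mean perpendicular distances
# (mm) from the reoriented transverse axis, used to calibrate the template
# geometry of the 15 analysis landmarks.

.axis_locating_error <- local({
  m <- matrix(c(
    0.19, 0.16, 0.14,   # MLWS
    0.32, 0.20, 0.31,   # Na
    0.39, 0.31, 0.38,   # S
    0.30, 0.33, 0.20,   # Ba
    0.27, 0.26, 0.24,   # Ans
    0.24, 0.20, 0.79,   # A
    0.24, 0.25, 0.31,   # Pns
    0.50, 0.17, 0.58,   # Pg
    0.53, 0.17, 0.27,   # Me
    0.55, 0.24, 0.44,   # Gn
    0.33, 0.14, 0.68,   # B
    0.89, 0.38, 0.23,   # OrR
    0.68, 0.34, 0.30,   # OrL
    0.61, 0.46, 0.32,   # PoR
    0.56, 0.50, 0.38,   # PoL
    0.38, 0.25, 0.14,   # CoR
    0.29, 0.31, 0.12,   # CoL
    0.46, 0.56, 0.70,   # GoR
    0.45, 0.45, 0.63    # GoL
  ), ncol = 3, byrow = TRUE)
  dimnames(m) <- list(ALL_LANDMARKS, c("x", "y", "z"))
  m
})

.axis_distance_target <- c(
  Ans = 55.35, A = 61.14, Pns = 47.82, Pg = 120.21, Me = 126.63,
  Gn = 124.70, B = 105.81, OrR = 47.01, OrL = 45.90, PoR = 50.14,
  PoL = 54.43, CoR = 57.98, CoL = 58.80, GoR = 95.37, GoL = 95.14
)

#' Anatomical skull template
#'
#' A fixed 19-landmark template expressed directly in the reoriented frame
#' convention: MLWS at the origin, nasion anterior on the midsagittal plane
#' (y+), basion posteroinferior, and the vertical axis z+ superior. The 15
#' analysis landmarks are placed so that each perpendicular distance from
#' the transverse x axis equals the published per-landmark mean exactly;
#' bilateral landmarks are mirrored across the midsagittal plane in x. The
#' depth split of each distance into y and z (and the transverse offsets of
#' bilateral points) is not constrained by those distances, so plausible
#' adult craniofacial values are fixed here.
#'
#' @return 19 x 3 numeric matrix (mm), rownames [ALL_LANDMARKS].
#' @export
default_template <- function() {
  d <- .axis_distance_target
  # landmark: c(x offset, chosen z, sign of y); y = sy * sqrt(d^2 - z^2)
  place <- function(lm, x, z, sy) c(x, sy * sqrt(d[[lm]]^2 - z^2), z)
  tmpl <- rbind(
    MLWS = c(0, 0, 0),
    Na   = c(0, 72, 3),
    S    = c(0, 4, 3),
    Ba   = c(0, -12, -28),
    Ans  = place("Ans", 0, -27, +1),
    A    = place("A",   0, -36, +1),
    Pns  = place("Pns", 0, -33, +1),
    Pg   = place("Pg",  0, -95, +1),
    Me   = place("Me",  0, -103, +1),
    Gn   = place("Gn",  0, -100, +1),
    B    = place("B",   0, -82, +1),
    OrR  = place("OrR", +33, -18, +1),
    OrL  = place("OrL", -33, -18, +1),
    PoR  = place("PoR", +55, -15, -1),
    PoL  = place("PoL", -55, -15, -1),
    CoR  = place("CoR", +50, -12, -1),
    CoL  = place("CoL", -50, -12, -1),
    GoR  = place("GoR", +45, -88, -1),
    GoL  = place("GoL", -45, -88, -1)
  )
  colnames(tmpl) <- c("x", "y", "z")
  tmpl
}

#' Calibrate placement-noise SD from a mean absolute difference
#'
#' If both placements of a coordinate carry independent Normal(0, sigma^2)
#' noise, their difference is Normal(0, 2 sigma^2) and the expected absolute
#' difference is 2 sigma / sqrt(pi). Inverting gives
#' sigma = mean_abs_diff * sqrt(pi) / 2, the SD at which simulated repeat
#' digitizations reproduce an observed mean absolute per-axis difference.
#'
#' @param mean_abs_diff observed mean absolute difference(s), mm (>= 0).
#' @return Per-axis noise SD(s), mm, same shape as the input.
#' @export
calibrate_axis_noise <- function(mean_abs_diff) {
  stopifnot(all(mean_abs_diff >= 0))
  mean_abs_diff * sqrt(pi) / 2
}

#' Default per-landmark per-axis placement-noise SDs
#'
#' [calibrate_axis_noise()] applied to the published per-axis mean absolute
#' locating errors of all 19 landmarks.
#'
#' @return 19 x 3 matrix of SDs (mm).
#' @export
default_locating_noise <- function() {
  calibrate_axis_noise(.axis_locating_error)
}

#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions: 20 patients, 3 digitization
#' trials per patient, placement noise calibrated to the published per-axis
#' locating errors, and between-patient anatomical variation (global size
#' scatter, per-landmark shape jitter, head positioning) large enough that
#' coordinate reliability is dominated by anatomy, as in the study.
#'
#' @param n_patients number of patients (default 20).
#' @param n_trials digitization trials per patient (default 3; >= 2 needed
#'   for any error analysis).
#' @param template landmark template matrix (default [default_template()]).
#' @param scale_sd SD of the global patient size factor (default 0.03, i.e.
#'   3% of size).
#' @param jitter_sd per-landmark isotropic anatomical jitter SD, mm
#'   (default 2).
#' @param locating_noise per-landmark per-axis placement-noise SD matrix, mm
#'   (default [default_locating_noise()]).
#' @param translation_sd SD of the patient's scanner-position offset per
#'   axis, mm (default 15).
#' @param rotation_sd_deg SD of the patient's head-orientation angle about a
#'   random axis, degrees (default 5).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L, n_trials = 3L,
                          template = default_template(),
                          scale_sd = 0.03, jitter_sd = 2.0,
                          locating_noise = default_locating_noise(),
                          translation_sd = 15, rotation_sd_deg = 5) {
  stopifnot(n_patients >= 1L, n_trials >= 1L,
            scale_sd >= 0, jitter_sd >= 0,
            translation_sd >= 0, rotation_sd_deg >= 0,
            all(locating_noise >= 0))
  if (!all(ALL_LANDMARKS %in% rownames(template))) {
    abort_class("template must contain all 19 landmark names", "validation_error")
  }
  if (!all(ALL_LANDMARKS %in% rownames(locating_noise))) {
    abort_class("locating_noise must cover all 19 landmarks", "validation_error")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_trials = as.integer(n_trials),
         template = template[ALL_LANDMARKS, , drop = FALSE],
         scale_sd = scale_sd, jitter_sd = jitter_sd,
         locating_noise = locating_noise[ALL_LANDMARKS, , drop = FALSE],
         translation_sd = translation_sd, rotation_sd_deg = rotation_sd_deg),
    class = "cohort_config"
  )
}

# Rodrigues rotation matrix about unit axis u by angle theta (radians).
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic digitization cohort
#'
#' Each patient's true anatomy is the template, globally rescaled by a
#' Normal(1, scale_sd) factor, jittered per landmark (isotropic Gaussian,
#' `jitter_sd`), and placed in the scanner by a random rigid motion (rotation
#' of Normal(0, rotation_sd_deg) degrees about a random axis plus a
#' Normal(0, translation_sd) translation per axis). All trials of a patient
#' digitize that same fixed truth; each trial adds independent per-landmark
#' per-axis Gaussian placement noise with the configured SDs. Deterministic
#' for a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @return An object of class `synthetic_cohort`: list with `config`,
#'   `truth` (long data.frame of true landmark positions per patient) and
#'   `trials` (long coordinate data.frame in the [read_landmark_table()]
#'   schema). `as.data.frame()` returns the trials table.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n_lm <- nrow(config$template)
  truth_rows <- vector("list", config$n_patients)
  trial_rows <- vector("list", config$n_patients * config$n_trials)
  k <- 0L
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    s <- 1 + stats::rnorm(1, 0, config$scale_sd)
    anatomy <- config$template * s +
      matrix(stats::rnorm(3L * n_lm, 0, config$jitter_sd), n_lm, 3L)
    R <- rotation_matrix(stats::rnorm(3L),
                         stats::rnorm(1, 0, config$rotation_sd_deg) * pi / 180)
    t_off <- stats::rnorm(3L, 0, config$translation_sd)
    truth <- anatomy %*% t(R) + matrix(t_off, n_lm, 3L, byrow = TRUE)
    dimnames(truth) <- dimnames(config$template)
    truth_rows[[i]] <- data.frame(
      patient_id = pid, landmark = rownames(truth),
      x_mm = truth[, 1], y_mm = truth[, 2], z_mm = truth[, 3],
      row.names = NULL, stringsAsFactors = FALSE)
    for (j in seq_len(config$n_trials)) {
      noise <- matrix(stats::rnorm(3L * n_lm), n_lm, 3L) * config$locating_noise
      pts <- truth + noise
      k <- k + 1L
      trial_rows[[k]] <- data.frame(
        patient_id = pid, trial_id = sprintf("T%d", j),
        landmark = rownames(pts),
        x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(config = config,
         truth = do.call(rbind, truth_rows),
         trials = do.call(rbind, trial_rows)),
    class = "synthetic_cohort"
  )
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) x$trials

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d trials x %d landmarks (%d rows)\n",
              x$config$n_patients, x$config$n_trials,
              nrow(x$config$template), nrow(x$trials)))
  invisible(x)
}
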