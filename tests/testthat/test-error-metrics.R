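make_pair <- function(pts_a, pts_b, patient = "P1") {
  trial_pair(landmark_set(pts_a, patient, "T1"),
             landmark_set(pts_b, patient, "T2"))
}

ref_plus <- function(extra_a, extra_b) {
  base <- axis_aligned_points()
  make_pair(rbind(base, extra_a), rbind(base, extra_b))
}

test_that("locating error is the per-axis absolute difference and 3D distance", {
  base <- axis_aligned_points()
  pair <- make_pair(base, base)
  expect_equal(unname(locating_error(pair, "Na")), c(0, 0, 0, 0))

  pair <- ref_plus(rbind(L = c(0, 0, 0)), rbind(L = c(0.3, 0.4, 0)))
  expect_equal(unname(locating_error(pair, "L")), c(0.3, 0.4, 0, 0.5))

  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(3, 0, 30); b <- rnorm(3, 0, 30)
    pair <- ref_plus(rbind(L = a), rbind(L = b))
    le <- locating_error(pair, "L")
    expect_equal(unname(le[["Db"]]), sqrt(sum((a - b)^2)), tolerance = 1e-12)
    expect_equal(le[["Db"]]^2, sum(le[1:3]^2), tolerance = 1e-9)
  }
  expect_error(locating_error(pair, "Nope"), class = "missing_landmark")
})

test_that("MLWS reorientation error is exactly zero", {
  set.seed(22)
  for (i in 1:10) {
    pair <- trial_pair(random_trial(trial = "T1"), random_trial(trial = "T2"))
    expect_identical(reorientation_error(pair, "MLWS"), 0)
  }
})

test_that("identical reference landmarks make Y equal Db", {
  set.seed(23)
  base <- axis_aligned_points()
  for (i in 1:20) {
    a <- rbind(base, L = rnorm(3, 0, 40))
    b <- rbind(base, L = rnorm(3, 0, 40))
    pair <- make_pair(a, b)
    expect_equal(reorientation_error(pair, "L"),
                 unname(locating_error(pair, "L")[["Db"]]), tolerance = 1e-9)
  }
})

test_that("reference jitter alone creates reorientation error, matching the dual-path oracle", {
  set.seed(24)
  for (i in 1:15) {
    a <- rbind(axis_aligned_points(), L = c(10, 40, -20))
    b <- a
    b[c("Na", "S", "Ba", "MLWS"), ] <-
      b[c("Na", "S", "Ba", "MLWS"), ] + matrix(rnorm(12, 0, 0.5), 4, 3)
    pair <- make_pair(a, b)
    expect_equal(unname(locating_error(pair, "L")[["Db"]]), 0)
    y <- reorientation_error(pair, "L")
    expect_gt(y, 0)
    oracle <- sqrt(sum((oracle_reoriented(pair$trial_a)["L", ] -
                        oracle_reoriented(pair$trial_b)["L", ])^2))
    expect_equal(y, oracle, tolerance = 1e-8)
  }
})

test_that("Y, Db, DX, A3r are symmetric in trial order and rigid-motion invariant", {
  set.seed(25)
  a <- random_trial(n_extra = 2, trial = "T1")
  b <- random_trial(n_extra = 2, trial = "T2")
  pair <- trial_pair(a, b)
  rev <- trial_pair(b, a)
  for (lm in c("L1", "L2")) {
    expect_equal(reorientation_error(pair, lm), reorientation_error(rev, lm))
    expect_equal(locating_error(pair, lm)[["Db"]], locating_error(rev, lm)[["Db"]])
    expect_equal(dx_metric(pair, lm), dx_metric(rev, lm))
    expect_equal(a3r(pair, lm), a3r(rev, lm))
  }
  R <- random_rotation(); t <- runif(3, -80, 80)
  moved <- trial_pair(landmark_set(apply_rigid(a$points, R, t), "P1", "T1"),
                      landmark_set(apply_rigid(b$points, R, t), "P1", "T2"))
  for (lm in c("L1", "L2")) {
    expect_equal(reorientation_error(moved, lm), reorientation_error(pair, lm),
                 tolerance = 1e-9)
    expect_equal(locating_error(moved, lm)[["Db"]],
                 locating_error(pair, lm)[["Db"]], tolerance = 1e-9)
    expect_equal(dx_metric(moved, lm), dx_metric(pair, lm), tolerance = 1e-9)
    expect_equal(a3r(moved, lm), a3r(pair, lm), tolerance = 1e-9)
  }
})

test_that("A3r sums the three reference angles at the averaged landmark", {
  base <- axis_aligned_points()
  pair <- make_pair(rbind(base, L = c(20, -30, 10)),
                    rbind(base, L = c(20, -30, 10)))
  expect_lt(a3r(pair, "L"), 1e-5)  # acos roundoff only

  # averaged landmark at the origin; S swings by 90 degrees, Na and Ba fixed
  a <- rbind(MLWS = c(5, 5, 5), Na = c(0, 60, 0), S = c(1, 0, 0),
             Ba = c(0, -10, -30), L = c(3, 1, -2))
  b <- a; b["S", ] <- c(0, 1, 0); b["L", ] <- -a["L", ]
  expect_equal(a3r(make_pair(a, b), "L"), 90, tolerance = 1e-9)

  # random configurations against an atan2-based oracle
  set.seed(26)
  for (i in 1:15) {
    pa <- random_trial(n_extra = 1, trial = "T1")
    pb <- random_trial(n_extra = 1, trial = "T2")
    pair <- trial_pair(pa, pb)
    abar <- (pa$points["L1", ] + pb$points["L1", ]) / 2
    oracle <- 0
    for (ref in c("Na", "S", "Ba")) {
      u <- pa$points[ref, ] - abar; v <- pb$points[ref, ] - abar
      cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      oracle <- oracle + atan2(sqrt(sum(cr^2)), sum(u * v))
    }
    expect_equal(a3r(pair, "L1"), oracle * 180 / pi, tolerance = 1e-9)
  }

  # degenerate: averaged landmark coincides with a reference placement
  a <- axis_aligned_points()
  a <- rbind(a, L = a["Na", ])
  expect_error(a3r(make_pair(a, a), "L"), class = "degenerate_angle")
})

test_that("DX is the point-to-line distance from the averaged landmark to the averaged x axis", {
  base <- axis_aligned_points()
  pair <- make_pair(base, base)
  expect_equal(dx_metric(pair, "MLWS"), 0)

  a <- rbind(base, L = c(0, 2, 0) + c(7, 3, 4))
  expect_equal(dx_metric(make_pair(a, a), "L"), 5, tolerance = 1e-12)

  set.seed(27)
  for (i in 1:15) {
    pa <- random_trial(n_extra = 1, trial = "T1")
    pb <- random_trial(n_extra = 1, trial = "T2")
    pair <- trial_pair(pa, pb)
    avg_pts <- (pa$points + pb$points) / 2
    avg <- landmark_set(avg_pts)
    f <- build_reference_frame(avg)
    # point-line distance oracle: line through averaged MLWS along averaged x axis
    d <- avg_pts["L1", ] - f$origin
    perp <- d - sum(d * f$x_axis) * f$x_axis
    expect_equal(dx_metric(pair, "L1"), sqrt(sum(perp^2)), tolerance = 1e-9)
  }
})

test_that("mean Y does not decrease as reference-landmark noise grows", {
  mean_y <- vapply(c(0.5, 1, 2), function(scale) {
    noise <- default_locating_noise()
    noise[REFERENCE_LANDMARKS, ] <- noise[REFERENCE_LANDMARKS, ] * scale
    cfg <- cohort_config(n_patients = 200L, n_trials = 2L,
                         locating_noise = noise)
    rec <- error_records(generate_cohort(cfg, seed = 28))
    mean(rec$Y_mm[!(rec$landmark %in% REFERENCE_LANDMARKS)])
  }, numeric(1))
  expect_true(all(diff(mean_y) >= 0))
})

test_that("ICC(3,1) behaves at its analytic anchors", {
  # zero within-subject variance -> 1
  m <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_equal(icc31(m), 1)

  # hand-computed two-way fixture, checked against aov mean squares
  m2 <- matrix(c(1, 2, 3, 4,
                 2, 4, 5, 7,
                 1.5, 3, 4.5, 6), 4, 3)
  d <- data.frame(y = as.vector(m2),
                  subj = factor(rep(1:4, 3)), rater = factor(rep(1:3, each = 4)))
  ms <- summary(stats::aov(y ~ subj + rater, d))[[1]][, "Mean Sq"]
  expect_equal(icc31(m2), (ms[1] - ms[3]) / (ms[1] + 2 * ms[3]), tolerance = 1e-12)

  # pure noise: ICC near zero at n = 200
  set.seed(29)
  expect_lt(abs(icc31(matrix(rnorm(200 * 3), 200, 3))), 0.2)

  expect_error(icc31(matrix(1:3, 3, 1)), class = "insufficient_data")
})

test_that("per-coordinate ICC exceeds 0.99 when anatomy dwarfs placement noise", {
  # between-patient SD 10 mm, within-trial SD 0.3 mm
  set.seed(30)
  tmpl <- default_template()
  noise <- default_locating_noise(); noise[] <- 0.3
  cfg <- cohort_config(n_patients = 20L, n_trials = 3L, template = tmpl,
                       scale_sd = 0, jitter_sd = 10, locating_noise = noise,
                       translation_sd = 0, rotation_sd_deg = 0)
  icc <- icc_per_coordinate(generate_cohort(cfg, seed = 30))
  expect_true(all(icc$icc > 0.99))
  expect_error(icc_per_coordinate(
    as.data.frame(generate_cohort(cohort_config(n_patients = 1L), seed = 1))),
    class = "insufficient_data")
})

test_that("record summaries use sample SD and inclusive quartiles", {
  rec <- data.frame(patient_id = "P1", pair = c("T1-T2", "T1-T3", "T2-T3", "T1-T2"),
                    landmark = "Me",
                    dxerr_mm = 0, dyerr_mm = 0, dzerr_mm = 0,
                    Db_mm = c(1, 2, 3, 4), Y_mm = c(1, 2, 3, 4),
                    DX_mm = 100, A3r_deg = 0.5,
                    DY_mm = 0, DZ_mm = 0, D0_mm = 0)
  s <- summarize_records(rec)
  expect_equal(s$Y_mean, 2.5)
  expect_equal(s$Y_sd, sd(c(1, 2, 3, 4)))
  expect_equal(s$Y_q1, 1.75)
  expect_equal(s$Y_q3, 3.25)

  one <- rec[1, ]
  s1 <- summarize_records(one)
  expect_equal(s1$Y_mean, 1)
  expect_true(is.na(s1$Y_sd))

  set.seed(31)
  full <- summarize_records(error_records(
    generate_cohort(cohort_config(n_patients = 4L), seed = 31)))
  mlws <- full[full$landmark == "MLWS", ]
  expect_equal(mlws$Y_mean, 0)
  expect_equal(mlws$Y_sd, 0)
  expect_true(is.na(mlws$A3r_mean))
})
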