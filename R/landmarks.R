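#' Landmark vocabulary
#'
#' The 19 craniofacial landmarks used throughout the package, in canonical
#' order. `MLWS` (midpoint between the posterior points of the bilateral
#' lesser wings of the sphenoid) together with nasion (`Na`), sella (`S`) and
#' basion (`Ba`) defines the anatomical reference frame; the remaining 15 are
#' the commonly used orthodontic landmarks analysed for superimposition error.
#'
#' @format Character vectors.
#' @name landmark_names
NULL

#' @rdname landmark_names
#' @export
ALL_LANDMARKS <- c(
  "MLWS", "Na", "S", "Ba",
  "Ans", "A", "Pns", "Pg", "Me", "Gn", "B",
  "OrR", "OrL", "PoR", "PoL", "CoR", "CoL", "GoR", "GoL"
)

#' @rdname landmark_names
#' @export
REFERENCE_LANDMARKS <- c("MLWS", "Na", "S", "Ba")

#' @rdname landmark_names
#' @export
ANALYSIS_LANDMARKS <- setdiff(ALL_LANDMARKS, REFERENCE_LANDMARKS)

#' One digitization trial of one patient
#'
#' A `landmark_set` holds the named 3D points (mm, scanner coordinates) that
#' one digitization session produced for one patient.
#'
#' @param points numeric matrix with one row per landmark (rownames are the
#'   landmark names) and columns x, y, z in mm. A data.frame is accepted.
#' @param patient_id,trial_id identifiers (e.g. `"P01"`, `"T1"`).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, patient_id = "P1", trial_id = "T1") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    abort_class("landmark points must have 3 columns (x, y, z)", "validation_error")
  }
  if (is.null(rownames(points)) || anyDuplicated(rownames(points))) {
    abort_class("landmark points need unique rownames naming the landmarks",
                "validation_error")
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    abort_class("all landmark coordinates must be finite", "validation_error")
  }
  colnames(points) <- c("x", "y", "z")
  structure(
    list(patient_id = patient_id, trial_id = trial_id, points = points),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> patient %s, trial %s, %d landmarks\n",
              x$patient_id, x$trial_id, nrow(x$points)))
  invisible(x)
}

landmark_point <- function(trial, landmark) {
  if (!landmark %in% rownames(trial$points)) {
    missing_landmark(sprintf("landmark '%s' absent from trial %s of patient %s",
                             landmark, trial$trial_id, trial$patient_id))
  }
  trial$points[landmark, ]
}

require_reference_landmarks <- function(trial) {
  missing <- setdiff(REFERENCE_LANDMARKS, rownames(trial$points))
  if (length(missing)) {
    missing_landmark(sprintf(
      "trial %s of patient %s lacks reference landmark(s): %s",
      trial$trial_id, trial$patient_id, paste(missing, collapse = ", ")))
  }
  invisible(trial)
}

#' Two digitization trials of the same patient
#'
#' The unit on which every error statistic is defined: two repeated
#' digitizations of the same image by the same observer.
#'
#' @param trial_a,trial_b `landmark_set` objects sharing a patient.
#' @param pair_label label such as `"T1-T2"`; derived from the trial ids when
#'   omitted.
#' @return An object of class `trial_pair`.
#' @export
trial_pair <- function(trial_a, trial_b, pair_label = NULL) {
  stopifnot(inherits(trial_a, "landmark_set"), inherits(trial_b, "landmark_set"))
  if (!identical(trial_a$patient_id, trial_b$patient_id)) {
    abort_class("both trials of a pair must belong to the same patient",
                "validation_error")
  }
  if (is.null(pair_label)) {
    pair_label <- paste(trial_a$trial_id, trial_b$trial_id, sep = "-")
  }
  structure(
    list(patient_id = trial_a$patient_id, trial_a = trial_a,
         trial_b = trial_b, pair_label = pair_label),
    class = "trial_pair"
  )
}

#' Read or write a landmark coordinate table
#'
#' The interchange format is a plain CSV with columns
#' `patient_id,trial_id,landmark,x_mm,y_mm,z_mm` (UTF-8, `.` decimal
#' separator), one row per landmark per digitization trial. Reoriented tables
#' carry an extra `frame` column naming the trial whose reference landmarks
#' defined the frame.
#'
#' @param path file path.
#' @param df data.frame with at least the schema columns above.
#' @return `read_landmark_table` returns the data.frame;
#'   `write_landmark_table` returns `path` invisibly.
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "trial_id", "landmark", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort_class(sprintf("landmark table %s lacks column(s): %s",
                        path, paste(missing, collapse = ", ")),
                "validation_error")
  }
  df
}

#' @rdname read_landmark_table
#' @export
write_landmark_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a long coordinate table into landmark_set objects, a list indexed by
# patient then trial (order of first appearance).
table_to_landmark_sets <- function(df) {
  out <- list()
  for (pid in unique(df$patient_id)) {
    dfp <- df[df$patient_id == pid, , drop = FALSE]
    trials <- list()
    for (tid in unique(dfp$trial_id)) {
      dft <- dfp[dfp$trial_id == tid, , drop = FALSE]
      pts <- as.matrix(dft[, c("x_mm", "y_mm", "z_mm")])
      rownames(pts) <- dft$landmark
      trials[[as.character(tid)]] <- landmark_set(pts, pid, as.character(tid))
    }
    out[[as.character(pid)]] <- trials
  }
  out
}

landmark_sets_to_table <- function(sets) {
  rows <- lapply(sets, function(ls) {
    data.frame(patient_id = ls$patient_id, trial_id = ls$trial_id,
               landmark = rownames(ls$points),
               x_mm = ls$points[, 1], y_mm = ls$points[, 2],
               z_mm = ls$points[, 3], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
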