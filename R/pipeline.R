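# Pipeline stages behind the analysis drivers: simulate -> reorient ->
# metrics -> regress. Each stage is a plain function over data.frames so the
# numbered scripts under analysis/ stay thin.

#' Simulate a cohort and optionally write the coordinate CSV
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (deterministic output per seed).
#' @param path optional CSV path; written in the [read_landmark_table()]
#'   schema when given.
#' @return The long coordinate data.frame, invisibly when written.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L, path = NULL) {
  if (config$n_trials < 2L) {
    warning("n_trials < 2: downstream error metrics need repeated digitizations",
            call. = FALSE)
  }
  df <- as.data.frame(generate_cohort(config, seed = seed))
  if (!is.null(path)) {
    write_landmark_table(df, path)
    return(invisible(df))
  }
  df
}

#' Reorient every trial of a coordinate table
#'
#' Builds each trial's own 4-point frame and expresses its landmarks in it.
#' Trials whose reference landmarks are missing or degenerate are skipped
#' with a warning naming the patient and trial; the remaining trials are
#' still processed.
#'
#' @param df long coordinate data.frame.
#' @param tol degeneracy tolerance, mm.
#' @return Data.frame in the same schema plus a `frame` column naming the
#'   trial whose reference landmarks defined the frame.
#' @export
reorient_table <- function(df, tol = 1e-6) {
  sets <- table_to_landmark_sets(df)
  out <- list()
  for (pid in names(sets)) {
    for (tid in names(sets[[pid]])) {
      trial <- sets[[pid]][[tid]]
      res <- tryCatch({
        frame <- build_reference_frame(trial, tol)
        reorient(trial, frame)
      }, fourpoint_error = function(e) {
        warning(sprintf("skipping patient %s trial %s: %s",
                        pid, tid, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      tab <- landmark_sets_to_table(list(res))
      tab$frame <- tid
      out[[length(out) + 1L]] <- tab
    }
  }
  if (!length(out)) abort_class("no trial could be reoriented", "validation_error")
  do.call(rbind, out)
}

#' Compute all error tables for a cohort
#'
#' @param df long coordinate data.frame (>= 2 trials per patient).
#' @return `list(records, summary, icc)`: the per-(patient, pair, landmark)
#'   [error_records()], their per-landmark [summarize_records()] table, and
#'   the [icc_per_coordinate()] table.
#' @export
metrics_tables <- function(df) {
  records <- error_records(df)
  list(records = records,
       summary = summarize_records(records),
       icc = icc_per_coordinate(df))
}

#' Fit the error model and assemble the regression report
#'
#' Assembles regression rows from the error records, fits all four scopes
#' (outlier screening + stepwise selection per scope), and returns a plain
#' list ready for JSON serialization, alongside a per-row kept/excluded flag
#' table for the Total scope.
#'
#' @param records output of [error_records()].
#' @param ... passed to [fit_all_scopes()].
#' @return `list(fits, report, flags)`.
#' @export
regression_report <- function(records, ...) {
  rows <- assemble_rows(records)
  fits <- fit_all_scopes(rows, ...)
  report <- lapply(fits, function(f) {
    if (inherits(f, "condition")) {
      return(list(error = conditionMessage(f)))
    }
    list(scope = f$scope,
         predictors = as.list(f$predictors),
         B = as.list(f$coefficients),
         p = as.list(f$p_values),
         VIF = as.list(f$vif),
         intercept = f$intercept,
         adjusted_R2 = f$adj_r2,
         n = f$n, n_excluded = f$n_excluded)
  })
  scr <- exclude_outliers(rows)
  flags <- rows[, c("patient_id", "pair", "landmark", "Y")]
  m <- mean(rows$Y); s <- stats::sd(rows$Y)
  flags$kept <- if (is.finite(s) && s > 0) abs(rows$Y - m) <= 3 * s else TRUE
  list(fits = fits, report = report, flags = flags)
}

#' Write a regression report as JSON
#'
#' @param report the `report` element of [regression_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
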