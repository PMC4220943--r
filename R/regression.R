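#' Assemble the regression dataset
#'
#' One observation per (patient, trial pair, non-reference landmark): the
#' response Y (reorientation error) plus the candidate predictors Db, DX,
#' A3r and the additional averaged-landmark geometry DY, DZ, D0. The four
#' reference landmarks (MLWS, Na, S, Ba) are excluded: only the 15 commonly
#' used orthodontic landmarks contribute rows.
#'
#' @param records output of [error_records()].
#' @return A data.frame `patient_id, pair, landmark, Y, Db, DX, A3r, DY,
#'   DZ, D0`.
#' @export
assemble_rows <- function(records) {
  r <- records[records$landmark %in% ANALYSIS_LANDMARKS, , drop = FALSE]
  out <- data.frame(
    patient_id = r$patient_id, pair = r$pair, landmark = r$landmark,
    Y = r$Y_mm, Db = r$Db_mm, DX = r$DX_mm, A3r = r$A3r_deg,
    DY = r$DY_mm, DZ = r$DZ_mm, D0 = r$D0_mm,
    row.names = NULL, stringsAsFactors = FALSE
  )
  num <- c("Y", "Db", "DX", "A3r", "DY", "DZ", "D0")
  if (!all(vapply(out[num], function(x) all(is.finite(x)), logical(1)))) {
    abort_class("non-finite value in regression rows", "validation_error")
  }
  out
}

#' Exclude response outliers
#'
#' Single-pass rule: rows whose response lies more than `k` sample standard
#' deviations from the scope mean are removed before fitting. When the SD is
#' zero (all responses equal) nothing is excluded.
#'
#' @param rows regression rows from [assemble_rows()] (>= 10 rows).
#' @param k SD multiple (default 3).
#' @param response response column name.
#' @return `list(rows = kept data.frame, n_excluded = count)`.
#' @export
exclude_outliers <- function(rows, k = 3, response = "Y") {
  if (nrow(rows) < 10L) insufficient_data("outlier screening needs >= 10 rows")
  y <- rows[[response]]
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) {
    return(list(rows = rows, n_excluded = 0L))
  }
  keep <- abs(y - mean(y)) <= k * s
  list(rows = rows[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Construct a regression result
#'
#' Container for a fitted (or externally reported) error model: per-predictor
#' slopes B in mm per predictor unit, p-values, variance inflation factors,
#' the intercept, and fit summaries. The intercept is always estimated by
#' [stepwise_fit()] but flagged: published versions of this model report none,
#' so it is not comparable across systems.
#'
#' @param scope scope label (`"T1-T2"`, ..., `"Total"`).
#' @param coefficients named numeric vector of slopes B for the selected
#'   predictors (may be empty for a null model).
#' @param p_values,vif named numeric vectors aligned with `coefficients`.
#' @param intercept,adj_r2,r2,n,n_excluded scalars (NA when unknown).
#' @return An object of class `regression_result`.
#' @export
regression_result <- function(scope, coefficients, p_values = NULL, vif = NULL,
                              intercept = NA_real_, adj_r2 = NA_real_,
                              r2 = NA_real_, n = NA_integer_,
                              n_excluded = NA_integer_) {
  coefficients <- unlist(coefficients)
  structure(
    list(scope = scope, predictors = names(coefficients),
         coefficients = coefficients, p_values = p_values, vif = vif,
         intercept = intercept, adj_r2 = adj_r2, r2 = r2,
         n = n, n_excluded = n_excluded),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> scope %s, n = %s (%s outliers excluded)\n",
              x$scope, x$n, x$n_excluded))
  if (length(x$predictors) == 0L) {
    cat("  no predictor met the entry threshold\n")
  } else {
    tab <- data.frame(B = x$coefficients,
                      p = if (is.null(x$p_values)) NA else round(x$p_values, 3),
                      VIF = if (is.null(x$vif)) NA else x$vif)
    print(tab)
  }
  cat(sprintf("  intercept %.4g (not comparable to published model), adj R^2 %.4g\n",
              x$intercept, x$adj_r2))
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j comes from regressing predictor j on
#' the other predictors. A single predictor has VIF 1 by convention.
#'
#' @param data data.frame holding the predictor columns.
#' @param predictors character vector of column names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif_values <- function(data, predictors) {
  if (length(predictors) == 1L) {
    return(stats::setNames(1, predictors))
  }
  vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    fit <- stats::lm(stats::reformulate(others, response = p), data = data)
    r2 <- summary(fit)$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

#' Stepwise multiple linear regression of the reorientation error
#'
#' Forward-entry / backward-removal stepwise ordinary least squares: at each
#' step the not-yet-selected candidate with the smallest coefficient p-value
#' enters if p < `entry`; selected predictors whose p-value rises above
#' `removal` are dropped. Iteration stops when no candidate can enter, or
#' when the model fits the response to numerical precision (a perfect fit
#' leaves nothing for further candidates to explain).
#'
#' @param rows regression rows (outliers already excluded).
#' @param candidates candidate predictor column names (no duplicates).
#' @param response response column (default `"Y"`).
#' @param entry,removal p-value thresholds (entry 0.05, removal 0.10 --
#'   the stepwise convention of mainstream statistics packages).
#' @param scope label stored in the result.
#' @param n_excluded outlier count stored in the result.
#' @return A [regression_result()]; empty predictor set when no candidate
#'   meets the entry threshold.
#' @export
stepwise_fit <- function(rows, candidates = c("Db", "DX", "A3r", "DY", "DZ", "D0"),
                         response = "Y", entry = 0.05, removal = 0.10,
                         scope = "Total", n_excluded = NA_integer_) {
  if (anyDuplicated(candidates)) {
    collinearity_error("duplicated candidate predictor: design matrix rank-deficient")
  }
  if (length(candidates) < 1L) {
    abort_class("stepwise selection needs at least one candidate", "validation_error")
  }
  missing <- setdiff(c(response, candidates), names(rows))
  if (length(missing)) {
    abort_class(paste("missing column(s):", paste(missing, collapse = ", ")),
                "validation_error")
  }
  if (!(entry <= removal)) {
    abort_class("entry threshold must not exceed removal threshold",
                "validation_error")
  }
  if (nrow(rows) < 10L * length(candidates)) {
    insufficient_data(sprintf(
      "stepwise fit needs >= %d rows for %d candidates (got %d)",
      10L * length(candidates), length(candidates), nrow(rows)))
  }

  y_sd <- stats::sd(rows[[response]])
  sigma_tol <- 1e-8 * (y_sd + .Machine$double.eps)

  coef_p <- function(predictors, target) {
    # p-value of `target`'s coefficient in the OLS of response on `predictors`
    fit <- stats::lm(stats::reformulate(predictors, response = response),
                     data = rows)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      collinearity_error("rank-deficient design matrix during stepwise step")
    }
    sm <- suppressWarnings(summary(fit))$coefficients
    list(p = sm[target, "Pr(>|t|)"], fit = fit)
  }

  selected <- character(0)
  for (iter in seq_len(10L * length(candidates))) {
    remaining <- setdiff(candidates, selected)
    if (length(selected)) {
      cur <- stats::lm(stats::reformulate(selected, response = response),
                       data = rows)
      if (suppressWarnings(summary(cur))$sigma < sigma_tol) break  # perfect fit
    }
    if (!length(remaining)) break
    ps <- vapply(remaining, function(cand) {
      coef_p(c(selected, cand), cand)$p
    }, numeric(1))
    best <- remaining[which.min(ps)]
    if (!is.finite(min(ps)) || min(ps) >= entry) break
    selected <- c(selected, best)
    # backward pass
    repeat {
      if (length(selected) == 0L) break
      fit <- stats::lm(stats::reformulate(selected, response = response),
                       data = rows)
      sm <- suppressWarnings(summary(fit))$coefficients
      pv <- sm[selected, "Pr(>|t|)", drop = TRUE]
      if (max(pv) <= removal) break
      worst <- selected[which.max(pv)]
      selected <- setdiff(selected, worst)
      if (identical(worst, best)) break  # guard against entry/removal cycling
    }
  }

  if (length(selected) == 0L) {
    return(regression_result(scope, stats::setNames(numeric(0), character(0)),
                             p_values = numeric(0), vif = numeric(0),
                             intercept = mean(rows[[response]]),
                             adj_r2 = 0, r2 = 0,
                             n = nrow(rows), n_excluded = n_excluded))
  }

  fit <- stats::lm(stats::reformulate(selected, response = response), data = rows)
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  regression_result(
    scope,
    cf[selected],
    p_values = sm$coefficients[selected, "Pr(>|t|)", drop = TRUE],
    vif = vif_values(rows, selected),
    intercept = unname(cf[["(Intercept)"]]),
    adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
    n = nrow(rows), n_excluded = n_excluded
  )
}

#' Linear marginal effect of a selected predictor
#'
#' The model is linear, so a change of `delta` units in one predictor changes
#' the predicted reorientation error by B * delta mm, independent of the
#' intercept and of the other predictors.
#'
#' @param result a [regression_result()].
#' @param predictor predictor name (must be in the model).
#' @param delta change in predictor units (mm for Db/DX, degrees for A3r).
#' @return Predicted change in reorientation error, mm.
#' @export
predict_marginal <- function(result, predictor, delta) {
  stopifnot(inherits(result, "regression_result"))
  if (!predictor %in% names(result$coefficients)) {
    unknown_predictor(sprintf("predictor '%s' is not in the %s model",
                              predictor, result$scope))
  }
  unname(result$coefficients[[predictor]] * delta)
}

#' Fit the error model per trial pair and pooled
#'
#' Outlier exclusion and stepwise selection run independently for each of
#' the three trial-pair scopes (T1-T2, T1-T3, T2-T3) and once on the pooled
#' rows ("Total"). A scope absent from the data yields a captured
#' `insufficient_data` condition in its slot rather than aborting the rest.
#'
#' @param rows regression rows from [assemble_rows()].
#' @param ... passed to [stepwise_fit()] (candidates, thresholds).
#' @param k outlier SD multiple.
#' @return Named list of [regression_result()] (or condition objects for
#'   missing scopes): `"T1-T2", "T1-T3", "T2-T3", "Total"`.
#' @export
fit_all_scopes <- function(rows, ..., k = 3) {
  scopes <- c("T1-T2", "T1-T3", "T2-T3")
  fit_one <- function(sub, label) {
    scr <- exclude_outliers(sub, k = k)
    stepwise_fit(scr$rows, ..., scope = label, n_excluded = scr$n_excluded)
  }
  out <- lapply(scopes, function(sc) {
    sub <- rows[rows$pair == sc, , drop = FALSE]
    if (nrow(sub) == 0L) {
      tryCatch(insufficient_data(sprintf("no rows for scope %s", sc)),
               insufficient_data = function(e) e)
    } else {
      fit_one(sub, sc)
    }
  })
  names(out) <- scopes
  out$Total <- fit_one(rows, "Total")
  out
}
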