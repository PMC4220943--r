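#!/usr/bin/env Rscript
# Stage 4: stepwise error-model regression per trial-pair scope and pooled.
#
# Assembles one observation per (patient, pair, analysis landmark), screens
# response outliers beyond 3 SD, runs forward/backward stepwise OLS with the
# full candidate set {Db, DX, A3r, DY, DZ, D0}, and writes the report JSON
# plus the kept/excluded row flags.

suppressPackageStartupMessages({
  library(fourpoint)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--dir", type = "character", default = "results")
)))

records <- utils::read.csv(file.path(opts$dir, "error_records.csv"),
                           stringsAsFactors = FALSE)
rep <- regression_report(records)

write_regression_json(rep$report, file.path(opts$dir, "regression_report.json"))
utils::write.csv(rep$flags, file.path(opts$dir, "regression_row_flags.csv"),
                 row.names = FALSE)

for (scope in names(rep$fits)) {
  f <- rep$fits[[scope]]
  if (inherits(f, "condition")) {
    cat(scope, ": ", conditionMessage(f), "\n", sep = "")
  } else {
    cat(sprintf("%s: predictors {%s}, adj R^2 %.3f, n %d (%d excluded)\n",
                scope, paste(f$predictors, collapse = ", "),
                f$adj_r2, f$n, f$n_excluded))
  }
}
cat("wrote regression_report.json, regression_row_flags.csv\n")
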