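# Classed error conditions used across the package. Each scientific failure
# mode gets its own class so callers (and tests) can distinguish, e.g., an
# unusable reference configuration from a plain validation error.

abort_class <- function(message, class) {
  stop(structure(
    class = c(class, "fourpoint_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

degenerate_frame <- function(message) abort_class(message, "degenerate_frame")
missing_landmark <- function(message) abort_class(message, "missing_landmark")
degenerate_angle <- function(message) abort_class(message, "degenerate_angle")
insufficient_data <- function(message) abort_class(message, "insufficient_data")
collinearity_error <- function(message) abort_class(message, "collinearity_error")
unknown_predictor <- function(message) abort_class(message, "unknown_predictor")
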