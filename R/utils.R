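# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
stop_methregion <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "methregion_error"), ...)
}

warn_methregion <- function(message, class, ...) {
  rlang::warn(message, class = c(class, "methregion_warning"), ...)
}

# Check that `x` is a single finite number.
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_methregion(sprintf("`%s` must be a single finite number.", name),
                    "methregion_bad_argument")
  }
  invisible(x)
}

# Orientation switch used everywhere a pre/post difference is formed.
check_orientation <- function(orientation) {
  match.arg(orientation, c("pre_minus_post", "post_minus_pre"))
}

orientation_sign <- function(orientation) {
  if (check_orientation(orientation) == "pre_minus_post") 1 else -1
}
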