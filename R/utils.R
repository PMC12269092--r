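# Internal argument checks shared across modules.

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "lakephoto_invalid_argument")
  }
  invisible(x)
}

stop_if_not_positive <- function(x, name) {
  stop_if_not_scalar_number(x, name)
  if (x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x),
          class = "lakephoto_invalid_argument")
  }
  invisible(x)
}

abort_invalid <- function(msg) {
  abort(msg, class = "lakephoto_invalid_argument")
}

abort_insufficient <- function(msg) {
  abort(msg, class = "lakephoto_insufficient_data")
}

# Trapezoidal integral of y over x (both numeric, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Derive a stream-specific sub-seed from a master seed; stays below 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 1000003L
}

SECONDS_PER_MONTH <- 86400 * 30.44
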