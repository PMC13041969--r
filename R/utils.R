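# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
nm_error <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(paste0("neuromidi_", class), "neuromidi_error", "error", "condition"),
    list(message = message, call = call)
  )
}

nm_stop <- function(class, fmt, ...) {
  stop(nm_error(class, sprintf(fmt, ...), call = sys.call(-1)))
}

# Round to nearest integer, ties away from zero (base round() is banker's).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards
# so library functions never leave hidden global randomness behind.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    nm_stop("bad_seed", "seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}
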