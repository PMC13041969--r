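# Pitch mapping: musical scale definitions, the injective unit->pitch
# assignment ("one pitch per neuron", the auditory analog of anatomical
# pseudocolor), and the log-rate->pitch map used for rhythm tracks.

#' Define a musical scale
#'
#' A scale is a root pitch plus strictly increasing semitone offsets within
#' one octave. Pitches outside the listed degrees are never emitted when the
#' scale is active; the default pentatonic restriction keeps concurrently
#' sounding units from clashing.
#'
#' @param root_pitch Integer MIDI pitch 0-127 of scale degree 0 (default 48,
#'   the C below middle C).
#' @param degrees Strictly increasing integer semitone offsets, each in
#'   0-11. Default `c(0, 2, 4, 7, 9)`: the major pentatonic scale.
#' @return An object of class `scale_def`.
#' @examples
#' scale_def()                    # C major pentatonic rooted at 48
#' scale_def(60, c(0, 3, 5, 7, 10)) # minor pentatonic on middle C
#' @export
scale_def <- function(root_pitch = 48L, degrees = c(0L, 2L, 4L, 7L, 9L)) {
  root_pitch <- as.integer(root_pitch)
  degrees <- as.integer(degrees)
  if (is.na(root_pitch) || root_pitch < 0L || root_pitch > 127L) {
    nm_stop("pitch_range", "root_pitch must be in [0, 127]")
  }
  if (length(degrees) == 0L || anyNA(degrees) ||
      any(degrees < 0L | degrees > 11L) || any(diff(degrees) <= 0L)) {
    nm_stop("bad_scale", "degrees must be strictly increasing integers in [0, 11]")
  }
  structure(list(root_pitch = root_pitch, degrees = degrees), class = "scale_def")
}

#' @export
print.scale_def <- function(x, ...) {
  cat(sprintf("<scale_def> root %d, degrees (%s)\n",
              x$root_pitch, paste(x$degrees, collapse = ", ")))
  invisible(x)
}

#' Pitch of the i-th scale degree
#'
#' Degree `index` (0-based) maps to
#' `root + 12 * floor(index / k) + degrees[index mod k]` where `k` is the
#' number of degrees per octave, i.e. indices walk up the scale, wrapping
#' into the next octave every `k` steps.
#'
#' @param scale A [scale_def()].
#' @param index Non-negative integer degree index (vectorized).
#' @return Integer MIDI pitch(es) in \[0, 127\].
#' @examples
#' scale_pitch(scale_def(), 0:5) # 48 50 52 55 57 60
#' @export
scale_pitch <- function(scale, index) {
  stopifnot(inherits(scale, "scale_def"))
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L)) nm_stop("bad_index", "index must be non-negative")
  k <- length(scale$degrees)
  p <- scale$root_pitch + 12L * (index %/% k) + scale$degrees[(index %% k) + 1L]
  if (any(p > 127L)) {
    nm_stop("pitch_range", "scale degree index %d maps to pitch %d > 127",
            index[which(p > 127L)[1L]], max(p))
  }
  p
}

# All pitches of the scale representable in [0, 127], for snapping.
scale_pitch_set <- function(scale) {
  octaves <- seq(scale$root_pitch %% 12L - 12L, 132L, by = 12L)
  p <- as.integer(outer(scale$degrees, octaves, `+`))
  sort(p[p >= 0L & p <= 127L])
}

#' Assign one pitch per unit on a scale
#'
#' Units are ordered by the given policy and assigned consecutive scale
#' degrees starting at the root, so distinct units always get distinct
#' pitches (injective by construction).
#'
#' @param unit_ids Unique event identities (integers or strings).
#' @param scale A [scale_def()].
#' @param ordering `"id"` (ascending unit id, numeric when ids are numeric;
#'   the default), `"given"` (input order), or a function receiving the ids
#'   and returning an ordering permutation — e.g. a probe-depth lookup.
#' @param fit_root Five scale degrees per octave make a large population
#'   span many octaves (52 units span ten and a half), which can push the
#'   top pitch past 127 from a mid-keyboard root. With `fit_root = TRUE`
#'   the root is lowered by whole octaves until the population fits, which
#'   changes the register but not scale membership; with the default
#'   `FALSE`, an overflowing population is an error.
#' @return A `pitch_map`: a named integer vector, names are unit ids.
#' @examples
#' assign_unit_pitches(c(7, 2, 9), scale_def()) # 2->48, 7->50, 9->52
#' assign_unit_pitches(1:52, fit_root = TRUE)   # 52 pitches, root dropped to 0
#' @export
assign_unit_pitches <- function(unit_ids, scale = scale_def(), ordering = "id",
                                fit_root = FALSE) {
  if (anyDuplicated(unit_ids)) {
    nm_stop("duplicate_ids", "unit ids must be unique (duplicate: %s)",
            unit_ids[duplicated(unit_ids)][[1L]])
  }
  n <- length(unit_ids)
  if (n == 0L) {
    return(structure(stats::setNames(integer(), character()), class = "pitch_map"))
  }
  ord <- if (is.function(ordering)) {
    ordering(unit_ids)
  } else if (identical(ordering, "given")) {
    seq_len(n)
  } else if (identical(ordering, "id")) {
    num <- suppressWarnings(as.numeric(unit_ids))
    if (anyNA(num)) order(as.character(unit_ids)) else order(num)
  } else {
    nm_stop("bad_ordering", "ordering must be \"id\", \"given\", or a function")
  }
  if (fit_root) {
    top <- function(root) root + 12L * ((n - 1L) %/% length(scale$degrees)) +
      scale$degrees[((n - 1L) %% length(scale$degrees)) + 1L]
    while (scale$root_pitch >= 12L && top(scale$root_pitch) > 127L) {
      scale$root_pitch <- scale$root_pitch - 12L
    }
  }
  pitches <- scale_pitch(scale, seq_len(n) - 1L)  # errors if n exceeds the range
  structure(stats::setNames(pitches, as.character(unit_ids[ord])), class = "pitch_map")
}

#' @export
print.pitch_map <- function(x, ...) {
  cat(sprintf("<pitch_map> %d identities -> pitches [%s]\n", length(x),
              if (length(x)) paste(range(x), collapse = ", ") else ""))
  invisible(x)
}

#' Instantaneous event rate from event times
#'
#' The rate at event i (i >= 2) is the reciprocal of the preceding
#' inter-event interval, `1 / (t_i - t_(i-1))`; the first event, which has
#' no preceding interval, is assigned the second event's rate so it still
#' sounds (e.g. the first drum hit of a session).
#'
#' @param times Strictly increasing event times in seconds, length >= 2.
#' @return Rates in Hz, one per event.
#' @examples
#' instantaneous_rate(c(0, 0.25, 0.75)) # 4 4 2
#' @export
instantaneous_rate <- function(times) {
  if (length(times) < 2L) {
    nm_stop("too_few_events", "need at least 2 events to form a rate, got %d", length(times))
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    nm_stop("zero_interval", "event times must be strictly increasing (interval <= 0 at index %d)",
            which(dt <= 0)[[1L]])
  }
  r <- 1 / dt
  c(r[[1L]], r)
}

#' Map a rate to pitch on a log scale
#'
#' Linear interpolation in log rate between `(r_min, p_lo)` and
#' `(r_max, p_hi)`, clamped to the pitch band and rounded to the nearest
#' integer (ties away from zero). With `quantize_scale`, the result is
#' snapped to the nearest pitch of that scale, ties toward the lower pitch.
#' This is the sniff-rate map: higher breathing frequency, higher drum
#' pitch, with equal pitch steps per frequency *ratio*.
#'
#' @param rate Rate(s) in Hz, positive (vectorized).
#' @param r_min,r_max Rate band mapped onto the pitch band; `0 < r_min < r_max`.
#' @param p_lo,p_hi Pitch band, `0 <= p_lo < p_hi <= 127`.
#' @param quantize_scale Optional [scale_def()] to snap pitches to.
#' @return Integer pitch(es).
#' @examples
#' rate_to_pitch(c(2, 4, 8), r_min = 2, r_max = 8, p_lo = 36, p_hi = 60) # 36 48 60
#' @export
rate_to_pitch <- function(rate, r_min, r_max, p_lo = 36L, p_hi = 60L,
                          quantize_scale = NULL) {
  if (!is.numeric(r_min) || !is.numeric(r_max) || r_min <= 0 || r_max <= r_min) {
    nm_stop("bad_rate_band", "need 0 < r_min < r_max, got [%s, %s]",
            format(r_min), format(r_max))
  }
  p_lo <- as.integer(p_lo); p_hi <- as.integer(p_hi)
  if (p_lo < 0L || p_hi > 127L || p_lo >= p_hi) {
    nm_stop("pitch_range", "need 0 <= p_lo < p_hi <= 127, got [%d, %d]", p_lo, p_hi)
  }
  if (any(!is.finite(rate) | rate <= 0)) {
    nm_stop("bad_rate", "rates must be positive and finite")
  }
  frac <- (log(rate) - log(r_min)) / (log(r_max) - log(r_min))
  frac <- pmin(1, pmax(0, frac))
  p <- as.integer(round_half_away(p_lo + (p_hi - p_lo) * frac))
  if (!is.null(quantize_scale)) {
    stopifnot(inherits(quantize_scale, "scale_def"))
    set <- scale_pitch_set(quantize_scale)
    p <- vapply(p, function(pi) {
      d <- abs(set - pi)
      cand <- set[d == min(d)]
      min(cand)                         # tie -> lower pitch
    }, integer(1))
  }
  p
}
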