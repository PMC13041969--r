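# NoteTable: the six-column note representation at the heart of the
# conversion -- track, channel, pitch, velocity, onset, offset per note.
# Track separates event types (drums vs piano vs claps); channel is held
# constant except for percussion routing; pitch carries identity or rate;
# velocity is constant by design; onset/offset are in seconds and get
# quantized to the time grid only at serialization.

#' Construct a note table
#'
#' @param track Non-negative integer track index per note.
#' @param channel Integer MIDI channel 0-15 per note.
#' @param pitch Integer MIDI pitch 0-127 per note.
#' @param velocity Integer velocity 1-127 per note.
#' @param onset_s Note onset in seconds, >= 0.
#' @param offset_s Note offset in seconds, > onset.
#' @return An object of class `note_table` (a data frame with the six
#'   columns), stably sorted by onset.
#' @export
note_table <- function(track = integer(), channel = integer(), pitch = integer(),
                       velocity = integer(), onset_s = numeric(), offset_s = numeric()) {
  n <- length(onset_s)
  out <- data.frame(
    track = rep_len(as.integer(track), n),
    channel = rep_len(as.integer(channel), n),
    pitch = rep_len(as.integer(pitch), n),
    velocity = rep_len(as.integer(velocity), n),
    onset_s = as.double(onset_s),
    offset_s = rep_len(as.double(offset_s), n)
  )
  validate_note_table(out)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("note_table", "data.frame")
  out
}

validate_note_table <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$track < 0L)) nm_stop("bad_track", "track indices must be non-negative")
  if (any(x$channel < 0L | x$channel > 15L)) {
    nm_stop("bad_channel", "channel must be in [0, 15]")
  }
  if (any(x$pitch < 0L | x$pitch > 127L)) {
    nm_stop("pitch_range", "pitch must be in [0, 127], got %d",
            x$pitch[which(x$pitch < 0L | x$pitch > 127L)[1L]])
  }
  if (any(x$velocity < 1L | x$velocity > 127L)) {
    nm_stop("bad_velocity", "velocity must be in [1, 127]")
  }
  if (any(x$onset_s < 0) || anyNA(x$onset_s)) {
    nm_stop("negative_time", "onsets must be non-negative")
  }
  if (any(x$offset_s <= x$onset_s)) {
    nm_stop("bad_duration", "every note must have offset_s > onset_s")
  }
  invisible(x)
}

#' @export
print.note_table <- function(x, ...) {
  cat(sprintf("<note_table> %d notes", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(" on %d track(s), pitches [%d, %d], t in [%.4g, %.4g] s",
                length(unique(x$track)), min(x$pitch), max(x$pitch),
                min(x$onset_s), max(x$offset_s)))
  }
  cat("\n")
  invisible(x)
}

#' A log-rate pitch policy for rhythm tracks
#'
#' Bundles the parameters of [rate_to_pitch()] for use with
#' [events_to_notes()]: each event's pitch encodes the instantaneous event
#' rate at that moment. Leave `r_min`/`r_max` `NULL` to use the 1st and
#' 99th percentiles of the observed rates (explicit values always win).
#'
#' @inheritParams rate_to_pitch
#' @return An object of class `rate_pitch_policy`.
#' @export
rate_pitch_policy <- function(r_min = NULL, r_max = NULL, p_lo = 36L, p_hi = 60L,
                              quantize_scale = NULL) {
  structure(list(r_min = r_min, r_max = r_max, p_lo = as.integer(p_lo),
                 p_hi = as.integer(p_hi), quantize_scale = quantize_scale),
            class = "rate_pitch_policy")
}

#' Convert an event stream to notes
#'
#' Each event becomes exactly one note: onset at the event time, offset a
#' constant `duration_s` later (default 10 ms), pitch from the policy.
#' With a `pitch_map` policy the pitch is the event identity's assigned
#' pitch; with a [rate_pitch_policy()] the pitch encodes the instantaneous
#' event rate on a log scale.
#'
#' Two notes of the same (track, channel, pitch) may not overlap: when a
#' later same-pitch note starts before an earlier one ends, the earlier
#' note's offset is truncated to the later onset. Truncation changes
#' durations, never the note count. Notes starting at the *same* instant on
#' the same pitch are left coincident.
#'
#' @param events An [event_stream()].
#' @param policy A `pitch_map` (see [assign_unit_pitches()]) or a
#'   [rate_pitch_policy()].
#' @param track Track index for all emitted notes.
#' @param channel MIDI channel 0-15 for all emitted notes.
#' @param velocity Note velocity 1-127 (constant by design).
#' @param duration_s Note length in seconds before overlap truncation.
#' @return A [note_table()] sorted by onset.
#' @export
events_to_notes <- function(events, policy, track = 0L, channel = 0L,
                            velocity = 100L, duration_s = 0.010) {
  stopifnot(inherits(events, "event_stream"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    nm_stop("bad_duration", "duration_s must be positive")
  }
  n <- nrow(events)
  if (n == 0L) {
    return(note_table())
  }

  if (inherits(policy, "pitch_map")) {
    missing_ids <- setdiff(unique(events$label), names(policy))
    if (length(missing_ids) > 0L) {
      nm_stop("unmapped_identity", "event identity not in pitch map: %s",
              paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    pitch <- unname(policy[events$label])
  } else if (inherits(policy, "rate_pitch_policy")) {
    rates <- instantaneous_rate(events$time_s)
    r_min <- policy$r_min %||% stats::quantile(rates, 0.01, names = FALSE)
    r_max <- policy$r_max %||% stats::quantile(rates, 0.99, names = FALSE)
    if (r_max <= r_min) r_max <- r_min * (1 + 1e-9)  # degenerate constant-rate stream
    pitch <- rate_to_pitch(rates, r_min, r_max, policy$p_lo, policy$p_hi,
                           policy$quantize_scale)
  } else {
    nm_stop("bad_policy", "policy must be a pitch_map or rate_pitch_policy")
  }

  notes <- note_table(track = track, channel = channel, pitch = pitch,
                      velocity = velocity, onset_s = events$time_s,
                      offset_s = events$time_s + duration_s)
  resolve_overlaps(notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Same-(track, channel, pitch) notes may not overlap: truncate the earlier
# note's offset to the later note's onset. Coincident onsets are left as-is.
resolve_overlaps <- function(notes) {
  if (nrow(notes) < 2L) return(notes)
  key <- paste(notes$track, notes$channel, notes$pitch)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    on_next <- notes$onset_s[idx][-1L]
    off_cur <- notes$offset_s[idx][-length(idx)]
    truncated <- pmin(off_cur, on_next)
    # keep offsets strictly after onsets; coincident onsets stay untouched
    ok <- truncated > notes$onset_s[idx][-length(idx)]
    notes$offset_s[idx[-length(idx)][ok]] <- truncated[ok]
  }
  notes
}
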