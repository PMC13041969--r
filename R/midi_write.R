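# Standard MIDI File serialization. Format 1: one conductor track carrying
# the (slow-down-scaled) tempo meta-event, then one track chunk per distinct
# note-table track value. Byte output is a pure function of (notes, config).

#' Quantize a time to the configured grid
#'
#' Returns the grid index `round(t * grid_per_s)`, nearest integer with
#' ties away from zero. Under the default grid of `1e4` points per second
#' the grid step is exactly 100 microseconds.
#'
#' @param t Time(s) in seconds, >= 0 (vectorized).
#' @param grid_per_s Grid resolution in points per second.
#' @return Integer grid index (as double to allow long recordings).
#' @examples
#' quantize_onset(0.1234, 1e4)  # 1234
#' quantize_onset(0.12345, 1e4) # 1235 (tie rounds away from zero)
#' @export
quantize_onset <- function(t, grid_per_s = 1e4) {
  if (any(!is.finite(t)) || any(t < 0)) {
    nm_stop("negative_time", "times to quantize must be finite and non-negative")
  }
  if (!is.numeric(grid_per_s) || grid_per_s <= 0) {
    nm_stop("bad_config", "grid_per_s must be positive")
  }
  round_half_away(t * grid_per_s)
}

# Variable-length quantity: 7 bits per byte, MSB set on all but the last.
encode_vlq <- function(n) {
  if (n < 0 || n > 0x0FFFFFFF) nm_stop("bad_value", "VLQ out of range: %s", format(n))
  bytes <- n %% 128
  n <- n %/% 128
  while (n > 0) {
    bytes <- c(n %% 128 + 128, bytes)
    n <- n %/% 128
  }
  as.raw(bytes)
}

uint_be <- function(n, width) {
  as.raw(rev((n %/% 256^(0:(width - 1))) %% 256))
}

meta_event <- function(type, payload) {
  c(as.raw(c(0xFF, type)), encode_vlq(length(payload)), payload)
}

track_chunk <- function(event_bytes) {
  body <- c(do.call(c, event_bytes), as.raw(c(0x00, 0xFF, 0x2F, 0x00)))
  c(charToRaw("MTrk"), uint_be(length(body), 4L), body)
}

# Seconds -> ticks: quantize to the grid first, then express the quantized
# time in ticks of the *nominal* tempo (slow-down never touches ticks).
seconds_to_ticks <- function(t, config) {
  q <- quantize_onset(t, config$grid_per_s)
  round_half_away((q / config$grid_per_s) * config$ppq * 1e6 / config$tempo_us_per_quarter)
}

#' Serialize a note table to Standard MIDI File bytes
#'
#' Emits a format-1 SMF: a conductor track holding the tempo meta-event
#' (nominal tempo times the slow-down factor) followed by one track chunk
#' per distinct `track` value, each named `track:<n>` so the note-table
#' track indices survive a round trip. Every note becomes one note-on and
#' one note-off; at equal ticks note-offs are serialized before program
#' changes before note-ons (then by channel, then pitch) so no note is ever
#' left hanging. Onsets are quantized to the configured grid; a note whose
#' quantized offset would not fall after its onset is extended to one tick.
#'
#' Tracks flagged `"percussion"` in `track_instruments` are routed to MIDI
#' channel 10 (zero-indexed 9) so generic players render drum sounds;
#' numeric instrument entries emit a program-change on the track's channel.
#'
#' @param notes A [note_table()].
#' @param config A [sonification_config()].
#' @return A raw vector: the bytes of the `.mid` file.
#' @seealso [write_smf()] to write to disk, [parse_smf()] for the inverse.
#' @export
notes_to_smf <- function(notes, config = sonification_config()) {
  stopifnot(inherits(notes, "note_table") || is.data.frame(notes),
            inherits(config, "sonification_config"))
  validate_note_table(notes)

  track_ids <- sort(unique(notes$track))
  conductor <- track_chunk(list(
    c(encode_vlq(0), meta_event(0x03, charToRaw("conductor"))),
    c(encode_vlq(0), meta_event(0x51, uint_be(effective_tempo(config), 3L)))
  ))

  chunks <- lapply(track_ids, function(tid) {
    sel <- notes$track == tid
    instrument <- config$track_instruments[[as.character(tid)]]
    percussive <- identical(instrument, "percussion")
    channel <- if (percussive) rep(9L, sum(sel)) else notes$channel[sel]

    on_tick <- seconds_to_ticks(notes$onset_s[sel], config)
    off_tick <- seconds_to_ticks(notes$offset_s[sel], config)
    off_tick <- pmax(off_tick, on_tick + 1)

    ev <- data.frame(
      tick = c(on_tick, off_tick),
      class = rep(c(2L, 0L), each = sum(sel)),  # 0 = off, 1 = prog, 2 = on
      channel = c(channel, channel),
      pitch = rep(notes$pitch[sel], 2L),
      velocity = c(notes$velocity[sel], rep(0L, sum(sel)))
    )
    if (!percussive && !is.null(instrument)) {
      prog <- as.integer(instrument)
      if (is.na(prog) || prog < 0L || prog > 127L) {
        nm_stop("bad_config", "instrument for track %d must be 0-127 or \"percussion\"", tid)
      }
      ch0 <- if (sum(sel) > 0) channel[[1L]] else 0L
      ev <- rbind(data.frame(tick = 0, class = 1L, channel = ch0,
                             pitch = prog, velocity = NA_integer_), ev)
    }
    ev <- ev[order(ev$tick, ev$class, ev$channel, ev$pitch), , drop = FALSE]

    deltas <- diff(c(0, ev$tick))
    events <- lapply(seq_len(nrow(ev)), function(i) {
      d <- encode_vlq(deltas[[i]])
      if (ev$class[[i]] == 1L) {
        c(d, as.raw(c(0xC0 + ev$channel[[i]], ev$pitch[[i]])))
      } else if (ev$class[[i]] == 2L) {
        c(d, as.raw(c(0x90 + ev$channel[[i]], ev$pitch[[i]], ev$velocity[[i]])))
      } else {
        c(d, as.raw(c(0x80 + ev$channel[[i]], ev$pitch[[i]], 0x00)))
      }
    })
    track_chunk(c(list(c(encode_vlq(0),
                         meta_event(0x03, charToRaw(sprintf("track:%d", tid))))),
                  events))
  })

  header <- c(charToRaw("MThd"), uint_be(6L, 4L), uint_be(1L, 2L),
              uint_be(length(track_ids) + 1L, 2L), uint_be(config$ppq, 2L))
  c(header, conductor, do.call(c, c(list(raw()), chunks)))
}

#' Write a note table to a `.mid` file
#'
#' @inheritParams notes_to_smf
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smf <- function(notes, config = sonification_config(), path) {
  bytes <- notes_to_smf(notes, config)
  writeBin(bytes, path)
  invisible(path)
}
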