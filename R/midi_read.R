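# Standard MIDI File parsing: the inverse of notes_to_smf, used for
# inspection and round-trip verification. Accepts any format-0 or format-1
# file, handles running status, and honors the tempo map when converting
# ticks back to real seconds.

#' Parse a Standard MIDI File
#'
#' Reconstructs the six-column note table by pairing each note-on with the
#' next matching note-off (FIFO per track, channel, and pitch; a note-on
#' with velocity 0 counts as a note-off). Tick times are converted to real
#' seconds through the file's tempo map, so a slowed-down file reports its
#' slowed (playback) times. Track values are recovered from the `track:<n>`
#' name meta-events written by [notes_to_smf()]; unnamed tracks are
#' numbered 0, 1, ... in chunk order, skipping chunks that contain no notes
#' (such as a conductor track).
#'
#' @param x A raw vector of SMF bytes, or a path to a `.mid` file.
#' @return A list of class `parsed_smf` with elements:
#'   \describe{
#'     \item{notes}{A [note_table()] with extra columns `onset_tick` and
#'       `offset_tick`.}
#'     \item{format, ppq, n_chunks}{Header fields.}
#'     \item{tempo_us_per_quarter}{The first tempo meta-event (500000 when
#'       none is present, per the SMF default).}
#'     \item{duration_s}{Real time of the last note offset (0 when empty).}
#'   }
#' @export
parse_smf <- function(x) {
  bytes <- if (is.raw(x)) x else {
    if (!file.exists(x)) nm_stop("missing_file", "MIDI file not found: %s", x)
    readBin(x, "raw", file.info(x)$size)
  }
  pos <- 1L
  need <- function(n) {
    if (pos + n - 1L > length(bytes)) nm_stop("malformed_smf", "truncated MIDI file")
    out <- bytes[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  uint <- function(n) sum(as.numeric(need(n)) * 256^((n - 1):0))

  if (!identical(rawToChar(need(4L)), "MThd")) {
    nm_stop("malformed_smf", "missing MThd header")
  }
  if (uint(4L) != 6) nm_stop("malformed_smf", "unexpected MThd length")
  format <- uint(2L)
  n_chunks <- uint(2L)
  division <- uint(2L)
  if (division >= 0x8000) {
    nm_stop("malformed_smf", "SMPTE time division not supported")
  }
  ppq <- division

  all_events <- list()
  tempo_events <- list(list(tick = 0, us = 500000))  # SMF default tempo
  chunk_i <- 0L
  while (pos <= length(bytes) - 7L) {
    id <- rawToChar(need(4L))
    len <- uint(4L)
    if (id != "MTrk") { need(len); next }            # skip alien chunks
    chunk_i <- chunk_i + 1L
    end <- pos + len
    tick <- 0
    status <- NULL
    track_name <- NA_character_
    repeat {
      if (pos >= end) nm_stop("malformed_smf", "track chunk ran past its length")
      # delta time (VLQ)
      delta <- 0
      repeat {
        b <- as.integer(need(1L))
        delta <- delta * 128 + (b %% 128)
        if (b < 128) break
      }
      tick <- tick + delta
      b <- as.integer(need(1L))
      if (b < 0x80) {                                # running status
        if (is.null(status)) nm_stop("malformed_smf", "data byte with no running status")
        pos <- pos - 1L
        b <- status
      } else if (b < 0xF0) {
        status <- b
      }
      if (b == 0xFF) {                               # meta event
        type <- as.integer(need(1L))
        mlen <- 0
        repeat {
          mb <- as.integer(need(1L))
          mlen <- mlen * 128 + (mb %% 128)
          if (mb < 128) break
        }
        payload <- if (mlen > 0) need(mlen) else raw()
        if (type == 0x51) {
          tempo_events[[length(tempo_events) + 1L]] <-
            list(tick = tick, us = sum(as.numeric(payload) * 256^((mlen - 1):0)))
        } else if (type == 0x03) {
          track_name <- rawToChar(payload)
        } else if (type == 0x2F) {
          break
        }
      } else if (b %in% c(0xF0, 0xF7)) {             # sysex: length-prefixed
        slen <- 0
        repeat {
          sb <- as.integer(need(1L))
          slen <- slen * 128 + (sb %% 128)
          if (sb < 128) break
        }
        if (slen > 0) need(slen)
      } else {
        hi <- b %/% 16
        ch <- b %% 16
        n_data <- if (hi %in% c(0xC, 0xD)) 1L else 2L
        data <- as.integer(need(n_data))
        if (hi == 0x9 || hi == 0x8) {
          on <- hi == 0x9 && data[[2L]] > 0L
          all_events[[length(all_events) + 1L]] <- data.frame(
            chunk = chunk_i, tick = tick, on = on, channel = ch,
            pitch = data[[1L]], velocity = if (on) data[[2L]] else 0L
          )
        }
      }
    }
    if (pos != end) pos <- end                       # tolerate padding
    # tag this chunk's events with its name
    if (length(all_events) > 0) {
      for (j in seq_along(all_events)) {
        if (all_events[[j]]$chunk[[1L]] == chunk_i && is.null(all_events[[j]]$name)) {
          all_events[[j]]$name <- track_name
        }
      }
    }
  }

  tempo_tab <- do.call(rbind, lapply(tempo_events, as.data.frame))
  tempo_tab <- tempo_tab[order(tempo_tab$tick), , drop = FALSE]
  tempo_tab <- tempo_tab[!duplicated(tempo_tab$tick, fromLast = TRUE), , drop = FALSE]
  tick_to_seconds <- make_tick_clock(tempo_tab, ppq)

  if (length(all_events) == 0L) {
    notes <- note_table()
    notes$onset_tick <- numeric(0)
    notes$offset_tick <- numeric(0)
    return(structure(list(notes = notes, format = format, ppq = ppq,
                          n_chunks = n_chunks,
                          tempo_us_per_quarter = tempo_tab$us[[1L]],
                          duration_s = 0),
                     class = "parsed_smf"))
  }

  ev <- do.call(rbind, all_events)
  # map chunk -> note-table track value: named "track:<n>" wins, else the
  # 0-based order among note-carrying chunks
  chunk_ids <- sort(unique(ev$chunk))
  track_of <- stats::setNames(seq_along(chunk_ids) - 1L, chunk_ids)
  for (cid in chunk_ids) {
    nm <- ev$name[ev$chunk == cid][[1L]]
    if (!is.na(nm) && grepl("^track:[0-9]+$", nm)) {
      track_of[[as.character(cid)]] <- as.integer(sub("^track:", "", nm))
    }
  }
  ev$track <- unname(track_of[as.character(ev$chunk)])

  notes_list <- list()
  for (key in unique(paste(ev$track, ev$channel, ev$pitch))) {
    sel <- ev[paste(ev$track, ev$channel, ev$pitch) == key, , drop = FALSE]
    sel <- sel[order(sel$tick, sel$on), , drop = FALSE]  # offs first at a tick
    ons <- sel[sel$on, , drop = FALSE]
    offs <- sel[!sel$on, , drop = FALSE]
    if (nrow(ons) != nrow(offs)) {
      nm_stop("unpaired_note", "unpaired note-on/note-off for track %s channel %s pitch %s",
              sel$track[[1L]], sel$channel[[1L]], sel$pitch[[1L]])
    }
    # FIFO pairing: i-th on with i-th off; count must never dip negative
    running <- cumsum(ifelse(sel$on, 1L, -1L))
    if (any(running < 0L)) {
      nm_stop("unpaired_note", "note-off precedes its note-on for pitch %s", sel$pitch[[1L]])
    }
    notes_list[[key]] <- data.frame(
      track = ons$track, channel = ons$channel, pitch = ons$pitch,
      velocity = ons$velocity, onset_tick = ons$tick, offset_tick = offs$tick
    )
  }
  nt <- do.call(rbind, notes_list)
  for (col in c("track", "channel", "pitch", "velocity")) nt[[col]] <- as.integer(nt[[col]])
  nt$onset_s <- tick_to_seconds(nt$onset_tick)
  nt$offset_s <- tick_to_seconds(nt$offset_tick)
  nt <- nt[order(nt$onset_s, nt$track, nt$channel, nt$pitch), , drop = FALSE]
  rownames(nt) <- NULL
  nt <- nt[, c("track", "channel", "pitch", "velocity", "onset_s", "offset_s",
               "onset_tick", "offset_tick")]
  class(nt) <- c("note_table", "data.frame")

  structure(list(notes = nt, format = format, ppq = ppq, n_chunks = n_chunks,
                 tempo_us_per_quarter = tempo_tab$us[[1L]],
                 duration_s = max(nt$offset_s)),
            class = "parsed_smf")
}

# Piecewise-linear tick -> seconds under a tempo map: within a tempo
# segment, seconds advance by tempo/ppq microseconds per tick.
make_tick_clock <- function(tempo_tab, ppq) {
  starts <- tempo_tab$tick
  us <- tempo_tab$us
  sec_at <- cumsum(c(0, diff(starts) * us[-length(us)] / ppq / 1e6))
  function(tick) {
    i <- findInterval(tick, starts)
    sec_at[i] + (tick - starts[i]) * us[i] / ppq / 1e6
  }
}

#' @export
print.parsed_smf <- function(x, ...) {
  cat(sprintf("<parsed_smf> format %d, ppq %d, tempo %g us/quarter\n",
              x$format, x$ppq, x$tempo_us_per_quarter))
  cat(sprintf("  %d notes on %d track(s), duration %.3f s\n",
              nrow(x$notes), length(unique(x$notes$track)), x$duration_s))
  invisible(x)
}
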