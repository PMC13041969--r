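# EventStream: the universal intermediate representation. A labeled,
# time-sorted sequence of discrete events -- spikes, inhalations, gaze
# shifts, blinks, behavioral syllables -- with identities kept opaque.

#' Construct an event stream
#'
#' An event stream holds discrete events as parallel vectors of identities
#' and times in seconds. It is the common representation every input route
#' (spike-sorting output, generic event file) is converted to before pitch
#' mapping. Events are stably sorted by time on construction, so ties keep
#' their input order.
#'
#' @param labels Event identities (character or integer-like; stored as
#'   character).
#' @param times Event times in seconds; finite and non-negative.
#' @return An object of class `event_stream`: a data frame with columns
#'   `label` and `time_s`, sorted by `time_s`.
#' @examples
#' ev <- event_stream(c("A", "B", "A"), c(0.30, 0.25, 0.10))
#' ev$time_s # 0.10 0.25 0.30
#' @export
event_stream <- function(labels = character(), times = numeric()) {
  if (length(labels) != length(times)) {
    nm_stop("length_mismatch", "labels (%d) and times (%d) differ in length",
            length(labels), length(times))
  }
  times <- as.double(times)
  if (anyNA(times) || any(!is.finite(times))) {
    nm_stop("non_numeric_time", "event times must be finite numbers")
  }
  if (any(times < 0)) {
    nm_stop("negative_time", "event times must be non-negative (min was %g)", min(times))
  }
  ord <- order(times)                     # radix sort: stable
  out <- data.frame(label = as.character(labels)[ord], time_s = times[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("event_stream", "data.frame")
  out
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %d identities, t in [%.4g, %.4g] s",
                length(unique(x$label)), min(x$time_s), max(x$time_s)))
  }
  cat("\n")
  invisible(x)
}

#' Read a two-column event file
#'
#' The event-file dialect is delimiter-separated text with two columns:
#' event identity, then event time in seconds. The delimiter (comma or tab)
#' is auto-detected and an optional header row (`event_id,time_s`) is
#' skipped. Identities are preserved verbatim.
#'
#' @param path Path to a CSV or TSV file.
#' @return An [event_stream()], sorted by time.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("event_id,time_s", "u1,0.5", "u2,0.25"), f)
#' read_event_file(f)
#' @export
read_event_file <- function(path) {
  if (!file.exists(path)) nm_stop("missing_file", "event file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) nm_stop("empty_file", "event file is empty: %s", path)

  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    nm_stop("malformed_row", "line %d has fewer than two %s-separated fields",
            bad[[1L]], if (sep == ",") "comma" else "tab")
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  tms <- trimws(vapply(parts, `[[`, "", 2L))

  # Optional header row: a non-numeric time field whose names look like
  # column headers ("event_id,time_s" and variants).
  looks_header <- is.na(suppressWarnings(as.numeric(tms[[1L]]))) &&
    (grepl("time|sec", tms[[1L]], ignore.case = TRUE) ||
       grepl("event|id|label", ids[[1L]], ignore.case = TRUE))
  if (looks_header) {
    ids <- ids[-1L]
    tms <- tms[-1L]
    if (length(ids) == 0L) nm_stop("empty_file", "event file has a header but no rows: %s", path)
  }
  times <- suppressWarnings(as.numeric(tms))
  if (anyNA(times)) {
    nm_stop("non_numeric_time", "non-numeric event time on data row %d: '%s'",
            which(is.na(times))[[1L]], tms[which(is.na(times))[[1L]]])
  }
  event_stream(ids, times)
}

#' Write an event stream to the two-column event-file dialect
#'
#' Emits a comma-separated file with header `event_id,time_s`; reading it
#' back with [read_event_file()] reproduces the stream exactly (times are
#' printed with full double precision).
#'
#' @param events An [event_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_file <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  lines <- c("event_id,time_s",
             sprintf("%s,%s", events$label, formatC(events$time_s, format = "g", digits = 17)))
  writeLines(lines, path)
  invisible(path)
}
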