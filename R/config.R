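# SonificationConfig: everything about how notes become bytes -- time-grid
# resolution, the constant note length and velocity, the tick scheme
# (tempo + PPQ), the slow-down factor, and the track->instrument map.

#' Sonification configuration
#'
#' The time grid (default `1e4` points per second) is realized in MIDI
#' ticks: at the default tempo of 120 BPM (500000 microseconds per quarter
#' note) and 5000 ticks per quarter, one tick lasts exactly 100
#' microseconds = one grid step. For non-default grids, the smallest PPQ
#' (at most 32767) realizing at least one tick per grid step is derived
#' automatically when `ppq` is `NULL`.
#'
#' Slow-down is applied through the tempo meta-event alone: note ticks are
#' computed against the nominal tempo, and the serialized tempo is
#' `tempo_us_per_quarter * slowdown`, so the data and the playback time
#' scale stay cleanly separated and tick values are bit-exact across
#' slow-down factors.
#'
#' @param grid_per_s Grid resolution in points per second (default `1e4`).
#' @param duration_s Default note length in seconds (default `0.010`).
#' @param velocity Default note velocity 1-127 (default `100`).
#' @param tempo_us_per_quarter Nominal tempo in microseconds per quarter
#'   note (default `500000`, i.e. 120 BPM).
#' @param ppq Ticks per quarter note, 1-32767; `NULL` derives the smallest
#'   PPQ realizing the grid (5000 under defaults).
#' @param slowdown Playback slow-down factor, >= 1 (demonstrations use 3).
#' @param track_instruments Named list mapping track index (as a name) to a
#'   General-MIDI program number (0-127) or the string `"percussion"`,
#'   which routes that track to the percussion channel (10, zero-indexed 9).
#' @return An object of class `sonification_config`.
#' @examples
#' sonification_config()
#' sonification_config(slowdown = 3, track_instruments = list(`0` = "percussion", `1` = 0))
#' @export
sonification_config <- function(grid_per_s = 1e4, duration_s = 0.010,
                                velocity = 100L, tempo_us_per_quarter = 500000,
                                ppq = NULL, slowdown = 1,
                                track_instruments = list()) {
  if (!is.numeric(grid_per_s) || grid_per_s <= 0) {
    nm_stop("bad_config", "grid_per_s must be positive")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    nm_stop("bad_config", "duration_s must be positive")
  }
  velocity <- as.integer(velocity)
  if (is.na(velocity) || velocity < 1L || velocity > 127L) {
    nm_stop("bad_velocity", "velocity must be in [1, 127]")
  }
  if (!is.numeric(tempo_us_per_quarter) || tempo_us_per_quarter < 1) {
    nm_stop("bad_config", "tempo_us_per_quarter must be >= 1")
  }
  if (!is.numeric(slowdown) || slowdown < 1) {
    nm_stop("bad_slowdown", "slowdown must be >= 1")
  }
  if (is.null(ppq)) {
    ppq <- ceiling(tempo_us_per_quarter * grid_per_s / 1e6)
    if (ppq > 32767) {
      nm_stop("bad_config",
              "grid of %g points/s needs PPQ %d > 32767; lower the grid or the tempo",
              grid_per_s, ppq)
    }
  }
  ppq <- as.integer(ppq)
  if (is.na(ppq) || ppq < 1L || ppq > 32767L) {
    nm_stop("bad_config", "ppq must be in [1, 32767]")
  }
  if (round(tempo_us_per_quarter * slowdown) > 0xFFFFFF) {
    nm_stop("bad_config", "tempo * slowdown exceeds the 3-byte tempo meta-event range")
  }
  if (length(track_instruments) > 0 &&
      (is.null(names(track_instruments)) || any(!nzchar(names(track_instruments))))) {
    nm_stop("bad_config", "track_instruments must be a named list (names = track indices)")
  }
  structure(list(
    grid_per_s = as.double(grid_per_s),
    duration_s = as.double(duration_s),
    velocity = velocity,
    tempo_us_per_quarter = as.double(tempo_us_per_quarter),
    ppq = ppq,
    slowdown = as.double(slowdown),
    track_instruments = track_instruments
  ), class = "sonification_config")
}

#' @export
print.sonification_config <- function(x, ...) {
  cat(sprintf(paste0("<sonification_config> grid %g/s, note %g ms, velocity %d,\n",
                     "  tempo %g us/quarter, ppq %d (tick = %g us), slowdown %gx\n"),
              x$grid_per_s, 1000 * x$duration_s, x$velocity,
              x$tempo_us_per_quarter, x$ppq, x$tempo_us_per_quarter / x$ppq,
              x$slowdown))
  if (length(x$track_instruments) > 0) {
    cat(sprintf("  track %s -> %s\n", names(x$track_instruments),
                vapply(x$track_instruments, format, "")), sep = "")
  }
  invisible(x)
}

#' Slow playback down by a tempo factor
#'
#' Multiplies the configuration's slow-down factor, so the serialized tempo
#' meta-event is scaled while every note's tick value stays identical; the
#' parsed real playback duration scales by exactly `factor`.
#'
#' @param config A [sonification_config()].
#' @param factor Slow-down factor, >= 1.
#' @return The updated configuration.
#' @export
apply_slowdown <- function(config, factor) {
  stopifnot(inherits(config, "sonification_config"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1) {
    nm_stop("bad_slowdown", "slow-down factor must be >= 1, got %s", format(factor))
  }
  config$slowdown <- config$slowdown * factor
  if (round(config$tempo_us_per_quarter * config$slowdown) > 0xFFFFFF) {
    nm_stop("bad_config", "tempo * slowdown exceeds the 3-byte tempo meta-event range")
  }
  config
}

# The tempo actually serialized: nominal tempo stretched by the slow-down.
effective_tempo <- function(config) {
  round(config$tempo_us_per_quarter * config$slowdown)
}

#' Read a sonification configuration file
#'
#' The file is YAML with global settings (`grid_per_s`, `note_ms`,
#' `velocity`, `slowdown`, `seed`, `tempo_us_per_quarter`, `ppq`) and a
#' `tracks` list, one entry per output track:
#'
#' ```yaml
#' grid_per_s: 10000
#' note_ms: 10
#' slowdown: 3
#' tracks:
#'   - source: sorting/          # directory -> spike-sorting convention
#'     policy: unit_pitch
#'     instrument: 0             # GM program number, or "percussion"
#'     scale: {root: 48, degrees: [0, 2, 4, 7, 9]}
#'   - source: inhalations.csv   # file -> two-column event file
#'     policy: log_rate
#'     instrument: percussion
#'     p_lo: 36
#'     p_hi: 60
#' ```
#'
#' Relative `source` paths are resolved against the config file's
#' directory. Flag/argument overrides beat file values beat defaults.
#'
#' @param path Path to a YAML configuration file.
#' @param overrides Named list of global settings that win over the file.
#' @return A list with elements `config` (a [sonification_config()]),
#'   `tracks` (list of track specs), and `seed`.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) nm_stop("missing_file", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  build_run_config(raw, overrides, base_dir = dirname(path))
}

# Shared by read_config and cmd_convert-without-a-file. Precedence:
# defaults < file values < overrides.
build_run_config <- function(raw = list(), overrides = list(), base_dir = ".") {
  get_opt <- function(name, default = NULL) {
    overrides[[name]] %||% raw[[name]] %||% default
  }
  config <- sonification_config(
    grid_per_s = get_opt("grid_per_s", 1e4),
    duration_s = get_opt("note_ms", 10) / 1000,
    velocity = get_opt("velocity", 100L),
    tempo_us_per_quarter = get_opt("tempo_us_per_quarter", 500000),
    ppq = get_opt("ppq"),
    slowdown = get_opt("slowdown", 1)
  )
  tracks <- raw$tracks %||% list()
  tracks <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    tr$track <- as.integer(tr$track %||% (i - 1L))
    if (!is.null(tr$source) && !grepl("^/", tr$source)) {
      tr$source <- file.path(base_dir, tr$source)
    }
    tr$policy <- tr$policy %||% "unit_pitch"
    if (!tr$policy %in% c("unit_pitch", "log_rate")) {
      nm_stop("bad_config", "unknown track policy: %s", tr$policy)
    }
    tr
  })
  instruments <- list()
  for (tr in tracks) {
    if (!is.null(tr$instrument)) instruments[[as.character(tr$track)]] <- tr$instrument
  }
  config$track_instruments <- instruments
  list(config = config, tracks = tracks,
       seed = get_opt("seed"), keep_labels = get_opt("keep_labels"))
}
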