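# Seeded synthetic-data generators emulating the statistical structure of
# the two demonstration datasets: background multi-unit Poisson spiking, a
# state-switching breathing rhythm whose states persist for seconds to
# minutes in stable frequency bands, and trigger-locked sequential firing
# with coarse-to-fine latency ordering. All randomness flows through the
# seed argument; the caller's RNG state is left untouched.

#' Describe one breathing state
#'
#' @param name State label.
#' @param rate_band_hz Length-2 numeric `(low, high)` inhalation-rate band
#'   in Hz, `0 < low <= high`.
#' @param mean_dwell_s Mean dwell time in the state, seconds (default 20).
#' @return An object of class `breathing_state`.
#' @export
breathing_state <- function(name, rate_band_hz, mean_dwell_s = 20) {
  if (length(rate_band_hz) != 2L || rate_band_hz[[1L]] <= 0 ||
      rate_band_hz[[2L]] < rate_band_hz[[1L]]) {
    nm_stop("bad_state", "rate_band_hz must be (low, high) with 0 < low <= high")
  }
  if (!is.numeric(mean_dwell_s) || mean_dwell_s <= 0) {
    nm_stop("bad_state", "mean_dwell_s must be positive")
  }
  structure(list(name = as.character(name),
                 rate_band_hz = as.double(rate_band_hz),
                 mean_dwell_s = as.double(mean_dwell_s)),
            class = "breathing_state")
}

# Default three-state repertoire: slow resting breathing, the intermediate
# "grooming" rhythm, and fast sniffing. Bands are disjoint so states are
# recoverable from the sonified drum pitch alone.
default_breathing_states <- function() {
  list(breathing_state("slow", c(2, 4)),
       breathing_state("grooming", c(5, 8)),
       breathing_state("fast", c(9, 13)))
}

#' Simulate independent homogeneous Poisson spike trains
#'
#' @param n_units Number of units (>= 0).
#' @param rates_hz Firing rate per unit (recycled to `n_units`), >= 0.
#' @param duration_s Recording length in seconds.
#' @param seed Integer RNG seed.
#' @param sampling_rate_hz Sampling rate recorded on the output table.
#' @return A [spike_table()] of the merged, time-sorted trains. Unit ids
#'   are 0-based, matching the spike-sorting convention.
#' @export
simulate_poisson_units <- function(n_units, rates_hz, duration_s, seed,
                                   sampling_rate_hz = 30000) {
  if (!is_count(n_units)) nm_stop("bad_value", "n_units must be a non-negative integer")
  if (any(rates_hz < 0) || duration_s < 0) {
    nm_stop("bad_value", "rates and duration must be non-negative")
  }
  rates_hz <- rep_len(as.double(rates_hz), n_units)
  with_seed(seed, {
    per_unit <- lapply(seq_len(n_units), function(u) {
      n <- stats::rpois(1L, rates_hz[[u]] * duration_s)
      sort(stats::runif(n, 0, duration_s))
    })
    ids <- rep(seq_len(n_units) - 1L, lengths(per_unit))
    spike_table(unit_ids = ids, times_s = unlist(c(list(numeric()), per_unit)),
                sampling_rate_hz = sampling_rate_hz)
  })
}

#' Simulate a state-switching breathing rhythm
#'
#' A semi-Markov chain over breathing states: dwell times are exponential
#' with each state's mean and the next state is chosen uniformly among the
#' other states. Within a state, inter-inhalation intervals are drawn
#' uniformly from the reciprocal of the state's rate band, so every
#' instantaneous rate lies inside its state's band by construction. State
#' switches take effect at an inhalation: each interval is drawn wholly
#' from one state's band and the inhalation ending it carries that state's
#' label. The first inhalation, whose displayed rate is by convention the
#' second one's (see [instantaneous_rate()]), inherits the second's label.
#'
#' @param states List of [breathing_state()] objects (default: disjoint
#'   slow 2-4 Hz / grooming 5-8 Hz / fast 9-13 Hz bands).
#' @param duration_s Session length in seconds.
#' @param seed Integer RNG seed.
#' @return A list with `events` (an [event_stream()] of inhalation times,
#'   all labeled `"inh"`), `state_labels` (state name per inhalation), and
#'   `segments` (data frame of state onsets/offsets).
#' @export
simulate_breathing <- function(states = default_breathing_states(),
                               duration_s, seed) {
  if (length(states) == 0L) nm_stop("bad_state", "need at least one breathing state")
  if (!is.numeric(duration_s) || duration_s <= 0) {
    nm_stop("bad_value", "duration_s must be positive")
  }
  with_seed(seed, {
    state_i <- sample.int(length(states), 1L)
    dwell_end <- stats::rexp(1L, 1 / states[[state_i]]$mean_dwell_s)
    seg_start <- 0
    t <- 0
    times <- numeric()
    labels <- character()
    seg <- list()
    repeat {
      st <- states[[state_i]]
      isi <- stats::runif(1L, 1 / st$rate_band_hz[[2L]], 1 / st$rate_band_hz[[1L]])
      t_next <- t + isi
      if (t_next >= duration_s) break
      times <- c(times, t_next)
      labels <- c(labels, st$name)
      t <- t_next
      if (t >= dwell_end) {                # switch takes effect at this inhalation
        seg[[length(seg) + 1L]] <- data.frame(state = st$name,
                                              start_s = seg_start, end_s = t)
        seg_start <- t
        state_i <- next_state(state_i, length(states))
        dwell_end <- t + stats::rexp(1L, 1 / states[[state_i]]$mean_dwell_s)
      }
    }
    seg[[length(seg) + 1L]] <- data.frame(state = states[[state_i]]$name,
                                          start_s = seg_start, end_s = duration_s)
    if (length(labels) >= 2L) labels[[1L]] <- labels[[2L]]
    list(events = event_stream(rep("inh", length(times)), times),
         state_labels = labels,
         segments = do.call(rbind, seg))
  })
}

# Uniform choice among the other states (identity when there is only one).
next_state <- function(current, n_states) {
  if (n_states == 1L) return(current)
  others <- setdiff(seq_len(n_states), current)
  others[[sample.int(length(others), 1L)]]
}

#' Simulate trigger-locked sequential firing
#'
#' For every trigger, unit `k` (1-based) fires once at
#' `trigger + base_latency_s + (k - 1) * latency_step_s + N(0, jitter_sd_s)`,
#' the coarse-to-fine pattern in which low-spatial-frequency-preferring
#' units respond earlier than high-spatial-frequency-preferring ones.
#'
#' @param n_units Number of responding units (>= 1).
#' @param trigger_times An [event_stream()] (or numeric vector) of trigger
#'   times in seconds.
#' @param base_latency_s Latency of the first unit, seconds.
#' @param latency_step_s Latency increment per unit, >= 0.
#' @param jitter_sd_s Gaussian jitter SD per spike, seconds.
#' @param seed Integer RNG seed.
#' @param sampling_rate_hz Sampling rate recorded on the output table.
#' @return A [spike_table()] (unit ids 0-based), merged and time-sorted.
#' @export
simulate_sequential_responses <- function(n_units, trigger_times, base_latency_s,
                                          latency_step_s, jitter_sd_s, seed,
                                          sampling_rate_hz = 30000) {
  if (!is_count(n_units) || n_units < 1L) nm_stop("bad_value", "n_units must be >= 1")
  if (latency_step_s < 0) nm_stop("bad_value", "latency_step_s must be >= 0")
  trig <- if (inherits(trigger_times, "event_stream")) trigger_times$time_s else as.double(trigger_times)
  n_t <- length(trig)
  if (n_t == 0L) {
    return(spike_table(sampling_rate_hz = sampling_rate_hz))
  }
  with_seed(seed, {
    lat <- base_latency_s + (seq_len(n_units) - 1L) * latency_step_s
    times <- rep(trig, each = n_units) + rep(lat, n_t) +
      stats::rnorm(n_units * n_t, 0, jitter_sd_s)
    ids <- rep(seq_len(n_units) - 1L, n_t)
    if (any(times < 0)) {
      nm_stop("negative_time", "latency parameters produce negative spike times")
    }
    spike_table(unit_ids = ids, times_s = times, sampling_rate_hz = sampling_rate_hz)
  })
}

#' Write a complete synthetic session fixture to disk
#'
#' Produces everything the input readers consume, in the formats they
#' read: a spike-sorting-convention directory (`spike_times.npy` as sample
#' indices, `spike_clusters.npy`, `params.py`, `cluster_group.tsv` with all
#' units labeled good), event CSV files, and a `ground_truth.json` sidecar
#' holding the generator's hidden state (per-inhalation state labels,
#' latency parameters).
#'
#' Scenarios:
#' \describe{
#'   \item{`"grooming"`}{120 s session; breathing switches among three
#'     disjoint-band states (slow 2-4 Hz, grooming 5-8 Hz, fast 9-13 Hz,
#'     mean dwell 20 s) written to `inhalations.csv`; 52 background Poisson
#'     units (0.5-3 Hz) as the spiking population.}
#'   \item{`"blink"`}{120 s session; gaze-shift and blink trigger trains
#'     (`gaze_shifts.csv`, `blinks.csv`) each evoking a 12-unit sequential
#'     response (base latency 20 ms, step 10 ms, jitter 1 ms).}
#' }
#'
#' @param out_dir Directory to create/fill.
#' @param seed Integer RNG seed; the fixture is byte-identical per seed.
#' @param scenario `"grooming"` or `"blink"`.
#' @param duration_s Session length in seconds (default 120).
#' @return Invisibly, a list of class `synthetic_session`: the in-memory
#'   objects plus the paths written.
#' @export
make_session_fixture <- function(out_dir, seed, scenario = c("grooming", "blink"),
                                 duration_s = 120) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) nm_stop("unwritable_path", "cannot create %s", out_dir)
  sort_dir <- file.path(out_dir, "sorting")
  dir.create(sort_dir, showWarnings = FALSE)
  rate <- 30000

  if (scenario == "grooming") {
    br <- simulate_breathing(default_breathing_states(), duration_s, seed = seed)
    n_units <- 52L
    sp <- with_seed(seed + 1L, {
      rates <- stats::runif(n_units, 0.5, 3)
      simulate_poisson_units(n_units, rates, duration_s, seed = seed + 2L,
                             sampling_rate_hz = rate)
    })
    write_event_file(br$events, file.path(out_dir, "inhalations.csv"))
    truth <- list(
      scenario = scenario, seed = seed, duration_s = duration_s,
      sample_rate = rate,
      states = lapply(default_breathing_states(), function(s) {
        list(name = s$name, rate_band_hz = s$rate_band_hz, mean_dwell_s = s$mean_dwell_s)
      }),
      inhalation_state = br$state_labels
    )
    session <- list(scenario = scenario, seed = seed, inhalations = br$events,
                    state_labels = br$state_labels, spikes = sp,
                    gaze_shifts = NULL)
  } else {
    gaze <- with_seed(seed + 3L, {
      iti <- stats::runif(ceiling(duration_s), 1, 3)
      event_stream(rep("gaze", sum(cumsum(iti) < duration_s)),
                   cumsum(iti)[cumsum(iti) < duration_s])
    })
    blink <- with_seed(seed + 4L, {
      iti <- stats::runif(ceiling(duration_s / 2), 2, 6)
      event_stream(rep("blink", sum(cumsum(iti) < duration_s)),
                   cumsum(iti)[cumsum(iti) < duration_s])
    })
    n_units <- 12L
    resp <- list(base_latency_s = 0.020, latency_step_s = 0.010, jitter_sd_s = 0.001)
    sp_g <- simulate_sequential_responses(n_units, gaze, resp$base_latency_s,
                                          resp$latency_step_s, resp$jitter_sd_s,
                                          seed = seed + 5L, sampling_rate_hz = rate)
    sp_b <- simulate_sequential_responses(n_units, blink, resp$base_latency_s,
                                          resp$latency_step_s, resp$jitter_sd_s,
                                          seed = seed + 6L, sampling_rate_hz = rate)
    sp <- spike_table(unit_ids = c(sp_g$unit_id, sp_b$unit_id),
                      times_s = c(sp_g$time_s, sp_b$time_s),
                      sampling_rate_hz = rate)
    write_event_file(gaze, file.path(out_dir, "gaze_shifts.csv"))
    write_event_file(blink, file.path(out_dir, "blinks.csv"))
    truth <- c(list(scenario = scenario, seed = seed, duration_s = duration_s,
                    sample_rate = rate, n_units = n_units), resp)
    session <- list(scenario = scenario, seed = seed, gaze_shifts = gaze,
                    blinks = blink, spikes = sp, response = resp)
  }

  # spike-sorting-convention directory
  samples <- round(sp$time_s * rate)
  write_npy(samples, file.path(sort_dir, "spike_times.npy"), dtype = "uint64")
  write_npy(sp$unit_id, file.path(sort_dir, "spike_clusters.npy"), dtype = "int32")
  writeLines(c("dat_path = 'synthetic.dat'", "n_channels_dat = 64",
               "dtype = 'int16'", sprintf("sample_rate = %d.", rate)),
             file.path(sort_dir, "params.py"))
  units <- sort(unique(sp$unit_id))
  writeLines(c("cluster_id\tgroup", sprintf("%d\tgood", units)),
             file.path(sort_dir, "cluster_group.tsv"))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  session$paths <- list(
    root = out_dir, sorting = sort_dir,
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  class(session) <- "synthetic_session"
  invisible(session)
}
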