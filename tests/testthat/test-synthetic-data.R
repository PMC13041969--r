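# Seeded generators: Poisson trains, the state-switching breathing rhythm,
# trigger-locked sequential responses, and the on-disk session fixtures.

test_that("Poisson trains are reproducible, sorted, and sized correctly", {
  a <- simulate_poisson_units(5, 10, duration_s = 10, seed = 42)
  b <- simulate_poisson_units(5, 10, duration_s = 10, seed = 42)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$time_s))
  expect_equal(nrow(simulate_poisson_units(0, numeric(), 10, seed = 1)), 0L)
  expect_error(simulate_poisson_units(2, -1, 10, seed = 1), class = "neuromidi_bad_value")
})

test_that("Poisson spike counts match the rate-duration product (oracle)", {
  # mean 1000, sd sqrt(1000); average over 20 seeds must sit well inside 3 sigma
  counts <- vapply(1:20, function(s) {
    nrow(simulate_poisson_units(1, 10, duration_s = 100, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000) / sqrt(20))
  expect_true(all(abs(counts - 1000) < 4 * sqrt(1000)))
})

test_that("generator randomness never leaks into the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_poisson_units(3, 5, 10, seed = 7))
  invisible(simulate_breathing(duration_s = 20, seed = 7))
  invisible(simulate_sequential_responses(3, c(1, 2), 0.02, 0.01, 0.001, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("a degenerate single-band state is strictly periodic", {
  br <- simulate_breathing(list(breathing_state("only", c(2, 2))),
                           duration_s = 10, seed = 1)
  expect_equal(unique(round(diff(br$events$time_s), 12)), 0.5)
  expect_equal(unique(br$state_labels), "only")
})

test_that("every within-state interval lies in the state's reciprocal band", {
  br <- simulate_breathing(duration_s = 120, seed = 9)
  bands <- list(slow = c(2, 4), grooming = c(5, 8), fast = c(9, 13))
  rates <- instantaneous_rate(br$events$time_s)
  for (i in seq_along(rates)) {
    band <- bands[[br$state_labels[[i]]]]
    expect_gte(rates[[i]], band[[1]] - 1e-9)
    expect_lte(rates[[i]], band[[2]] + 1e-9)
  }
})

test_that("inhalation counts agree with the dwell-weighted rate oracle", {
  # with equal mean dwells the chain spends 1/3 of its time in each state;
  # E[ISI] per state is the midpoint of the reciprocal band
  states <- default_breathing_states()
  e_isi <- vapply(states, function(s) mean(1 / s$rate_band_hz), numeric(1))
  expected <- 120 * mean(1 / e_isi)
  counts <- vapply(1:20, function(s) {
    nrow(simulate_breathing(states, duration_s = 120, seed = s)$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * stats::sd(counts) / sqrt(20))
})

test_that("sequential responses follow the latency ladder exactly without jitter", {
  sp <- simulate_sequential_responses(3, trigger_times = 1, base_latency_s = 0.02,
                                      latency_step_s = 0.01, jitter_sd_s = 0,
                                      seed = 1)
  expect_equal(sp$time_s, c(1.02, 1.03, 1.04))
  expect_equal(sp$unit_id, 0:2)
  expect_equal(nrow(simulate_sequential_responses(3, numeric(), 0.02, 0.01, 0, seed = 1)), 0L)
  expect_error(simulate_sequential_responses(2, 0.001, -0.1, 0.01, 0, seed = 1),
               class = "neuromidi_negative_time")
})

test_that("median latencies increase strictly with unit index under small jitter", {
  triggers <- cumsum(rep(0.5, 60))
  sp <- simulate_sequential_responses(8, triggers, 0.02, 0.01, 0.001, seed = 4)
  med <- vapply(0:7, function(u) {
    tu <- sp$time_s[sp$unit_id == u]
    median(vapply(triggers, function(tr) min(tu[tu >= tr] - tr), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("session fixtures are byte-identical per seed and round-trip", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  s1 <- make_session_fixture(d1, seed = 5, scenario = "grooming", duration_s = 60)
  make_session_fixture(d2, seed = 5, scenario = "grooming", duration_s = 60)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # reading the sorting directory reproduces the generated spike table
  # (sample-index rounding moves times by < half a sample)
  sp <- read_spike_sorting_output(s1$paths$sorting)
  expect_equal(sp$unit_id, s1$spikes$unit_id)
  expect_lt(max(abs(sp$time_s - s1$spikes$time_s)), 0.5 / 30000)
  # the event file reloads the inhalation stream exactly
  ev <- read_event_file(file.path(d1, "inhalations.csv"))
  expect_equal(ev, s1$inhalations)
})

test_that("grooming fixture states map to disjoint drum pitch sets", {
  d <- withr::local_tempdir()
  # a session long enough that all three states occur (dwell mean 20 s)
  s <- make_session_fixture(d, seed = 17, scenario = "grooming", duration_s = 120)
  nt <- events_to_notes(s$inhalations, rate_pitch_policy(r_min = 2, r_max = 13),
                        track = 0L, channel = 9L)
  sets <- split(nt$pitch, s$state_labels)
  expect_length(sets, 3L)
  expect_length(intersect(sets$slow, sets$grooming), 0)
  expect_length(intersect(sets$grooming, sets$fast), 0)
  expect_length(intersect(sets$slow, sets$fast), 0)
})

test_that("blink fixture carries both trigger streams and labeled-good units", {
  d <- withr::local_tempdir()
  s <- make_session_fixture(d, seed = 2, scenario = "blink", duration_s = 60)
  expect_true(file.exists(file.path(d, "gaze_shifts.csv")))
  expect_true(file.exists(file.path(d, "blinks.csv")))
  truth <- jsonlite::read_json(s$paths$ground_truth)
  expect_equal(truth$scenario, "blink")
  expect_equal(truth$n_units, 12L)
  sp <- read_spike_sorting_output(s$paths$sorting)   # defaults keep "good"
  expect_equal(sort(unique(sp$unit_id)), 0:11)
})
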