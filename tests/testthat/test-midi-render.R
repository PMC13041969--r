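# Grid quantization, SMF serialization/parsing, tempo-based slow-down.

test_that("onset quantization rounds to the nearest grid point, ties away from zero", {
  expect_equal(quantize_onset(0, 1e4), 0)
  expect_equal(quantize_onset(0.1234, 1e4), 1234)
  expect_equal(quantize_onset(0.12344, 1e4), 1234)
  expect_equal(quantize_onset(0.12345, 1e4), 1235)   # exact tie -> away from zero
  expect_equal(quantize_onset(5e-5, 1e4), 1)
  expect_error(quantize_onset(-1), class = "neuromidi_negative_time")
})

test_that("variable-length quantities encode per the SMF spec", {
  enc <- neuromidi:::encode_vlq
  expect_equal(enc(0), as.raw(0x00))
  expect_equal(enc(127), as.raw(0x7F))
  expect_equal(enc(128), as.raw(c(0x81, 0x00)))
  expect_equal(enc(10000), as.raw(c(0xCE, 0x10)))
  expect_equal(enc(0x0FFFFFFF), as.raw(c(0xFF, 0xFF, 0xFF, 0x7F)))
})

test_that("a single note serializes to the hand-computed byte sequence", {
  nt <- note_table(track = 0L, channel = 0L, pitch = 60L, velocity = 100L,
                   onset_s = 1.0, offset_s = 1.01)
  bytes <- notes_to_smf(nt, sonification_config())
  # header: format 1, 2 chunks, ppq 5000; conductor with tempo 500000
  # (07 A1 20); note track named "track:0"; note-on at tick 10000
  # (VLQ CE 10), note-off 100 ticks later (VLQ 64)
  expected <- as.raw(c(
    0x4D, 0x54, 0x68, 0x64, 0x00, 0x00, 0x00, 0x06, 0x00, 0x01, 0x00, 0x02, 0x13, 0x88,
    0x4D, 0x54, 0x72, 0x6B, 0x00, 0x00, 0x00, 0x18,
    0x00, 0xFF, 0x03, 0x09, charToRaw("conductor"),
    0x00, 0xFF, 0x51, 0x03, 0x07, 0xA1, 0x20,
    0x00, 0xFF, 0x2F, 0x00,
    0x4D, 0x54, 0x72, 0x6B, 0x00, 0x00, 0x00, 0x18,
    0x00, 0xFF, 0x03, 0x07, charToRaw("track:0"),
    0xCE, 0x10, 0x90, 0x3C, 0x64,
    0x64, 0x80, 0x3C, 0x00,
    0x00, 0xFF, 0x2F, 0x00
  ))
  expect_identical(bytes, expected)
  p <- parse_smf(bytes)
  expect_equal(p$notes$onset_tick, 10000)
  expect_equal(p$notes$offset_tick, 10100)
})

test_that("an empty note table yields a valid header-plus-conductor file", {
  bytes <- notes_to_smf(note_table(), sonification_config())
  p <- parse_smf(bytes)
  expect_equal(nrow(p$notes), 0L)
  expect_equal(p$tempo_us_per_quarter, 500000)
  expect_equal(p$format, 1)
})

test_that("serialization is a pure function of notes and config", {
  nt <- random_note_table(50, seed = 11)
  cfg <- sonification_config(slowdown = 2)
  expect_identical(notes_to_smf(nt, cfg), notes_to_smf(nt, cfg))
})

test_that("round trip reproduces notes up to grid quantization (property)", {
  cfg <- sonification_config()
  for (seed in 1:8) {
    nt <- random_note_table(40, seed = seed)
    p <- parse_smf(notes_to_smf(nt, cfg))
    a <- canon(nt)
    b <- canon(p$notes)
    expect_equal(b[c("track", "channel", "pitch", "velocity")],
                 a[c("track", "channel", "pitch", "velocity")])
    expect_lt(max(abs(b$onset_s - a$onset_s)), 0.5 / cfg$grid_per_s + 1e-12)
    expect_lt(max(abs(b$offset_s - a$offset_s)), 0.5 / cfg$grid_per_s + 1e-12)
  }
})

test_that("round trip is exact for notes already on the grid", {
  cfg <- sonification_config()
  nt <- random_note_table(60, seed = 3, jitter = FALSE)
  p <- parse_smf(notes_to_smf(nt, cfg))
  expect_equal(canon(p$notes), canon(nt), tolerance = 1e-12)
})

test_that("slow-down scales the tempo meta-event and playback time, not ticks", {
  cfg <- sonification_config()
  cfg3 <- apply_slowdown(cfg, 3)
  expect_equal(cfg3$slowdown, 3)
  expect_identical(apply_slowdown(cfg, 1)$slowdown, cfg$slowdown)  # identity
  expect_error(apply_slowdown(cfg, 0.5), class = "neuromidi_bad_slowdown")

  nt <- random_note_table(30, seed = 5, jitter = FALSE)
  p1 <- parse_smf(notes_to_smf(nt, cfg))
  p3 <- parse_smf(notes_to_smf(nt, cfg3))
  expect_equal(p3$tempo_us_per_quarter, 1500000)     # parsed from the meta-event
  expect_identical(p3$notes$onset_tick, p1$notes$onset_tick)
  expect_equal(p3$notes$onset_s, 3 * p1$notes$onset_s)
  expect_equal(p3$duration_s, 3 * p1$duration_s)
})

test_that("tick times scale linearly with the tempo value", {
  nt <- note_table(0L, 0L, 60L, 100L, 2, 2.01)
  for (tempo in c(250000, 500000, 1000000)) {
    cfg <- sonification_config(tempo_us_per_quarter = tempo, ppq = NULL)
    p <- parse_smf(notes_to_smf(nt, cfg))
    expect_equal(p$notes$onset_s, 2, tolerance = 1e-9)
  }
  # doubled tempo at fixed ticks doubles real time
  cfg <- sonification_config()
  b <- notes_to_smf(nt, cfg)
  p <- parse_smf(b)
  cfg2 <- cfg; cfg2$slowdown <- 2
  p2 <- parse_smf(notes_to_smf(nt, cfg2))
  expect_identical(p2$notes$onset_tick, p$notes$onset_tick)
  expect_equal(p2$notes$onset_s, 2 * p$notes$onset_s)
})

test_that("percussion tracks are routed to channel 9 and programs are emitted", {
  nt <- note_table(track = c(0L, 1L), channel = 0L, pitch = c(40L, 60L),
                   velocity = 100L, onset_s = c(0.5, 0.6), offset_s = c(0.51, 0.61))
  cfg <- sonification_config(track_instruments = list(`0` = "percussion", `1` = 5))
  p <- parse_smf(notes_to_smf(nt, cfg))
  expect_equal(p$notes$channel[p$notes$track == 0L], 9L)
  expect_equal(p$notes$channel[p$notes$track == 1L], 0L)
})

test_that("malformed files raise named errors", {
  expect_error(parse_smf(as.raw(c(0x00, 0x01))), class = "neuromidi_malformed_smf")
  bytes <- notes_to_smf(note_table(0L, 0L, 60L, 100L, 1, 1.01), sonification_config())
  expect_error(parse_smf(bytes[1:30]), class = "neuromidi_malformed_smf")
  # a note-on with no matching note-off
  bad <- c(
    as.raw(c(0x4D, 0x54, 0x68, 0x64, 0, 0, 0, 6, 0, 0, 0, 1, 0x01, 0xE0)),
    as.raw(c(0x4D, 0x54, 0x72, 0x6B, 0, 0, 0, 8)),
    as.raw(c(0x00, 0x90, 0x3C, 0x64)),
    as.raw(c(0x00, 0xFF, 0x2F, 0x00))
  )
  expect_error(parse_smf(bad), class = "neuromidi_unpaired_note")
})

test_that("derived PPQ realizes non-default grids within one tick", {
  cfg <- sonification_config(grid_per_s = 2000, ppq = NULL)
  expect_equal(cfg$ppq, 1000L)                  # 500000 us/q * 2000 / 1e6
  nt <- note_table(0L, 0L, 60L, 100L, 0.1235, 0.1335)
  p <- parse_smf(notes_to_smf(nt, cfg))
  expect_lt(abs(p$notes$onset_s - 0.1235), 0.5 / 2000 + 1e-12)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sonification_config(grid_per_s = 0), class = "neuromidi_bad_config")
  expect_error(sonification_config(velocity = 0), class = "neuromidi_bad_velocity")
  expect_error(sonification_config(slowdown = 0.5), class = "neuromidi_bad_slowdown")
  expect_error(sonification_config(slowdown = 40), class = "neuromidi_bad_config")
  cfg <- sonification_config()
  expect_equal(cfg$tempo_us_per_quarter / cfg$ppq, 100)  # 100 us ticks = grid step
})
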