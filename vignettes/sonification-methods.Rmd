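---
title: "Methods: encoding event data as Standard MIDI Files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding event data as Standard MIDI Files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromidi)
```

## The conversion model

`neuromidi` treats any discrete neural or behavioral recording as an
*event stream*: a time-sorted sequence of (identity, time) pairs. Two
input routes produce this representation — spike-sorting output in the
Kilosort/Phy convention (sample indices divided by the declared sampling
rate) and generic two-column event files — and everything downstream
operates on it uniformly.

Conversion to sound is a pure function from events to a six-column note
table (track, channel, pitch, velocity, onset, offset) and from there to
Standard MIDI File bytes. The two pitch policies are:

- **One pitch per unit.** Units are ordered (ascending id by default; a
  custom ordering function, e.g. by probe depth, can be supplied) and
  assigned consecutive degrees of a musical scale. Distinct units always
  receive distinct pitches, so a listener can track individual cells the
  way an anatomist tracks pseudocolored processes.
- **Log-rate pitch.** For rhythm streams, each event's instantaneous rate
  (reciprocal of the preceding inter-event interval) is interpolated
  linearly in log rate between `(r_min, p_lo)` and `(r_max, p_hi)`.
  The log is deliberate: breathing states are frequency *bands*, and a
  log map gives each band a pitch interval whose width reflects its
  frequency ratio, matching how pitch perception itself is logarithmic.

The first event of a rhythm stream has no preceding interval; it is
assigned the second event's rate rather than dropped, so the first drum
hit of a session still sounds. When rate bounds are not supplied they
default to the 1st and 99th percentiles of the observed rates, which keeps
a handful of outlier intervals (e.g. across a pause) from compressing the
useful pitch range; explicit bounds always win.

## Parameters and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `grid_per_s` | 10⁴ | points/s | onset quantization grid; 100 µs is far below audible timing differences and exact in ticks |
| `duration_s` | 0.010 | s | constant note length; short enough that spikes read as percussive events |
| `velocity` | 100 | 1–127 | constant loudness; variable velocity is deliberately unused |
| `tempo_us_per_quarter` | 500000 | µs | 120 BPM nominal tempo |
| `ppq` | derived (5000) | ticks/quarter | smallest PPQ ≤ 32767 with at least one tick per grid step: `ceiling(tempo·grid/10⁶)` |
| `slowdown` | 1 | — | playback stretch; demonstrations use 3 |
| scale | C major pentatonic, root 48 | — | five degrees per octave minimize dissonance among concurrent units |
| drum pitch band | 36–60 | pitch | two octaves around the low-mid register where kick-drum samples read clearly |

## Numerical choices

- **Rounding.** Grid quantization and pitch interpolation round to the
  nearest integer with ties away from zero (`floor(|x| + 0.5)`), not
  banker's rounding — determinism and a simple mental model beat bias
  correction at this scale. Scale snapping breaks ties toward the lower
  pitch.
- **Ticks.** The grid is realized in ticks: at the defaults one tick =
  500000/5000 = 100 µs = exactly one grid step, so quantized onsets are
  integers in both representations and the round trip through a file is
  exact. Slow-down multiplies only the serialized tempo meta-event; note
  ticks are bit-identical across slow-down factors, which is also how
  DAWs separate musical time from wall-clock time.
- **Overlap rule.** Two notes of the same (track, channel, pitch) may not
  overlap, because downstream note-on/note-off pairing would otherwise be
  ambiguous. A later same-pitch onset truncates the earlier note's offset;
  truncation changes durations, never note counts. Notes starting at the
  same instant on the same pitch cannot be truncated to a positive
  duration and are left coincident; the writer serializes them FIFO so
  they still pair cleanly. A note whose quantized offset would not fall
  after its onset is extended to one tick.
- **Serialization order.** At equal ticks, note-offs precede program
  changes precede note-ons, then (channel, pitch) — no stuck notes, and
  byte output is a pure function of (notes, config).
- **Degenerate inputs.** An empty stream yields a valid header-plus-
  conductor file; a constant-rate stream (zero rate spread) maps to a
  single pitch; streams of length < 2 cannot define a rate and error.

## Design decisions

- **Octave fitting for large populations.** Five scale degrees per octave
  mean 52 units span 125 semitones — more than fits above the mid-keyboard
  default root of 48. `assign_unit_pitches(fit_root = TRUE)` (used by the
  conversion pipeline) lowers the root by whole octaves until the
  population fits, which changes register but neither injectivity nor
  scale membership. Populations that cannot fit even from the bottom
  octave are an error rather than a silent wrap.
- **Curation default.** When a `cluster_group.tsv` is present and no
  labels are requested, only `"good"` units are kept — the standard
  post-curation workflow — while uncurated directories load in full.
  Whether to sonify curated units only is exposed (`keep_labels`) because
  reasonable sessions differ.
- **Percussion routing.** Tracks flagged `"percussion"` are routed to MIDI
  channel 10 (zero-indexed 9), the General-MIDI drum channel, so generic
  players render drum sounds without a custom instrument map; all other
  tracks keep the constant channel 0.
- **Config files are YAML.** The configuration schema (global settings
  plus one section per track) is serialized as YAML, a format with a
  mature parser in the R ecosystem; the schema, not the surface syntax,
  is the contract. Flags beat file values beat defaults.
- **Track indices survive round trips** via `track:<n>` name meta-events,
  so a parsed file reports the same track structure the note table had.

## What the synthetic generator emulates

The generator exists so every pipeline stage is testable without
recordings. It emulates event *timing* structure only:

- **Poisson population.** 52 independent homogeneous Poisson units at
  0.5–3 Hz stand in for spontaneous olfactory-bulb-like background
  activity in the `"grooming"` scenario.
- **State-switching breathing.** A semi-Markov chain over breathing
  states — exponential dwells (mean 20 s), uniform choice among the other
  states — with inter-inhalation intervals drawn uniformly from the
  reciprocal of the state's rate band (slow 2–4 Hz, intermediate
  "grooming" 5–8 Hz, fast 9–13 Hz; the bands are disjoint by default).
  Switches take effect at an inhalation, so every interval is generated
  wholly by one state and the inhalation ending it carries that state's
  label; the first inhalation inherits the second's label, mirroring the
  first-event rate convention. This makes state recovery from drum pitch
  bands exact rather than statistical, which is the property the
  recovery test checks.
- **Sequential responses.** For each trigger (gaze shift or blink), unit
  *k* fires once at `trigger + 20 ms + k·10 ms + N(0, 1 ms)` — the
  minimal structure carrying a coarse-to-fine latency ladder.

What it does **not** emulate: refractoriness, rate co-modulation between
breathing and spiking, bursting, non-stationarity, unit waveform or
amplitude structure, or realistic sniff-cycle shape. Passing tests
therefore demonstrate that the *encoding* is faithful and reversible on
data with the right event statistics, not that any biological claim holds
on real recordings.

Fixtures are written in exactly the formats the readers consume (NPY
sample indices at 30 kHz — the common extracellular convention — plus
cluster ids, `params.py`, curation labels, event CSVs) along with a
`ground_truth.json` sidecar holding the hidden state. Everything is
reproducible from the seed, and generators restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script use 30–120 s sessions, 52-unit
populations, 100 randomized 25-note tables for round-trip checks, and
1000-point rate sweeps — sizes at which every structural property checked
(injectivity, scale membership, grid exactness, byte determinism, exact
state recovery) is already fully exercised; the encoding is linear in
event count, and longer sessions change nothing but runtime.

## Known limitations

- 64-bit sample indices are decoded into doubles (exact to 2⁵³; about
  9,500 years at 30 kHz), and big-endian or Fortran-order NPY inputs are
  rejected rather than converted.
- SMPTE time division in parsed MIDI files is not supported (PPQ only).
- A population larger than the scale can represent in pitches 0–127
  (54 units for a pentatonic scale rooted at 0) is an error; downmixing
  many units onto shared pitches is deliberately out of scope.
- Variable velocity and variable note length are unused by design; both
  are natural extensions.
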