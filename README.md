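# neuromidi

Sonification of neural and behavioral event data as Standard MIDI Files.

High-density recordings produce event streams — spikes from dozens of
units, inhalation times, gaze shifts, blinks — that are hard to eye-test
directly. `neuromidi` renders such discrete events as music: each unit
gets its own pitch on a musical scale (the auditory analog of anatomical
pseudocolor), rhythm rates are mapped to pitch on a log scale, and the
result is written as a format-1 Standard MIDI File that any MIDI-capable
media player or digital audio workstation can play alongside the session
video. The intended users are systems neuroscientists who want to browse
their recordings by ear as well as by eye.

## The encoding

Every note is a row of a six-column table

```
track  channel  pitch  velocity  onset_s  offset_s
```

built from events as follows:

- **Identity → pitch.** For a population of units, unit *i* (in id order,
  or any custom ordering such as probe depth) receives the *i*-th degree of
  a musical scale: `pitch = root + 12·⌊i/k⌋ + degrees[i mod k]` for a scale
  with *k* degrees per octave. The default is C major pentatonic
  (degrees 0, 2, 4, 7, 9), which minimizes dissonance among concurrently
  sounding units. The assignment is injective — one pitch per neuron.
- **Rate → pitch.** For rhythm streams (e.g. inhalations), the
  instantaneous rate `r_i = 1/(t_i − t_{i−1})` is mapped linearly in
  log rate: `p = p_lo + (p_hi − p_lo)·(ln r − ln r_min)/(ln r_max − ln r_min)`,
  clamped and rounded, so equal frequency *ratios* move the pitch by equal
  steps. Faster sniffing literally sounds higher.
- **Timing.** Onsets are quantized to a grid of 10⁴ points per second;
  every note lasts a constant 10 ms (a later same-pitch onset truncates
  it); velocity is a constant 100. In the file, one tick = 100 µs
  (120 BPM, 5000 ticks per quarter note), so the grid is exact in ticks.
- **Slow-down.** Playback at, say, 1/3 speed is encoded purely in the
  tempo meta-event (500000 → 1500000 µs per quarter); tick values are
  untouched, so the data and the playback time scale stay separate.

Inputs are either spike-sorting output in the Kilosort/Phy convention
(`spike_times.npy`, `spike_clusters.npy`, `params.py`,
optional `cluster_group.tsv`; curated `"good"` units are kept by default)
or generic two-column event files (`event_id,time_s`).

## Worked example

Generate a synthetic 120 s session (state-switching breathing plus 52
Poisson units), convert it to MIDI at 1/3 speed, and inspect the result:

```r
library(neuromidi)
fx <- make_session_fixture("demo/session", seed = 42,
                           scenario = "grooming", duration_s = 120)
res <- cmd_convert(
  sources = c("demo/session/inhalations.csv", "demo/session/sorting"),
  out = "demo/session.mid", slowdown = 3)
print(res$notes)
print(res$config)
cmd_inspect("demo/session.mid")
```

```
<note_table> 10544 notes on 2 track(s), pitches [0, 122], t in [0.01623, 120] s
<sonification_config> grid 10000/s, note 10 ms, velocity 100,
  tempo 500000 us/quarter, ppq 5000 (tick = 100 us), slowdown 3x
  track 0 -> percussion
  track 1 -> 0
format 1 SMF, ppq 5000, tempo 1.5e+06 us/quarter
10544 notes, duration 359.933 s
  track 0: 649 notes, pitches 36-60
  track 1: 9895 notes, pitches 0-122
```

Track 0 is the breathing rhythm as a percussion (channel 10) track: 649
inhalations whose pitch (36–60) encodes the log sniff rate, so the three
breathing states occupy three audibly distinct pitch bands. Track 1 is the
spiking population on a piano program: 52 units → 52 distinct pentatonic
pitches. The 120 s session plays back over 359.9 s — exactly 3× slower —
because only the tempo meta-event was scaled. A `session.manifest.json`
written next to the output records inputs, settings, seed, and the output
file's checksum; re-running the same conversion reproduces the `.mid`
byte-for-byte.

The same commands are available from a shell:

```sh
neuromidi simulate grooming --seed 42 --out demo/session
neuromidi convert demo/session/inhalations.csv demo/session/sorting \
    --out demo/session.mid --slowdown 3
neuromidi inspect demo/session.mid
```

(The `neuromidi` script is installed under the package's `exec/`
directory.)

## Scope

`neuromidi` emits standard `.mid` files; audio synthesis (SoundFonts),
video handling, and spike sorting itself are deliberately out of scope —
upstream sorters produce the inputs, and downstream players and DAWs
render the sound.
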