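Package: neuromidi
Title: Sonification of Neural and Behavioral Event Data as Standard MIDI Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts discrete neural and behavioral event data (spike-sorting
    output in the Kilosort/Phy convention, or generic two-column event files)
    into Standard MIDI Files for audio-visual browsing in media players and
    digital audio workstations. Each recorded unit is assigned a unique pitch
    on a musical (by default pentatonic) scale; continuous rhythm rates such as
    the sniff rate are mapped to pitch on a logarithmic scale. Notes are
    quantized to a configurable time grid (default 10^4 points per second),
    rendered as format-1 MIDI with a tempo-based slow-down for slower-than-real-
    time playback, and written alongside a reproducibility manifest. Includes a
    seeded synthetic-data generator (Poisson spike trains, state-switching
    breathing rhythms, trigger-locked sequential firing) so the whole pipeline
    is testable without recordings, and a command-line interface with convert,
    simulate, and inspect subcommands.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
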