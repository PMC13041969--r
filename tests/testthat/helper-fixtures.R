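# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is read from stored data.

# Write a minimal spike-sorting-convention directory.
make_sorting_dir <- function(dir, samples, clusters, rate = 30000, groups = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  neuromidi:::write_npy(samples, file.path(dir, "spike_times.npy"), dtype = "uint64")
  neuromidi:::write_npy(clusters, file.path(dir, "spike_clusters.npy"), dtype = "int32")
  writeLines(sprintf("sample_rate = %s.", format(rate)), file.path(dir, "params.py"))
  if (!is.null(groups)) {
    writeLines(c("cluster_id\tgroup",
                 sprintf("%s\t%s", names(groups), unname(groups))),
               file.path(dir, "cluster_group.tsv"))
  }
  dir
}

# Random non-overlapping note table: onsets near grid multiples spaced at
# least one note length apart, so same-pitch notes never overlap and the
# round trip is exact up to grid quantization.
random_note_table <- function(n, seed, jitter = TRUE) {
  neuromidi:::with_seed(seed, {
    k <- sort(sample.int(50000, n))
    onset <- k * 0.01
    if (jitter) onset <- onset + stats::runif(n, -4e-5, 4e-5)
    note_table(
      track = sample(0:3, n, replace = TRUE),
      channel = 0L,
      pitch = sample(0:127, n, replace = TRUE),
      velocity = sample(1:127, n, replace = TRUE),
      onset_s = onset,
      offset_s = onset + 0.01
    )
  })
}

# Canonical ordering for comparing note tables whose onsets may tie.
canon <- function(nt) {
  nt <- as.data.frame(nt)[, c("track", "channel", "pitch", "velocity",
                              "onset_s", "offset_s")]
  nt <- nt[order(round(nt$onset_s, 6), nt$track, nt$channel, nt$pitch), ]
  rownames(nt) <- NULL
  nt
}
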