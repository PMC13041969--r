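# SpikeTable: per-spike unit assignments and times derived from
# spike-sorting output, plus the sampling rate the sample->second conversion
# came from and any curation labels attached during manual review.

#' Construct a spike table
#'
#' @param unit_ids Integer cluster identity per spike.
#' @param times_s Spike times in seconds, one per unit id.
#' @param sampling_rate_hz Positive sampling rate the times were derived at.
#' @param curation_labels Optional named character vector mapping unit id to
#'   a curation label (`"good"`, `"mua"`, `"noise"`, ...).
#' @return An object of class `spike_table`: a data frame with columns
#'   `unit_id` and `time_s` sorted by time, with attributes
#'   `sampling_rate_hz` and `curation_labels`.
#' @export
spike_table <- function(unit_ids = integer(), times_s = numeric(),
                        sampling_rate_hz = 30000, curation_labels = NULL) {
  if (length(unit_ids) != length(times_s)) {
    nm_stop("length_mismatch", "unit_ids (%d) and times_s (%d) differ in length",
            length(unit_ids), length(times_s))
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    nm_stop("bad_sampling_rate", "sampling_rate_hz must be a single positive number")
  }
  times_s <- as.double(times_s)
  if (anyNA(times_s) || any(!is.finite(times_s)) || any(times_s < 0)) {
    nm_stop("negative_time", "spike times must be finite and non-negative")
  }
  ord <- order(times_s)
  out <- data.frame(unit_id = as.integer(unit_ids)[ord], time_s = times_s[ord])
  attr(out, "sampling_rate_hz") <- as.double(sampling_rate_hz)
  attr(out, "curation_labels") <- curation_labels
  class(out) <- c("spike_table", "data.frame")
  out
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("<spike_table> %d spikes, %d units @ %g Hz sampling\n",
              nrow(x), length(unique(x$unit_id)), attr(x, "sampling_rate_hz")))
  invisible(x)
}

#' Read spike-sorting output in the Kilosort/Phy convention
#'
#' Loads a sorting directory containing `spike_times.npy` (sample indices),
#' `spike_clusters.npy` (per-spike cluster ids), a `params.py` declaring
#' `sample_rate`, and optionally `cluster_group.tsv` with curation labels
#' (columns `cluster_id`, `group`). Times are converted to seconds as
#' `sample_index / sampling_rate_hz`.
#'
#' When a curation table is present and `keep_labels` is not given, only
#' units labeled `"good"` are kept (the standard post-curation workflow);
#' with no curation table all spikes are kept. Pass `keep_labels` explicitly
#' to override either default.
#'
#' @param dir Sorting output directory.
#' @param keep_labels Optional character vector of curation labels to keep.
#' @param sampling_rate_hz Optional override for the rate declared in
#'   `params.py` (an explicit value always wins).
#' @return A [spike_table()] sorted by time.
#' @export
read_spike_sorting_output <- function(dir, keep_labels = NULL, sampling_rate_hz = NULL) {
  if (!dir.exists(dir)) nm_stop("missing_file", "sorting directory not found: %s", dir)
  f_times <- file.path(dir, "spike_times.npy")
  f_clust <- file.path(dir, "spike_clusters.npy")
  for (f in c(f_times, f_clust)) {
    if (!file.exists(f)) nm_stop("missing_file", "required file missing: %s", f)
  }

  samples <- read_npy(f_times)
  clusters <- read_npy(f_clust)
  if (length(samples) != length(clusters)) {
    nm_stop("length_mismatch",
            "spike_times.npy has %d entries but spike_clusters.npy has %d",
            length(samples), length(clusters))
  }

  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- read_params_sample_rate(file.path(dir, "params.py"))
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    nm_stop("bad_sampling_rate", "sampling rate must be positive, got %s",
            format(sampling_rate_hz))
  }

  labels <- read_cluster_groups(file.path(dir, "cluster_group.tsv"))
  if (!is.null(labels) && is.null(keep_labels)) keep_labels <- "good"
  if (!is.null(labels) && !is.null(keep_labels)) {
    keep_units <- as.integer(names(labels)[labels %in% keep_labels])
    sel <- clusters %in% keep_units
    samples <- samples[sel]
    clusters <- clusters[sel]
  }

  spike_table(unit_ids = clusters, times_s = samples / sampling_rate_hz,
              sampling_rate_hz = sampling_rate_hz, curation_labels = labels)
}

# params.py is a tiny python assignment file; the only field we need is
# sample_rate (a bare number, possibly with a trailing dot).
read_params_sample_rate <- function(path) {
  if (!file.exists(path)) {
    nm_stop("missing_file", "params.py not found (%s); pass sampling_rate_hz explicitly", path)
  }
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^\\s*sample_rate\\s*=", lines, value = TRUE)
  if (length(hit) == 0L) {
    nm_stop("bad_sampling_rate", "no sample_rate declaration in %s", path)
  }
  val <- sub("^\\s*sample_rate\\s*=\\s*", "", hit[[1L]])
  val <- sub("#.*$", "", val)
  rate <- suppressWarnings(as.numeric(sub("\\.$", "", trimws(val))))
  if (is.na(rate) || rate <= 0) {
    nm_stop("bad_sampling_rate", "sample_rate in %s is not a positive number: %s", path, val)
  }
  rate
}

read_cluster_groups <- function(path) {
  if (!file.exists(path)) return(NULL)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  id_col <- intersect(c("cluster_id", "id"), names(tab))
  grp_col <- intersect(c("group", "KSLabel", "label"), names(tab))
  if (length(id_col) == 0L || length(grp_col) == 0L) {
    nm_stop("malformed_row", "curation table %s lacks cluster_id/group columns", path)
  }
  stats::setNames(as.character(tab[[grp_col[[1L]]]]), as.character(tab[[id_col[[1L]]]]))
}

#' Convert a spike table to an event stream
#'
#' Unifies both input routes on one representation: each spike becomes one
#' event whose identity is the unit id.
#'
#' @param spikes A [spike_table()].
#' @return An [event_stream()] with one event per spike, order preserved.
#' @export
spikes_to_event_stream <- function(spikes) {
  stopifnot(inherits(spikes, "spike_table"))
  event_stream(labels = spikes$unit_id, times = spikes$time_s)
}
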