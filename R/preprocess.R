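# Preprocessing: filtering, downsampling, referencing, epoching, baseline
# extraction and per-slice normalization.

#' Multichannel recording
#'
#' Container for a continuous multichannel voltage recording: a channels x
#' samples matrix, its sampling rate, the trial-onset times, and an optional
#' sensor-to-region assignment.  Sample 1 is taken to occur at time 0, so
#' the sample at time t (seconds) has 0-based index `round(t * fs)`.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param onsets trial-onset times in seconds; must be strictly increasing
#'   and lie inside the recording.
#' @param region_of optional integer vector assigning each channel to a
#'   region (required for region-level analyses).
#' @param labels optional channel labels.
#' @return An object of class `fc_recording`.
#' @export
fc_recording <- function(data, fs, onsets = numeric(0), region_of = NULL,
                         labels = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop_arg("fs must be positive")
  onsets <- as.numeric(onsets)
  if (length(onsets) && any(diff(onsets) <= 0)) {
    stop_arg("onsets must be strictly increasing")
  }
  dur <- ncol(data) / fs
  if (length(onsets) && (min(onsets) < 0 || max(onsets) > dur)) {
    stop_arg("onsets must lie inside the recording (0 to ", round(dur, 3), " s)")
  }
  if (!is.null(region_of) && length(region_of) != nrow(data)) {
    stop_arg("region_of must have one entry per channel")
  }
  structure(list(
    data = data, fs = fs, onsets = onsets,
    region_of = if (is.null(region_of)) NULL else as.integer(region_of),
    labels = labels %||% paste0("s", seq_len(nrow(data)))
  ), class = "fc_recording")
}

#' @export
print.fc_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples (%.1f s at %g Hz), %d trials\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
              length(x$onsets)))
  if (!is.null(x$region_of)) {
    cat("  regions:", length(unique(x$region_of)), "\n")
  }
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the
#' given order to every channel.  Filtering twice cancels the phase
#' response, so filtered features keep their latency (no group delay), at
#' the cost of squaring the magnitude response.
#'
#' @param rec an [fc_recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order filter order of a single pass (default 3).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = 3) {
  stopifnot(inherits(rec, "fc_recording"))
  if (low <= 0 || high <= low || high >= rec$fs / 2) {
    stop_arg("band must satisfy 0 < low < high < fs/2 (fs = ", rec$fs, " Hz)")
  }
  filt <- signal::butter(order, c(low, high) / (rec$fs / 2), "pass")
  for (i in seq_len(nrow(rec$data))) {
    rec$data[i, ] <- signal::filtfilt(filt, rec$data[i, ])
  }
  attr(rec, "filter") <- list(low = low, high = high, order = order)
  rec
}

#' Integer decimation to a lower sampling rate
#'
#' Keeps every `fs / target_fs`-th sample.  No additional anti-alias filter
#' is applied: the intended use is after [bandpass_filter()] with an upper
#' edge below the new Nyquist frequency.  Onset times are in seconds and are
#' unchanged.
#'
#' @param rec an [fc_recording()].
#' @param target_fs new sampling rate; must divide `rec$fs` exactly.
#' @return The decimated recording.
#' @export
downsample <- function(rec, target_fs = 200) {
  stopifnot(inherits(rec, "fc_recording"))
  ratio <- rec$fs / target_fs
  if (ratio < 1 || abs(ratio - round(ratio)) > 1e-9) {
    stop_arg("target_fs (", target_fs, ") must divide fs (", rec$fs,
             ") exactly; resampling by non-integer ratios is not supported")
  }
  rec$data <- rec$data[, seq(1L, ncol(rec$data), by = round(ratio)), drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Common average reference
#'
#' Subtracts the across-channel mean from every channel at each time step,
#' so the channel mean of the output is exactly zero at every sample.
#'
#' @param rec an [fc_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "fc_recording"))
  if (nrow(rec$data) < 2L) {
    stop_arg("common average reference needs at least 2 channels")
  }
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), `-`)
  rec
}

# z-score a vector, refusing silently flat slices.
.zscore <- function(x, what) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_arg("flat (zero-variance) data in ", what,
             "; check for dead channels before epoching")
  }
  (x - mean(x)) / s
}

#' Extract normalized trial epochs
#'
#' Cuts the recording into per-trial epochs aligned to the trial onsets and
#' z-scores every (epoch, sensor, trial) slice.  Two epoch schemes are
#' supported:
#'
#' * `"before_after"`: two non-overlapping epochs per trial, the
#'   `half_width` seconds before the onset (`"before"`, half-open
#'   `[onset - hw, onset)`) and the `half_width` seconds from the onset
#'   (`"after"`, `[onset, onset + hw)`).
#' * `"sliding"`: windows of `width` seconds whose midpoints run from
#'   `-(half_width - width/2)` to `+(half_width - width/2)` seconds around
#'   the onset in steps of `step` (defaults give 161 windows of 200 ms at a
#'   5 ms step); epochs are labeled by their midpoints.
#'
#' @param rec a preprocessed [fc_recording()] with trial onsets.
#' @param scheme `"before_after"` or `"sliding"`.
#' @param half_width trial half-width in seconds (default 0.5).
#' @param width,step sliding-window width and step in seconds.
#' @return An `fc_epochs` object: `data` is an E x T x N x L array (epochs x
#'   time points x sensors x trials) in which every (epoch, sensor, trial)
#'   slice has mean 0 and standard deviation 1, plus `epoch_labels`,
#'   `epoch_mid` (window midpoints in seconds relative to onset), `fs`, and
#'   the region map carried over from the recording.
#' @export
extract_epochs <- function(rec, scheme = c("before_after", "sliding"),
                           half_width = 0.5, width = 0.2, step = 0.005) {
  stopifnot(inherits(rec, "fc_recording"))
  scheme <- match.arg(scheme)
  fs <- rec$fs
  L <- length(rec$onsets)
  if (L == 0L) stop_arg("recording has no trial onsets")
  N <- nrow(rec$data)

  if (scheme == "before_after") {
    tw <- round(half_width * fs)
    offsets <- list(-(tw:1), 0:(tw - 1L))
    labels <- c("before", "after")
    mids <- c(-half_width / 2, half_width / 2)
  } else {
    tw <- round(width * fs)
    mids <- seq(-(half_width - width / 2), half_width - width / 2, by = step)
    half <- round(width * fs / 2)
    offsets <- lapply(mids, function(m) {
      s <- round(m * fs) - half
      s:(s + tw - 1L)
    })
    labels <- sprintf("%+.3f", mids)
  }
  E <- length(offsets)
  onset_idx <- round(rec$onsets * fs) + 1L
  lo <- min(vapply(offsets, min, 0L))
  hi <- max(vapply(offsets, max, 0L))
  bad <- which(onset_idx + lo < 1L | onset_idx + hi > ncol(rec$data))
  if (length(bad)) {
    stop_arg("trial ", bad[1L], " (onset ", rec$onsets[bad[1L]],
             " s) lies too close to the recording edge for the requested epochs")
  }

  arr <- array(NA_real_, dim = c(E, tw, N, L))
  for (e in seq_len(E)) {
    off <- offsets[[e]]
    for (l in seq_len(L)) {
      seg <- rec$data[, onset_idx[l] + off, drop = FALSE]   # N x T
      for (nn in seq_len(N)) {
        arr[e, , nn, l] <- .zscore(seg[nn, ], sprintf(
          "epoch '%s', sensor %d, trial %d", labels[e], nn, l))
      }
    }
  }
  structure(list(
    data = arr, epoch_labels = labels, epoch_mid = mids, fs = fs,
    region_of = rec$region_of, labels = rec$labels
  ), class = "fc_epochs")
}

#' @export
print.fc_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched data: %d epochs x %d time points x %d sensors x %d trials\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Extract normalized baseline intervals
#'
#' Collects the maximal set of non-overlapping intervals of `duration`
#' seconds that stay at least `guard` seconds away from every trial epoch
#' (taken to span `onset - half_width` to `onset + half_width`), greedily
#' packed left to right, and z-scores every (sensor, interval) slice.  These
#' task-free segments feed the bootstrap null distribution of the coupling
#' statistics; their count K may (and usefully does) exceed the trial count.
#'
#' @param rec a preprocessed [fc_recording()].
#' @param duration interval length in seconds; must equal the epoch duration
#'   used for the observed statistics.
#' @param guard minimum distance from any trial epoch, in seconds.
#' @param half_width trial half-width in seconds (default 0.5).
#' @return An `fc_baseline` object: `data` is a T x N x K array (time x
#'   sensors x intervals), each (sensor, interval) slice z-scored, plus the
#'   interval start times.
#' @export
extract_baseline_intervals <- function(rec, duration = 0.5, guard = 0,
                                       half_width = 0.5) {
  stopifnot(inherits(rec, "fc_recording"))
  if (guard < 0) stop_arg("guard must be non-negative")
  fs <- rec$fs
  tw <- round(duration * fs)
  total <- ncol(rec$data) / fs
  zones <- cbind(rec$onsets - half_width - guard, rec$onsets + half_width + guard)

  starts <- numeric(0)
  t <- 0
  while (t + duration <= total + 1e-9) {
    hit <- which(t < zones[, 2] & (t + duration) > zones[, 1])
    if (length(hit)) {
      t <- max(zones[hit, 2])
    } else {
      starts <- c(starts, t)
      t <- t + duration
    }
  }
  if (!length(starts)) {
    stop_arg("no baseline intervals could be extracted; record a longer ",
             "baseline period or reduce the guard")
  }
  K <- length(starts)
  N <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(tw, N, K))
  idx0 <- round(starts * fs) + 1L
  for (k in seq_len(K)) {
    seg <- rec$data[, idx0[k]:(idx0[k] + tw - 1L), drop = FALSE]
    for (nn in seq_len(N)) {
      arr[, nn, k] <- .zscore(seg[nn, ], sprintf(
        "baseline interval %d, sensor %d", k, nn))
    }
  }
  structure(list(
    data = arr, starts = starts, fs = fs,
    region_of = rec$region_of, labels = rec$labels
  ), class = "fc_baseline")
}

#' @export
print.fc_baseline <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Baseline data: %d intervals x %d time points x %d sensors\n",
              d[3], d[1], d[2]))
  invisible(x)
}
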