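# Synthetic multichannel sessions with known ground-truth coupling.
#
# Each sensor trace is the sum of four components: pink (1/f) noise, white
# sensor noise, an optional "constant" 2-50 Hz component with a part shared
# by all sensors (persistent, task-unrelated correlations), and an 8-25 Hz
# trial component.  During each trial epoch the trial component of coupled
# sensors follows a shared band-limited signal, faded in and out by a
# variance-preserving window; outside trials it is fully uncorrelated.

# ---- spectral synthesis -----------------------------------------------------

# Positive-frequency bin grid for an n-sample signal (excludes DC/Nyquist).
.synth_freqs <- function(n, fs) {
  nb <- floor((n - 1) / 2)
  (1:nb) * fs / n
}

# Gaussian noise synthesized in the frequency domain with amplitude envelope
# `amp(f)` over positive frequencies; DC and Nyquist bins are zeroed so the
# signal has exactly zero mean.  Returns the time signal plus the per-bin
# power, from which filtered variances are computed exactly.
.synth_noise <- function(n, fs, amp) {
  nb <- floor((n - 1) / 2)
  f <- (1:nb) * fs / n
  A <- amp(f)
  Z <- complex(real = rnorm(nb), imaginary = rnorm(nb)) / sqrt(2)
  X <- A * Z
  spec <- complex(length.out = n)
  spec[2:(nb + 1)] <- X
  spec[n:(n - nb + 1)] <- Conj(X)
  x <- Re(fft(spec, inverse = TRUE)) / n
  list(x = x, pow = Mod(X)^2)   # var(x) = 2 * sum(pow) / n^2
}

# Squared-magnitude response of a two-pass (forward-backward) IIR filter at
# frequencies f: one pass multiplies amplitudes by |H(f)|, two passes by
# |H(f)|^2, so the power (variance) gain is |H(f)|^4.
.filtfilt_power_gain <- function(filt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den)^4)
}

#' Pink (1/f) noise
#'
#' Zero-mean, unit-variance noise whose power spectral density falls off as
#' 1/f, the broadband background characteristic of brain voltage recordings.
#' Synthesized in the frequency domain by shaping white Gaussian noise with a
#' `1/sqrt(f)` amplitude envelope (DC bin zeroed), so the spectral slope is
#' exact in expectation.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate in Hz.
#' @param seed optional RNG seed; the same seed yields the identical vector.
#' @return Numeric vector of length `n_samples` with sample variance 1.
#' @export
make_pink_noise <- function(n_samples, fs, seed = NULL) {
  if (n_samples < 2) stop_arg("n_samples must be at least 2")
  with_seed_or_not(seed, {
    x <- .synth_noise(n_samples, fs, function(f) 1 / sqrt(f))$x
    x / sd(x)
  })
}

#' Band-limited Gaussian noise
#'
#' Zero-mean, unit-variance noise with spectral content confined to
#' `[band[1], band[2]]` Hz, synthesized in the frequency domain (bins outside
#' the band are exactly zero).
#'
#' @inheritParams make_pink_noise
#' @param band length-2 numeric, `0 < band[1] < band[2] < fs/2`.
#' @return Numeric vector of length `n_samples` with sample variance 1.
#' @export
make_bandlimited_noise <- function(n_samples, fs, band, seed = NULL) {
  if (n_samples < 2) stop_arg("n_samples must be at least 2")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2) {
    stop_arg("band must satisfy 0 < low < high < fs/2")
  }
  with_seed_or_not(seed, {
    x <- .synth_noise(n_samples, fs, function(f) as.numeric(f >= band[1] & f <= band[2]))$x
    x / sd(x)
  })
}

#' Variance-preserving trial window
#'
#' Weight vector `w(t)` in `[0, 1]` that rises from 0, holds a peak of 1
#' around the epoch midpoint, and fades back to 0 (a tapered-cosine window
#' with taper fraction `taper`).  The shared trial signal `c(t)` is injected
#' into a background `u(t)` of the same band and variance as
#' `w(t) c(t) + sqrt(1 - w(t)^2) u(t)`, so the pointwise variance of the
#' band component is constant throughout the recording.
#'
#' @param epoch_samples number of samples in the epoch (>= 3).
#' @param taper fraction of the window spent fading in and out (0 < taper
#'   <= 1; 1 gives a Hann bump with no plateau).  The default 0.5 leaves the
#'   shared signal at full strength over the middle half of the epoch.
#' @return Numeric vector of length `epoch_samples`, `w[1] = w[end] = 0`,
#'   `max(w) = 1` at the epoch midpoint.
#' @export
make_trial_window <- function(epoch_samples, taper = 0.5) {
  n <- as.integer(epoch_samples)
  if (n < 3L) stop_arg("epoch_samples must be at least 3")
  if (taper <= 0 || taper > 1) stop_arg("taper must lie in (0, 1]")
  t <- (seq_len(n) - 1L) / (n - 1L)
  w <- rep(1, n)
  lo <- t < taper / 2
  hi <- t > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / taper - 1)))
  w
}

# ---- configuration ----------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of a synthetic session.  The defaults reproduce the reference
#' study conditions: 100 trials of 1 s (500 ms before + 500 ms after task
#' onset), a 200 s leading baseline that yields exactly 400 non-overlapping
#' 500 ms baseline intervals, and generation at 600 Hz so that downsampling
#' to the 200 Hz analysis rate is an exact integer decimation.
#'
#' `snr` is the per-edge signal-to-noise ratio: the variance of one edge's
#' shared trial-band signal at the window peak divided by the combined
#' variance of the pink and white background, both measured in the analysis
#' band (see Details).  A sensor carrying k edges therefore has total
#' task-related SNR `k * snr`.  `correlation_ratio` is the ratio of that
#' per-edge trial variance to the variance of the constant (persistent)
#' correlated component shared by all sensors; `NULL` disables the constant
#' component entirely.
#'
#' @details All component variances are calibrated in the analysis band:
#' each synthesized component is scaled so that its variance *after* the
#' nominal preprocessing filter (`filter_band`, zero-phase Butterworth of
#' order `filter_order`) equals its target.  This makes the effective SNR of
#' the preprocessed data independent of the raw generation rate (broadband
#' white noise would otherwise lose most of its variance to the band-pass
#' filter).
#'
#' @param n_trials number of trials.
#' @param fs raw generation rate (Hz); must be an integer multiple of the
#'   200 Hz analysis rate.
#' @param snr per-edge signal-to-noise ratio (>= 0).
#' @param correlation_ratio trial-to-constant correlated variance ratio, or
#'   `NULL` for no constant correlated component.
#' @param constant_band,trial_band frequency bands (Hz) of the constant and
#'   trial-locked correlated components.
#' @param trial_half_width half-width of a trial in seconds (0.5 gives the
#'   standard 500 ms before / 500 ms after epochs).
#' @param baseline_duration seconds of task-free recording before the first
#'   trial, used to build the null distribution.
#' @param trial_spacing seconds between consecutive trial onsets; must
#'   exceed `2 * trial_half_width` so trial epochs never overlap.
#' @param window_taper taper fraction of the trial window
#'   (see [make_trial_window()]).
#' @param filter_band,filter_order nominal preprocessing band-pass used for
#'   variance calibration (see Details).
#' @param seed RNG seed for the session.
#' @return An object of class `fc_sim_config` (a validated list).
#' @export
sim_config <- function(n_trials = 100, fs = 600, snr = 0.1,
                       correlation_ratio = NULL,
                       constant_band = c(2, 50), trial_band = c(8, 25),
                       trial_half_width = 0.5, baseline_duration = 200,
                       trial_spacing = 1.9, window_taper = 0.5,
                       filter_band = c(0.1, 30), filter_order = 3,
                       seed = 1L) {
  if (snr < 0) stop_arg("snr must be non-negative")
  if (fs <= 0 || round(fs) != fs || (fs %% 200) != 0) {
    stop_arg("fs must be a positive integer multiple of 200 Hz")
  }
  for (b in list(constant_band, trial_band, filter_band)) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1] || b[2] >= fs / 2) {
      stop_arg("bands must satisfy 0 < low < high < fs/2")
    }
  }
  if (trial_spacing <= 2 * trial_half_width) {
    stop_arg("trial_spacing must exceed the trial duration (",
             2 * trial_half_width, " s) so that epochs never overlap")
  }
  if (!is.null(correlation_ratio) && correlation_ratio <= 0) {
    stop_arg("correlation_ratio must be positive (or NULL to disable)")
  }
  structure(list(
    n_trials = as.integer(n_trials), fs = fs, snr = snr,
    correlation_ratio = correlation_ratio,
    constant_band = constant_band, trial_band = trial_band,
    trial_half_width = trial_half_width,
    baseline_duration = baseline_duration, trial_spacing = trial_spacing,
    window_taper = window_taper,
    filter_band = filter_band, filter_order = filter_order,
    seed = seed
  ), class = "fc_sim_config")
}

# ---- session construction ---------------------------------------------------

# A coupling group: one shared band-limited signal injected (with per-sensor
# signs) into the listed sensors during every window of one epoch.  An
# ordinary network edge is a group of two sensors with signs (+1, +1);
# sign-flipped and multi-sensor groups build the worked-example fixtures.
.group <- function(sensors, epoch, var, signs = rep(1, length(sensors))) {
  list(sensors = as.integer(sensors), epoch = epoch, var = var, signs = signs)
}

.groups_from_edges <- function(edges, epoch, var) {
  lapply(seq_len(nrow(edges)), function(k) .group(edges[k, ], epoch, var))
}

# Core generator: sums calibrated components per sensor.  All randomness is
# drawn inside cfg$seed, in a fixed order, so sessions are bit-reproducible.
.simulate_core <- function(cfg, net, groups) {
  fs <- cfg$fs
  hw <- cfg$trial_half_width
  first_onset <- cfg$baseline_duration + 1
  onsets <- first_onset + (seq_len(cfg$n_trials) - 1) * cfg$trial_spacing
  duration <- onsets[length(onsets)] + hw + 0.25
  n <- ceiling(duration * fs)
  ns <- net$n_sensors

  filt <- signal::butter(cfg$filter_order, cfg$filter_band / (fs / 2), "pass")
  # synthesize at a 2-3-5-smooth length (fast FFT) and keep the first n samples
  m <- stats::nextn(n, c(2, 3, 5))
  f <- .synth_freqs(m, fs)
  gain <- .filtfilt_power_gain(filt, f, fs)

  # scale a synthesized component so its analysis-band variance hits target
  calibrated <- function(amp, target) {
    s <- .synth_noise(m, fs, amp)
    vf <- 2 * sum(s$pow * gain) / m^2
    s$x[seq_len(n)] * sqrt(target / vf)
  }
  pink_amp <- function(f) 1 / sqrt(f)
  band_amp <- function(band) {
    force(band)
    function(f) as.numeric(f >= band[1] & f <= band[2])
  }

  # per-epoch window weight tracks over the whole recording
  tw <- round(hw * fs)
  w <- make_trial_window(tw, cfg$window_taper)
  onset_idx <- round(onsets * fs) + 1L
  track <- function(offsets) {
    W <- numeric(n)
    for (oi in onset_idx) W[oi + offsets] <- w
    W
  }
  W_epoch <- list(before = track(-(tw:1)), after = track(0:(tw - 1L)))

  with_seed_or_not(cfg$seed, {
    data <- matrix(0, nrow = ns, ncol = n)
    for (i in seq_len(ns)) {
      # unit-variance broadband background (pink + white in equal parts), of
      # which a 0.4 share falls inside the analysis band; SNR targets below
      # are expressed relative to the unit total background variance
      data[i, ] <- calibrated(pink_amp, 0.2) +
        calibrated(function(f) rep(1, length(f)), 0.2)
    }
    if (!is.null(cfg$correlation_ratio) && cfg$snr > 0) {
      v_const <- cfg$snr / cfg$correlation_ratio
      shared <- calibrated(band_amp(cfg$constant_band), v_const)
      for (i in seq_len(ns)) {
        data[i, ] <- data[i, ] + shared +
          calibrated(band_amp(cfg$constant_band), v_const)
      }
    }
    for (g in groups) {
      if (g$var <= 0) next
      W <- W_epoch[[g$epoch]]
      comp <- sqrt(pmax(0, 1 - W^2))
      cg <- calibrated(band_amp(cfg$trial_band), g$var)
      for (k in seq_along(g$sensors)) {
        u <- calibrated(band_amp(cfg$trial_band), g$var)
        i <- g$sensors[k]
        data[i, ] <- data[i, ] + g$signs[k] * (W * cg) + comp * u
      }
    }
    rec <- fc_recording(data, fs = fs, onsets = onsets,
                        region_of = net$region_of, labels = net$labels)
    structure(list(recording = rec, truth = net, config = cfg),
              class = "fc_session")
  })
}

#' Simulate a multichannel session with known true networks
#'
#' Generates a synthetic recording in which the coupling between sensors
#' follows `net$before_edges` during the 500 ms before every trial onset and
#' `net$after_edges` during the 500 ms after, embedded in pink + white noise
#' and (optionally) a persistent correlated component.  Each edge receives
#' its own independent band-limited shared signal, added to both endpoint
#' sensors and faded in and out by a variance-preserving window, so the
#' trial-band variance is stationary across the whole recording.
#'
#' @param cfg an [sim_config()] object.
#' @param net an [true_network_pair()] object; defaults to the bundled
#'   9-sensor, 3-region layout of [default_network_pair()].
#' @return An `fc_session`: list with `recording` (an `fc_recording`),
#'   `truth` (the `fc_truth` ground truth), and `config`.
#' @export
#' @examples
#' sess <- simulate_session(sim_config(n_trials = 5, baseline_duration = 10,
#'                                     seed = 7))
#' sess$recording
simulate_session <- function(cfg, net = default_network_pair()) {
  if (!inherits(cfg, "fc_sim_config")) stop_arg("cfg must come from sim_config()")
  if (max(c(0L, net$before_edges, net$after_edges)) > net$n_sensors) {
    stop_arg("network edges reference sensors beyond n_sensors")
  }
  groups <- c(.groups_from_edges(net$before_edges, "before", cfg$snr),
              .groups_from_edges(net$after_edges, "after", cfg$snr))
  .simulate_core(cfg, net, groups)
}

#' Worked-example fixtures for the canonical correlation measure
#'
#' Three scenarios that contrast sensor-level correlation, within-region
#' signal averaging, and canonical correlation:
#'
#' * `example1` — 10 sensors in two regions of five; all 25 cross-region
#'   sensor pairs are weakly coupled (per-edge SNR 0.028, total per-sensor
#'   SNR 0.14).  Individually the couplings are below the sensor-level
#'   detection floor, but canonical correlation aggregates them into a
#'   detectable region edge.
#' * `example2a` — 9 sensors in three regions of three; one shared signal on
#'   two sensors in each of two regions, with the sign flipped on one sensor
#'   per region, so the within-region average cancels exactly.  Averaging
#'   sees nothing; canonical correlation absorbs the sign into its
#'   coefficients and detects the region edge.
#' * `example2b` — same layout; two independent cross-region couplings of
#'   opposite sign.  Sensor networks detect both sensor edges; the region
#'   average mixes the positive and negative correlations into nothing;
#'   canonical correlation detects the region edge.
#'
#' @param name one of `"example1"`, `"example2a"`, `"example2b"`.
#' @param seed RNG seed.
#' @param n_trials number of trials; defaults to 40 for `example1` (the
#'   weak-coupling regime in which single sensor pairs stay below the
#'   detection floor while the aggregated region edge does not) and 100
#'   otherwise.
#' @return An `fc_session` (see [simulate_session()]); all couplings are
#'   active in the after epoch, the before epoch carries no shared signal.
#' @export
make_example_fixture <- function(name, seed = 1L, n_trials = NULL) {
  name <- match.arg(name, c("example1", "example2a", "example2b"))
  n_trials <- n_trials %||% if (name == "example1") 40 else 100
  if (name == "example1") {
    cross <- as.matrix(expand.grid(i = 1:5, j = 6:10))
    net <- true_network_pair(10L, rep(1:2, each = 5L),
                             before_edges = NULL, after_edges = cross)
    cfg <- sim_config(n_trials = n_trials, snr = 0.028, seed = seed)
    groups <- .groups_from_edges(net$after_edges, "after", 0.028)
  } else if (name == "example2a") {
    pairs4 <- t(utils::combn(c(4L, 5L, 7L, 8L), 2L))
    net <- true_network_pair(9L, rep(1:3, each = 3L),
                             before_edges = NULL, after_edges = pairs4)
    cfg <- sim_config(n_trials = n_trials, snr = 0.15, seed = seed)
    groups <- list(.group(c(4L, 5L, 7L, 8L), "after", 0.15,
                          signs = c(1, -1, 1, -1)))
  } else {
    net <- true_network_pair(9L, rep(1:3, each = 3L),
                             before_edges = NULL,
                             after_edges = rbind(c(4L, 7L), c(5L, 8L)))
    cfg <- sim_config(n_trials = n_trials, snr = 0.15, seed = seed)
    groups <- list(.group(c(4L, 7L), "after", 0.15, signs = c(1, 1)),
                   .group(c(5L, 8L), "after", 0.15, signs = c(1, -1)))
  }
  .simulate_core(cfg, net, groups)
}
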