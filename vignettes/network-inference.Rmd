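---
title: "Inferring task-related functional networks with bootstrap uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring task-related functional networks with bootstrap uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multichannel brain-voltage recordings (EEG, ECoG) collected during a
repeated task invite a natural question: which sensors — or which regions of
interest (ROIs) — become functionally coupled around task onset, and how
confident can we be in each detected connection and in summary measures of
the resulting network?  `fcnet` implements a complete answer for
correlation-based coupling:

1. a coupling statistic per node pair, pooled over trials;
2. a per-edge null distribution bootstrapped from task-free baseline data;
3. Benjamini–Hochberg FDR thresholding into a binary network;
4. a trial-resampling bootstrap that yields per-edge appearance
   probabilities and a confidence interval for the network density.

Every stage is modular: the statistic, the epoch scheme (static before/after
halves or a 200 ms sliding window), and the node definition (sensor or ROI)
can be exchanged without touching the rest.

## Model and statistics

**Sensor coupling.**  For an epoch with `T` time points and `L` trials, each
(epoch, sensor, trial) slice is z-scored, and the statistic for sensors
\(x, y\) is the trial-pooled absolute correlation

\[
\mathrm{AbsCorr}(x,y) \;=\;
\left|\frac{\sum_{l=1}^{L}\sum_{t=1}^{T} x_l(t)\,y_l(t)}
{\sqrt{\bigl(\sum_{l,t} x_l(t)^2\bigr)\bigl(\sum_{l,t} y_l(t)^2\bigr)}}\right| .
\]

The absolute value makes the test one-sided in magnitude: couplings that
become more negative during the task count like couplings that become more
positive.

**Region coupling.**  For channel groups \(X\) (\(n \times LT\)) and \(Y\)
(\(m \times LT\)) holding appended trial segments, the statistic is the first
canonical correlation \(\max_{a,b}\mathrm{Corr}(a^\top x, b^\top y)\),
computed from the thin SVDs \(X = U_X\Sigma_X V_X^\dagger\),
\(Y = U_Y\Sigma_Y V_Y^\dagger\) as the largest singular value of
\(V_X^\dagger V_Y\).  Because the weight vectors are free, the statistic is
invariant to invertible recombination of channels within a group — in
particular to sign flips, which defeat the common alternative of averaging
the channels within an ROI (`region_average_correlation()` is provided as
that comparator).  Rank-deficient groups have their null directions dropped
with a warning; a group with at least as many channels as pooled samples is
refused, since the statistic degenerates to 1.

**Null distribution and p-values.**  `K` non-overlapping task-free intervals
of epoch length are collected; each of `B_null` bootstrap draws resamples
`L` of them with replacement and recomputes the statistic for every pair.
The p-value of an observed statistic is the fraction of its pair's null
samples strictly above it, floored at `1/B_null`.  Because the baseline does
not depend on the epoch, one null serves all epochs.  Note what this null
buys: persistent, task-unrelated correlations (reference effects, ongoing
rhythms) are *included* in the baseline, so only coupling that strengthens
relative to baseline is declared an edge.

**FDR and the detectability bound.**  Within each epoch the p-values of all
\(N_{MC} = M(M-1)/2\) pairs enter the Benjamini–Hochberg step-up rule at
level `q` (default 0.05).  With an empirical null the smallest achievable
p-value is `1/B_null`, so a single edge can only be detected if
`1/B_null <= q/N_MC`; `infer_networks()` warns when `B_null` is too small
for that bound (e.g. 36 pairs at `q = 0.05` need `B_null >= 720`).

**Uncertainty.**  `B_net` surrogate networks are built by resampling trials
with replacement, recomputing statistics, and thresholding against the
*same* baseline null.  The proportion of surrogates containing an edge
estimates its Bernoulli appearance probability; the standard deviation
\(\hat{s}\) of the surrogate densities gives the Gaussian 95% interval
\([d_{obs} - 1.96\hat{s},\, d_{obs} + 1.96\hat{s}]\).  Surrogates contain
fewer unique trials than the original sample, so edge probabilities and
surrogate densities carry a small upward bias; the package reports the
Gaussian interval (rather than bootstrap quantiles) partly to blunt this,
and reports negative lower bounds as-is with a flag rather than clipping
them.  Uncertainty statements compare one epoch against baseline; they do
not license claims about *differences between epochs*.

## The synthetic-session generator

`simulate_session()` produces sessions with known ground truth for
verification.  Each sensor trace is a sum of four components:

* **pink (1/f) noise** — the broadband background of brain voltage data,
  synthesized in the frequency domain with a \(1/\sqrt{f}\) amplitude
  envelope;
* **white noise** — sensor noise;
* an optional **constant 2–50 Hz component** with a part shared by all
  sensors, emulating persistent task-unrelated correlations;
* a **trial-locked 8–25 Hz component**: each true edge owns an independent
  band-limited signal added to both endpoint sensors during its epoch
  (the 500 ms before onset for the "before" network, the 500 ms after for
  the "after" network), faded in and out by a window `w(t)`.

The shared signal is injected as \(w(t)c(t) + \sqrt{1-w(t)^2}\,u(t)\)
against an always-on background `u` of the same band and variance, so the
pointwise variance of the band component is constant across the whole
recording — coupling changes, variance does not.  `w` is a tapered-cosine
(Tukey) window with taper fraction 0.5: it rises from 0, holds 1 over the
middle half of the epoch, and fades back to 0.  A plain Hann bump (taper 1)
is available via `window_taper = 1`, but its mean-squared weight (0.375
versus 0.6875) dilutes the injected correlation enough that the default
operating points below would sit on the detection threshold.

**Calibration and what "SNR" means here.**  All component variances are
calibrated *in the analysis band*: a component is scaled so that its
variance after the nominal preprocessing filter (0.1–30 Hz zero-phase
3rd-order Butterworth) hits its target, computed exactly from the synthesis
spectrum and the squared two-pass filter response.  The broadband background
(pink + white) has unit total variance, of which a 0.4 share (0.2 + 0.2)
lies in the analysis band — about what a 1/f-plus-white mixture retains at a
few-hundred-hertz acquisition rate.  `snr` is the **per-edge**
signal-to-noise ratio: the in-band variance of one edge's shared signal at
the window peak, relative to the unit total background.  A sensor carrying
`k` edges therefore has total task-related SNR `k * snr` (the worked
example with five weak edges per sensor has per-edge SNR 0.028 and
per-sensor SNR 0.14).  `correlation_ratio` divides the per-edge trial
variance by the variance of the constant shared component; the constant
component also gets an equally strong independent part per sensor.

These choices — window taper, in-band background share, equal split of the
constant component — were fixed once against the reference operating
points (exact recovery of the 3-edge/6-edge truth at SNR 0.10–0.15,
partial recovery at 0.05, none at 0) and are not exposed as tuning advice;
they are what "SNR 0.1" *means* in this package.

**Timeline.**  Defaults: 200 s of leading task-free baseline (greedy
packing then yields exactly 400 non-overlapping 500 ms baseline intervals),
first onset at 201 s, 100 trials spaced 1.9 s apart (epochs can never
overlap), raw generation at 600 Hz so that decimation to the 200 Hz
analysis rate is exact.  A default session is about 390 s — small enough
that a full simulate–infer–bootstrap cycle takes a few seconds, which is
what makes the repeated-seed analyses below practical on one CPU.

**What the generator does not emulate:** volume conduction and forward
models, reference artifacts, non-stationary background power, heterogeneous
per-sensor SNR, and ROI geometry.  Passing the recovery tests therefore
shows the *inference machinery* is correct under the stated noise model,
not that real recordings meet that model.

## Numerical choices

* Preprocessing order is filter → downsample → (optional common average
  reference) → epoch → normalize.  Decimation without an extra anti-alias
  stage is sound because the 0.1–30 Hz band-pass precedes it; non-integer
  rate ratios are refused rather than resampled.
* The onset sample belongs to the "after" epoch (half-open intervals
  `[onset - 0.5, onset)` and `[onset, onset + 0.5)`).  Sliding windows run
  from midpoint −0.4 s to +0.4 s inclusive at a 5 ms step, giving 161
  windows of 40 samples.
* A zero-variance (flat) slice during normalization is an error naming the
  slice, not a silent `NaN`.
* Baseline intervals are packed greedily left-to-right (deterministic and
  maximal for a fixed duration) at least `guard` seconds from any trial
  epoch.
* Empirical p-values use a strict "above" count: ties with null samples do
  not count against the null (conservative).
* FDR is applied within each epoch, across that epoch's pairs.
* Rank decisions in the canonical correlation use a relative tolerance of
  `max(dim) * eps` on the singular values.
* All bootstrap stages take explicit seeds (localized with `withr`, leaving
  the caller's RNG stream untouched); identical seeds give bit-identical
  sessions, nulls, networks, and surrogate collections.
* The density standard error uses the sample (n−1) standard deviation.

## Problem sizes used in the shipped analyses

The test-suite and the acceptance script favour many medium sessions over
few large ones: recovery checks run 15 independent default sessions per SNR
level and report the median density (a single session is one noise
instantiation, exactly as a single experimental subject is); the
constant-correlation coverage analysis runs 20 sessions per correlation
ratio with 100 trial-bootstrap surrogates each; CI-coverage properties use
50 sessions with 60 surrogates.  Unit tests use shorter sessions (20–80
trials, 25–60 s baselines) where only mechanics are at stake.

## Known limitations

* The FDR rule assumes independent tests; edges sharing a sensor are mildly
  dependent, and a dependence-corrected rule (Benjamini–Yekutieli) is not
  provided.
* Power varies with per-sensor SNR, so absent edges are weak evidence of
  absent coupling (the procedure controls false positives, not false
  negatives).
* Canonical correlation values grow with group size; comparing each ROI
  pair against its own baseline null absorbs most of this, but strongly
  unbalanced ROIs may still be at a ceiling disadvantage.
* The trial bootstrap requires genuine trial structure; it is not
  appropriate for continuous, task-free data.
* Coupling measures beyond correlation and canonical correlation
  (coherence, phase-locking, synchronization likelihood) and network
  measures beyond density are out of scope, though the stage structure
  accommodates them.

## A minimal session

```{r, eval = FALSE}
library(fcnet)

sess <- simulate_session(sim_config(snr = 0.10, seed = 1))
res  <- run_pipeline(run_config(seed = 1), sess)
res                      # densities, true/false positives per epoch
res$uncertainty          # density CIs from the trial bootstrap
plot(res$networks$after, region_of = sess$truth$region_of)
```
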