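# Noise generators, trial window, and simulated-session ground truth.

test_that("pink noise has a 1/f spectrum, unit variance, and is seed-stable", {
  x <- make_pink_noise(2^14, fs = 1000, seed = 11)
  expect_equal(var(x), 1, tolerance = 0.05)
  expect_identical(x, make_pink_noise(2^14, fs = 1000, seed = 11))

  p <- oracle_psd(x, fs = 1000)
  keep <- p$f >= 1 & p$f <= 100
  slope <- coef(lm(log(p$psd[keep]) ~ log(p$f[keep])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)

  expect_error(make_pink_noise(1, fs = 100), "at least 2")
})

test_that("band-limited noise concentrates its power in the requested band", {
  fs <- 200
  x <- make_bandlimited_noise(2^15, fs, band = c(8, 25), seed = 3)
  expect_equal(var(x), 1, tolerance = 0.05)
  expect_identical(x, make_bandlimited_noise(2^15, fs, band = c(8, 25), seed = 3))

  p <- oracle_psd(x, fs)
  inband <- sum(p$psd[p$f >= 7.5 & p$f <= 25.5]) / sum(p$psd)
  expect_gte(inband, 0.9)

  y <- make_bandlimited_noise(2^15, 200, band = c(2, 50), seed = 4)
  py <- oracle_psd(y, 200)
  expect_lte(sum(py$psd[py$f > 60]) / sum(py$psd), 0.05)

  expect_error(make_bandlimited_noise(1000, 100, band = c(10, 60)), "fs/2")
})

test_that("trial window fades in and out, peaks at the midpoint, and preserves variance", {
  for (n in c(100, 101, 301)) {
    w <- make_trial_window(n)
    expect_equal(w[1], 0)
    expect_equal(w[n], 0)
    expect_equal(max(w), 1)
    mid <- (n + 1) / 2
    expect_equal(w[floor(mid)], 1)
    expect_true(all(w >= 0 & w <= 1))
    # complementary-background identity: total injected variance is constant
    expect_equal(w^2 + sqrt(1 - w^2)^2, rep(1, n))
  }
  expect_error(make_trial_window(2), "at least 3")
})

test_that("default ground-truth pair reproduces the reference layout and densities", {
  net <- default_network_pair()
  expect_equal(network_density(net$before_edges, 9), 3 / 36)
  expect_equal(network_density(net$after_edges, 9), 6 / 36)
  expect_equal(network_density(net$region_before_edges, 3), 2 / 3)
  expect_equal(network_density(net$region_after_edges, 3), 1 / 3)
  # region edges are exactly the projection of sensor edges
  expect_identical(net$region_before_edges,
                   fcnet:::project_edges(net$before_edges, net$region_of))
  expect_identical(net$region_after_edges,
                   fcnet:::project_edges(net$after_edges, net$region_of))
})

test_that("true_network_pair validates its edge sets", {
  expect_error(true_network_pair(4, rep(1:2, 2), rbind(c(1, 1)), NULL),
               "self-edges")
  expect_error(true_network_pair(4, rep(1:2, 2), rbind(c(1, 9)), NULL),
               "1..4")
  expect_error(sim_config(snr = -1), "non-negative")
  expect_error(sim_config(trial_spacing = 0.8), "epochs never overlap")
})

test_that("simulated sessions are bit-identical under a fixed seed", {
  a <- small_session(seed = 9, n_trials = 5, baseline_duration = 5)
  b <- small_session(seed = 9, n_trials = 5, baseline_duration = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$onsets, b$recording$onsets)
  c <- small_session(seed = 10, n_trials = 5, baseline_duration = 5)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("trial-band variance is stationary inside vs outside trial epochs", {
  sess <- small_session(snr = 0.15, seed = 21, n_trials = 80,
                        baseline_duration = 60)
  rec <- sess$recording
  # isolate the trial band: the windowing identity promises constant
  # variance there; broadband 1/f noise is excluded because its slow drifts
  # dominate finite-window variance estimates
  filt <- signal::butter(4, c(8, 25) / (rec$fs / 2), "pass")
  band <- t(apply(rec$data, 1, function(x) signal::filtfilt(filt, x)))
  idx <- round(rec$onsets * rec$fs) + 1
  ep_cols <- as.vector(outer(-(0.5 * rec$fs):(0.5 * rec$fs - 1), idx, `+`))
  base_cols <- seq(5 * rec$fs, 55 * rec$fs)  # leading task-free stretch
  v_in <- apply(band[, ep_cols], 1, var)
  v_out <- apply(band[, base_cols], 1, var)
  expect_lt(abs(mean(v_in / v_out) - 1), 0.05)
  expect_true(all(abs(v_in / v_out - 1) < 0.15))
})

test_that("zero SNR leaves sensors uncorrelated; coupled pairs correlate at high SNR", {
  sess0 <- small_session(snr = 0, seed = 13, n_trials = 40)
  res0 <- bandpass_filter(sess0$recording)
  res0 <- downsample(res0)
  ep0 <- extract_epochs(res0)
  s0 <- compute_stat_matrix(ep0, "sensor")
  pr <- s0$pairs
  vals0 <- s0$stat[cbind(2, pr[, 1], pr[, 2])]
  expect_lt(max(vals0), 0.12)   # all pooled correlations at the null scale

  sess <- small_session(snr = 0.15, seed = 14, n_trials = 40)
  rec <- downsample(bandpass_filter(sess$recording))
  ep <- extract_epochs(rec)
  s <- compute_stat_matrix(ep, "sensor")
  te <- sess$truth$after_edges
  on_edge <- s$stat[cbind(2, te[, 1], te[, 2])]
  pos <- fcnet:::pair_position(te, 9)
  off_edge <- s$stat[cbind(2, pr[-pos, 1], pr[-pos, 2])]
  expect_gt(mean(on_edge), mean(off_edge))
  expect_gt(min(on_edge), max(0, mean(off_edge)))
})

test_that("example fixtures have the documented layouts", {
  e1 <- make_example_fixture("example1", seed = 1, n_trials = 4)
  expect_equal(e1$truth$n_sensors, 10)
  expect_equal(nrow(e1$truth$after_edges), 25)
  expect_equal(nrow(e1$truth$region_after_edges), 1)

  e2a <- make_example_fixture("example2a", seed = 1, n_trials = 4)
  expect_equal(nrow(e2a$truth$after_edges), 6)   # complete subnetwork on 4 sensors
  expect_identical(e2a$truth$region_after_edges, fcnet:::edge_matrix(rbind(c(2, 3))))

  e2b <- make_example_fixture("example2b", seed = 1, n_trials = 4)
  expect_identical(e2b$truth$after_edges,
                   fcnet:::edge_matrix(rbind(c(4, 7), c(5, 8))))
  expect_error(make_example_fixture("nope"), "should be one of")
})
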