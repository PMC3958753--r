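# Shared fixtures and independent oracles.  Everything is generated in code
# under fixed seeds; no data files.

# z-score helper matching the package's per-slice normalization
zsc <- function(x) (x - mean(x)) / sd(x)

# Epoched data made of i.i.d. Gaussian noise (no autocorrelation), bypassing
# the simulator: useful for closed-form null checks.
make_iid_epochs <- function(E = 1, Tn = 50, N = 4, L = 20, seed = 1,
                            region_of = NULL) {
  arr <- withr::with_seed(seed, array(rnorm(E * Tn * N * L), dim = c(E, Tn, N, L)))
  for (e in seq_len(E)) for (nn in seq_len(N)) for (l in seq_len(L)) {
    arr[e, , nn, l] <- zsc(arr[e, , nn, l])
  }
  labels <- if (E == 2) c("before", "after") else paste0("e", seq_len(E))
  structure(list(data = arr, epoch_labels = labels,
                 epoch_mid = seq_len(E), fs = 200,
                 region_of = region_of, labels = paste0("s", seq_len(N))),
            class = "fc_epochs")
}

make_iid_baseline <- function(Tn = 50, N = 4, K = 40, seed = 2,
                              region_of = NULL) {
  arr <- withr::with_seed(seed, array(rnorm(Tn * N * K), dim = c(Tn, N, K)))
  for (nn in seq_len(N)) for (k in seq_len(K)) arr[, nn, k] <- zsc(arr[, nn, k])
  structure(list(data = arr, starts = seq_len(K), fs = 200,
                 region_of = region_of, labels = paste0("s", seq_len(N))),
            class = "fc_baseline")
}

# A cheap simulated session for unit tests (fewer trials, short baseline).
small_session <- function(snr = 0.15, seed = 1, n_trials = 30,
                          baseline_duration = 40, ...) {
  simulate_session(sim_config(n_trials = n_trials,
                              baseline_duration = baseline_duration,
                              snr = snr, seed = seed, ...))
}

# ---- independent oracles ----------------------------------------------------

# First canonical correlation by direct optimization: alternating
# least-squares on max_{a,b} corr(a'X, b'Y), i.e., power iteration on the
# composed regression operators.  Never touches the package's SVD route.
oracle_canoncorr <- function(X, Y, max_iter = 5000, tol = 1e-12) {
  X <- rbind(X); Y <- rbind(Y)
  Cxx <- tcrossprod(X); Cyy <- tcrossprod(Y); Cxy <- tcrossprod(X, Y)
  corr_of <- function(a, b) {
    as.numeric(abs(t(a) %*% Cxy %*% b) /
                 sqrt((t(a) %*% Cxx %*% a) * (t(b) %*% Cyy %*% b)))
  }
  a <- rep(1, nrow(X))
  b <- rep(1, nrow(Y))
  last <- -Inf
  for (it in seq_len(max_iter)) {
    a <- solve(Cxx, Cxy %*% b)
    a <- a / sqrt(sum(a^2))
    b <- solve(Cyy, crossprod(Cxy, a))
    b <- b / sqrt(sum(b^2))
    cur <- corr_of(a, b)
    if (abs(cur - last) < tol) break
    last <- cur
  }
  cur
}

# Benjamini-Hochberg by brute-force scan of p_(k) <= q k / N.
oracle_bh <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(n) / n)
  reject <- logical(n)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# Welch-style averaged periodogram (for spectral checks on the generators).
oracle_psd <- function(x, fs, seg = 1024) {
  nseg <- floor(length(x) / seg)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  acc <- 0
  for (s in seq_len(nseg)) {
    xs <- x[((s - 1) * seg + 1):(s * seg)]
    xs <- (xs - mean(xs)) * w
    acc <- acc + Mod(fft(xs))^2
  }
  f <- (seq_len(seg %/% 2) - 1) * fs / seg
  list(f = f[-1], psd = (acc / nseg)[2:(seg %/% 2)])
}
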