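# Coupling statistics: trial-pooled absolute correlation between sensors,
# canonical correlation between sensor groups (regions of interest), and the
# within-region signal-averaging comparator.  All three live in [0, 1].

# coerce trials-of-a-node input (L x T matrix or plain vector) to one long
# row vector of appended trials
.pool_trials <- function(x) {
  if (is.matrix(x)) as.vector(t(x)) else as.numeric(x)
}

#' Trial-pooled absolute correlation
#'
#' The absolute value of the Pearson correlation between two sensors pooled
#' over all trials of an epoch:
#' \deqn{\mathrm{AbsCorr}(x, y) = \left|\frac{\sum_{l=1}^{L}\sum_{t=1}^{T}
#'   x_l(t)\, y_l(t)}{\sqrt{\left(\sum x_l(t)^2\right)
#'   \left(\sum y_l(t)^2\right)}}\right|}
#' where trial slices are expected to be centered (z-scored) per trial, so
#' the quantity equals the absolute Pearson correlation of the
#' trial-concatenated signals.  Only magnitudes are used: correlations that
#' become more negative during a task count the same as correlations that
#' become more positive.
#'
#' @param x,y trials of the two nodes, as L x T matrices (trials in rows) of
#'   the same shape, or plain vectors.
#' @return A statistic in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 4)
#' abs_correlation(x, -x)  # 1: magnitude only
abs_correlation <- function(x, y) {
  xv <- .pool_trials(x); yv <- .pool_trials(y)
  if (length(xv) != length(yv)) stop_arg("x and y must have the same shape")
  den2 <- sum(xv^2) * sum(yv^2)
  if (den2 == 0) stop_arg("flat input: zero variance leaves the correlation undefined")
  min(1, abs(sum(xv * yv)) / sqrt(den2))
}

# numerical rank cut shared by the canonical-correlation routines
.rank_keep <- function(d, m) d > max(m) * .Machine$double.eps * max(d, 0)

#' Canonical correlation between two channel groups
#'
#' The maximum correlation achievable between linear combinations of the
#' channels of two groups, \eqn{\max_{a,b} \mathrm{Corr}(a^T x, b^T y)}.
#' Computed from the thin singular value decompositions
#' \eqn{X = U_X \Sigma_X V_X^\dagger}, \eqn{Y = U_Y \Sigma_Y V_Y^\dagger} as
#' the first singular value of \eqn{Q_{XY} = U_X V_X^\dagger V_Y U_Y^\dagger}
#' (equivalently of \eqn{V_X^\dagger V_Y}).  Because the coefficient vectors
#' are free, the statistic is invariant to any invertible linear
#' recombination of channels within a group — including sign flips, which is
#' what lets it detect coupling that cancels under within-region averaging.
#'
#' @param X,Y group matrices, n x (L*T) and m x (L*T): one row per channel,
#'   holding that channel's appended per-trial-normalized trial segments.
#'   Rows must be (numerically) linearly independent; directions below the
#'   relative rank tolerance are dropped with a warning.
#' @return The first canonical correlation, in `[0, 1]`.
#' @export
canonical_correlation <- function(X, Y) {
  X <- rbind(X); Y <- rbind(Y)   # promote vectors to 1-row matrices
  if (ncol(X) != ncol(Y)) stop_arg("X and Y must have the same number of columns")
  S <- ncol(X)
  if (nrow(X) >= S || nrow(Y) >= S) {
    stop_arg("need more pooled samples (L*T = ", S, ") than channels per group; ",
             "the statistic is degenerate at 1 otherwise")
  }
  sx <- svd(X); sy <- svd(Y)
  kx <- .rank_keep(sx$d, dim(X)); ky <- .rank_keep(sy$d, dim(Y))
  if (!all(kx) || !all(ky)) {
    warning("rank-deficient group: dropping ",
            sum(!kx) + sum(!ky), " null direction(s)", call. = FALSE)
  }
  if (!any(kx) || !any(ky)) stop_arg("flat input: a group has rank 0")
  M <- crossprod(sx$v[, kx, drop = FALSE], sy$v[, ky, drop = FALSE])
  min(1, max(0, svd(M)$d[1]))
}

#' Correlation between within-region channel averages
#'
#' The comparator to [canonical_correlation()] used in fMRI-style ROI
#' analyses: average the channels within each group and take the
#' [abs_correlation()] of the two averaged signals.  When signals within a
#' region carry opposite signs, or when a region pair mixes positively and
#' negatively correlated couplings, the averages cancel and this measure is
#' blind to the coupling.
#'
#' @inheritParams canonical_correlation
#' @return A statistic in `[0, 1]`.  An exactly flat averaged signal (the
#'   complete-cancellation case) is an error, surfaced explicitly.
#' @export
region_average_correlation <- function(X, Y) {
  X <- rbind(X); Y <- rbind(Y)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  den2 <- sum(xbar^2) * sum(ybar^2)
  if (den2 == 0) {
    stop_arg("a within-region average is exactly flat (complete cancellation); ",
             "the region-average correlation is undefined here")
  }
  min(1, abs(sum(xbar * ybar)) / sqrt(den2))
}

# ---- Gram-matrix fast path --------------------------------------------------
# Every resampled concatenation's cross-product (Gram) matrix is the
# multiplicity-weighted sum of per-slice Gram matrices, so the bootstrap
# loops below never touch the raw time series.  The three statistics are all
# functions of Gram blocks; tests pin them to the exposed per-pair ops.

# N x N x nslice array of crossprod(T x N slice)
.slice_grams <- function(slices) {
  d <- dim(slices)   # T x N x S
  out <- array(NA_real_, dim = c(d[2], d[2], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- crossprod(slices[, , k])
  out
}

.corr_from_gram <- function(G, i, j) {
  min(1, abs(G[i, j]) / sqrt(G[i, i] * G[j, j]))
}

.cc_from_gram <- function(G, ix, iy) {
  Gxx <- G[ix, ix, drop = FALSE]
  Gyy <- G[iy, iy, drop = FALSE]
  Gxy <- G[ix, iy, drop = FALSE]
  isqrt <- function(A) {
    e <- eigen(A, symmetric = TRUE)
    keep <- .rank_keep(sqrt(pmax(e$values, 0)), dim(A))
    if (!any(keep)) stop_arg("flat input: a group has rank 0")
    U <- e$vectors[, keep, drop = FALSE]
    U %*% (t(U) / sqrt(e$values[keep]))
  }
  M <- isqrt(Gxx) %*% Gxy %*% isqrt(Gyy)
  min(1, max(0, svd(M)$d[1]))
}

.avg_from_gram <- function(G, ix, iy) {
  num <- sum(G[ix, iy])
  den2 <- sum(G[ix, ix]) * sum(G[iy, iy])
  if (den2 == 0) stop_arg("a within-region average is exactly flat")
  min(1, abs(num) / sqrt(den2))
}

# statistic for every node pair from a pooled Gram matrix
.pair_stats <- function(G, pairs, measure, groups = NULL) {
  vapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    switch(measure,
      correlation = .corr_from_gram(G, i, j),
      canonical   = .cc_from_gram(G, groups[[i]], groups[[j]]),
      average     = .avg_from_gram(G, groups[[i]], groups[[j]]))
  }, numeric(1))
}

# node bookkeeping for a mode: labels, pair table, and (for regions) the
# member-channel index groups
.node_scheme <- function(mode, region_of, labels) {
  if (mode == "sensor") {
    n <- length(labels)
    list(nodes = labels, pairs = pair_index(n), groups = NULL)
  } else {
    if (is.null(region_of)) stop_arg("region mode needs a sensor-to-region map")
    regions <- sort(unique(region_of))
    groups <- lapply(regions, function(r) which(region_of == r))
    list(nodes = paste0("r", regions), pairs = pair_index(length(regions)),
         groups = groups)
  }
}

#' Coupling statistics for every node pair and epoch
#'
#' Computes the chosen coupling statistic, pooled over all trials, for each
#' unordered node pair in each epoch.  Nodes are individual sensors
#' (`mode = "sensor"`, measure `"correlation"`) or regions of interest
#' (`mode = "region"`, measure `"canonical"` or `"average"`).
#'
#' @param ep an [extract_epochs()] result.
#' @param mode `"sensor"` or `"region"`.
#' @param measure `"correlation"`, `"canonical"`, or `"average"`; defaults
#'   to `"correlation"` for sensors and `"canonical"` for regions.
#' @param region_of sensor-to-region map; defaults to the one carried by
#'   `ep`.
#' @return An `fc_stats` object: `stat` is an E x M x M symmetric array of
#'   statistics in `[0, 1]` (diagonal `NA`; M = sensors or regions), plus
#'   node labels, the pair table, measure, mode, and trial count.
#' @export
compute_stat_matrix <- function(ep, mode = c("sensor", "region"),
                                measure = NULL, region_of = NULL) {
  stopifnot(inherits(ep, "fc_epochs"))
  mode <- match.arg(mode)
  measure <- measure %||% if (mode == "sensor") "correlation" else "canonical"
  measure <- match.arg(measure, c("correlation", "canonical", "average"))
  if (mode == "sensor" && measure != "correlation") {
    stop_arg("sensor mode uses the correlation measure; region measures ",
             "need mode = 'region'")
  }
  if (mode == "region" && measure == "correlation") {
    stop_arg("region mode uses the canonical or average measure")
  }
  region_of <- region_of %||% ep$region_of
  sch <- .node_scheme(mode, region_of, ep$labels)
  d <- dim(ep$data)
  E <- d[1]; L <- d[4]
  M <- length(sch$nodes)
  out <- array(NA_real_, dim = c(E, M, M),
               dimnames = list(ep$epoch_labels, sch$nodes, sch$nodes))
  for (e in seq_len(E)) {
    G <- matrix(0, d[3], d[3])
    for (l in seq_len(L)) G <- G + crossprod(ep$data[e, , , l])
    s <- .pair_stats(G, sch$pairs, measure, sch$groups)
    for (p in seq_len(nrow(sch$pairs))) {
      out[e, sch$pairs[p, 1L], sch$pairs[p, 2L]] <- s[p]
      out[e, sch$pairs[p, 2L], sch$pairs[p, 1L]] <- s[p]
    }
  }
  structure(list(
    stat = out, nodes = sch$nodes, pairs = sch$pairs, groups = sch$groups,
    measure = measure, mode = mode, epoch_labels = ep$epoch_labels,
    n_trials = L
  ), class = "fc_stats")
}

#' Export coupling statistics as a long table
#'
#' @param x an `fc_stats` object.
#' @param ... unused.
#' @return A data.frame with columns `epoch_label`, `node_i`, `node_j`,
#'   `statistic`, one row per epoch and unordered node pair.
#' @export
as.data.frame.fc_stats <- function(x, ...) {
  P <- nrow(x$pairs)
  E <- length(x$epoch_labels)
  data.frame(
    epoch_label = rep(x$epoch_labels, each = P),
    node_i = rep(x$nodes[x$pairs[, 1L]], E),
    node_j = rep(x$nodes[x$pairs[, 2L]], E),
    statistic = as.vector(vapply(seq_len(E), function(e) {
      x$stat[cbind(e, x$pairs[, 1L], x$pairs[, 2L])]
    }, numeric(P))),
    stringsAsFactors = FALSE
  )
}
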