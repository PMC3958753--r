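# Edge inference: baseline-bootstrap null distributions, empirical p-values,
# Benjamini-Hochberg FDR thresholding, binary networks.

#' Bootstrap null distribution of the coupling statistic
#'
#' Builds a per-pair empirical null for the coupling statistic from the
#' task-free baseline intervals: for each of `B_null` bootstrap draws, `L`
#' intervals are sampled with replacement from the K available intervals and
#' the statistic is computed for every node pair exactly as for the trial
#' data.  The null hypothesis for an edge is that its trial-epoch statistic
#' comes from this baseline distribution; because the baseline is
#' epoch-independent, the same null serves every epoch of interest.
#'
#' @param base an [extract_baseline_intervals()] result.
#' @param L number of intervals per draw; must equal the trial count used
#'   for the observed statistics.
#' @param B_null number of bootstrap draws (default 1000).
#' @param mode,measure,region_of as in [compute_stat_matrix()].
#' @param seed optional RNG seed for reproducible draws.
#' @return An `fc_null` object: `samples` is a pairs x `B_null` matrix of
#'   null statistics in `[0, 1]` (pair order as in [compute_stat_matrix()]),
#'   plus node labels, the pair table, `L`, `B_null`, measure, mode, and the
#'   seed.  A single-interval baseline (K = 1) yields a degenerate,
#'   constant null and is flagged with a warning.
#' @export
bootstrap_null <- function(base, L, B_null = 1000,
                           mode = c("sensor", "region"), measure = NULL,
                           region_of = NULL, seed = NULL) {
  stopifnot(inherits(base, "fc_baseline"))
  mode <- match.arg(mode)
  measure <- measure %||% if (mode == "sensor") "correlation" else "canonical"
  region_of <- region_of %||% base$region_of
  sch <- .node_scheme(mode, region_of, base$labels)
  K <- dim(base$data)[3]
  N <- dim(base$data)[2]
  if (K < 1L) stop_arg("no baseline intervals")
  if (K == 1L) {
    warning("only one baseline interval: every bootstrap draw is identical ",
            "and the null distribution is degenerate", call. = FALSE)
  }
  grams <- .slice_grams(base$data)            # N x N x K
  Gm <- matrix(grams, nrow = N * N, ncol = K) # flattened for weighted sums
  P <- nrow(sch$pairs)

  samples <- with_seed_or_not(seed, {
    counts <- matrix(0, nrow = K, ncol = B_null)
    for (b in seq_len(B_null)) {
      counts[, b] <- tabulate(sample.int(K, L, replace = TRUE), nbins = K)
    }
    GB <- Gm %*% counts                        # N^2 x B_null
    out <- matrix(NA_real_, nrow = P, ncol = B_null)
    for (b in seq_len(B_null)) {
      out[, b] <- .pair_stats(matrix(GB[, b], N, N), sch$pairs, measure,
                              sch$groups)
    }
    out
  })
  structure(list(
    samples = samples, nodes = sch$nodes, pairs = sch$pairs,
    groups = sch$groups, L = as.integer(L), B_null = as.integer(B_null),
    K = K, measure = measure, mode = mode, region_of = region_of,
    seed = seed, degenerate = (K == 1L)
  ), class = "fc_null")
}

#' @export
print.fc_null <- function(x, ...) {
  cat(sprintf(
    "Bootstrap null: %s statistic, %d pairs x %d draws (L = %d of K = %d intervals)\n",
    x$measure, nrow(x$samples), x$B_null, x$L, x$K))
  invisible(x)
}

#' Empirical p-values for observed coupling statistics
#'
#' For each epoch and node pair, the p-value is the fraction of that pair's
#' bootstrap null samples that fall strictly above the observed statistic (a
#' one-sided test: only coupling stronger than baseline counts).  Zero
#' counts are replaced by the resolution floor `1 / B_null`, the smallest
#' p-value the empirical null can support.
#'
#' @param obs an `fc_stats` object from [compute_stat_matrix()].
#' @param null an `fc_null` from [bootstrap_null()] with matching mode,
#'   measure, and node set.
#' @return A matrix of p-values, epochs in rows, pairs in columns (pair
#'   order as in `obs$pairs`).
#' @export
edge_p_values <- function(obs, null) {
  stopifnot(inherits(obs, "fc_stats"), inherits(null, "fc_null"))
  if (obs$measure != null$measure || !identical(obs$nodes, null$nodes)) {
    stop_arg("observed statistics and null distribution disagree in ",
             "measure or node set")
  }
  E <- length(obs$epoch_labels)
  P <- nrow(obs$pairs)
  p <- matrix(NA_real_, nrow = E, ncol = P,
              dimnames = list(obs$epoch_labels, NULL))
  for (e in seq_len(E)) {
    s <- obs$stat[cbind(e, obs$pairs[, 1L], obs$pairs[, 2L])]
    cnt <- rowSums(null$samples > rep(s, times = ncol(null$samples)))
    p[e, ] <- pmax(cnt, 1L) / null$B_null
  }
  p
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up false-discovery-rate control: sort the p-values ascending, find
#' the largest k with `p_(k) <= q * k / N`, where N is the number of tests,
#' and reject exactly the k smallest; reject none if no k qualifies.  Among
#' the selected edges, only a proportion q is expected to be false.
#'
#' @param p numeric vector of p-values.
#' @param q FDR level in (0, 1), default 0.05.
#' @return Logical vector marking the rejected (significant) entries.
#' @export
#' @examples
#' fdr_select(c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.3))  # two rejections
fdr_select <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop_arg("q must lie in (0, 1)")
  if (!length(p)) return(logical(0))
  # p.adjust's BH adjustment <= q reproduces the step-up rule exactly
  p.adjust(p, method = "BH") <= q
}

# assemble an fc_network from a rejection vector
.make_network <- function(nodes, pairs, reject, p, stat, q, epoch, measure) {
  edges <- pairs[reject, , drop = FALSE]
  structure(list(
    nodes = nodes, edges = edge_matrix(edges, length(nodes)),
    pairs = pairs, p = p, stat = stat, q = q,
    epoch = epoch, measure = measure
  ), class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf("Binary %s network, epoch '%s': %d of %d possible edges (density %.3f)\n",
              x$measure, x$epoch, nrow(x$edges), nrow(x$pairs),
              network_density(x)))
  invisible(x)
}

#' Infer binary functional networks per epoch
#'
#' Runs the full edge-inference chain for every epoch: observed coupling
#' statistics ([compute_stat_matrix()]), empirical p-values against the
#' baseline bootstrap null ([edge_p_values()]), and Benjamini-Hochberg FDR
#' thresholding at level `q` ([fdr_select()]), applied within each epoch
#' across its node pairs.  The surviving pairs form the epoch's binary
#' network.
#'
#' When the p-value floor `1 / B_null` exceeds `q / N` (N = number of
#' pairs), no single edge can ever reach significance at k = 1; a warning
#' states the required `B_null` (the resolution of the empirical null
#' imposes this detectability bound).
#'
#' @param ep an [extract_epochs()] result.
#' @param null an `fc_null` from [bootstrap_null()]; its `L` must equal the
#'   trial count of `ep`.
#' @param q FDR level (default 0.05).
#' @return A list of `fc_network` objects, one per epoch, named by epoch
#'   label.  Each carries its per-pair p-values and statistics.
#' @export
infer_networks <- function(ep, null, q = 0.05) {
  stopifnot(inherits(ep, "fc_epochs"), inherits(null, "fc_null"))
  if (null$L != dim(ep$data)[4]) {
    stop_arg("null was built with L = ", null$L, " but the data have ",
             dim(ep$data)[4], " trials")
  }
  obs <- compute_stat_matrix(ep, mode = null$mode, measure = null$measure,
                             region_of = null$region_of)
  P <- nrow(obs$pairs)
  if (null$B_null < P / q) {
    warning(sprintf(
      paste0("the p-value floor 1/%d cannot clear the FDR cutoff q/N = %.2g ",
             "for a single edge; use B_null >= %d for %d pairs at q = %g"),
      null$B_null, q / P, ceiling(P / q), P, q), call. = FALSE)
  }
  pmat <- edge_p_values(obs, null)
  nets <- lapply(seq_len(nrow(pmat)), function(e) {
    s <- obs$stat[cbind(e, obs$pairs[, 1L], obs$pairs[, 2L])]
    .make_network(obs$nodes, obs$pairs, fdr_select(pmat[e, ], q),
                  pmat[e, ], s, q, obs$epoch_labels[e], obs$measure)
  })
  names(nets) <- obs$epoch_labels
  nets
}
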