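# Trial-bootstrap uncertainty: per-edge appearance probabilities and the
# sampling variability of network density.

#' Surrogate networks by trial resampling
#'
#' Resamples the trials with replacement `B_net` times; each surrogate
#' recomputes the coupling statistics over the resampled trials (reusing the
#' already-normalized epoch slices), converts them to p-values against the
#' *same* fixed baseline null used for the observed networks, and applies
#' FDR at level `q`, yielding one binary network per epoch per surrogate.
#' The surrogate population approximates the sampling distribution of the
#' inferred networks; note the mild upward bias in edge counts that comes
#' from surrogates containing fewer unique trials than the original sample.
#'
#' @inheritParams infer_networks
#' @param B_net number of surrogate networks (default 100; >= 2).
#' @param seed optional RNG seed.
#' @return An `fc_surrogates` object: `present` is a pairs x `B_net` x
#'   epochs logical array of edge occurrences, `densities` an epochs x
#'   `B_net` matrix of surrogate densities, plus the node/pair bookkeeping.
#' @export
trial_bootstrap_networks <- function(ep, null, q = 0.05, B_net = 100,
                                     seed = NULL) {
  stopifnot(inherits(ep, "fc_epochs"), inherits(null, "fc_null"))
  if (B_net < 2) stop_arg("B_net must be at least 2")
  d <- dim(ep$data)
  E <- d[1]; N <- d[3]; L <- d[4]
  if (null$L != L) {
    stop_arg("null was built with L = ", null$L, " but the data have ",
             L, " trials")
  }
  sch <- .node_scheme(null$mode, null$region_of, ep$labels)
  P <- nrow(sch$pairs)
  M <- length(sch$nodes)
  n_possible <- M * (M - 1L) / 2

  # per-trial Gram matrices per epoch; a surrogate's pooled Gram is a
  # multiplicity-weighted sum of these
  Gm <- vector("list", E)
  for (e in seq_len(E)) {
    g <- matrix(NA_real_, nrow = N * N, ncol = L)
    for (l in seq_len(L)) g[, l] <- crossprod(ep$data[e, , , l])
    Gm[[e]] <- g
  }

  with_seed_or_not(seed, {
    present <- array(FALSE, dim = c(P, B_net, E))
    densities <- matrix(NA_real_, nrow = E, ncol = B_net,
                        dimnames = list(ep$epoch_labels, NULL))
    for (b in seq_len(B_net)) {
      counts <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      for (e in seq_len(E)) {
        G <- matrix(Gm[[e]] %*% counts, N, N)
        s <- .pair_stats(G, sch$pairs, null$measure, sch$groups)
        cnt <- rowSums(null$samples > s)
        pvals <- pmax(cnt, 1L) / null$B_null
        rej <- fdr_select(pvals, q)
        present[, b, e] <- rej
        densities[e, b] <- sum(rej) / n_possible
      }
    }
    structure(list(
      present = present, densities = densities, nodes = sch$nodes,
      pairs = sch$pairs, epoch_labels = ep$epoch_labels,
      B_net = as.integer(B_net), q = q, measure = null$measure,
      seed = seed
    ), class = "fc_surrogates")
  })
}

#' @export
print.fc_surrogates <- function(x, ...) {
  cat(sprintf("Trial-bootstrap surrogates: %d networks x %d epochs (%s)\n",
              x$B_net, length(x$epoch_labels), x$measure))
  invisible(x)
}

#' Per-edge appearance probabilities
#'
#' Treats each potential edge as a Bernoulli variable whose success
#' probability is estimated by the proportion of surrogate networks that
#' contain the edge; the implied edge variance is `p * (1 - p)`.
#'
#' @param surr an `fc_surrogates` object from [trial_bootstrap_networks()].
#' @return A matrix of probabilities, epochs in rows, pairs in columns
#'   (pair order as in `surr$pairs`).
#' @export
edge_probability <- function(surr) {
  stopifnot(inherits(surr, "fc_surrogates"))
  if (!dim(surr$present)[2]) stop_arg("empty surrogate collection")
  out <- apply(surr$present, c(3, 1), mean)   # epochs x pairs
  rownames(out) <- surr$epoch_labels
  out
}

#' Confidence interval for network density
#'
#' Gaussian (normal-approximation) 95% confidence interval for the density
#' of an inferred network: the standard error is the sample standard
#' deviation of the surrogate densities, and the interval is
#' `[d_obs - 1.96 s, d_obs + 1.96 s]`.  The lower bound may fall below zero;
#' it is reported as-is and flagged, since clipping would hide the
#' long-tailed sampling distributions that produce it.
#'
#' @param d_obs observed network density.
#' @param surrogate_densities numeric vector of surrogate densities for the
#'   same epoch (>= 2 values).
#' @return A list with `d_obs`, `se`, `lower`, `upper`,
#'   `degenerate` (TRUE when all surrogates agree and the interval collapses
#'   to a point), and `below_zero` (TRUE when the lower bound is negative).
#' @export
#' @examples
#' density_ci(0.1, c(0.08, 0.10, 0.12, 0.10))  # +/- 1.96 * se
density_ci <- function(d_obs, surrogate_densities) {
  if (length(surrogate_densities) < 2) {
    stop_arg("need at least 2 surrogate densities")
  }
  se <- sd(surrogate_densities)
  lower <- d_obs - 1.96 * se
  upper <- d_obs + 1.96 * se
  list(d_obs = d_obs, se = se, lower = lower, upper = upper,
       degenerate = (se == 0), below_zero = (lower < 0))
}

#' Edge and density uncertainty for inferred networks
#'
#' Convenience wrapper tying the pieces together: runs
#' [trial_bootstrap_networks()], and for each epoch reports the observed
#' density of the corresponding inferred network, the per-edge appearance
#' probabilities, the surrogate density distribution, its standard error,
#' and the 95% confidence interval.
#'
#' @inheritParams trial_bootstrap_networks
#' @param networks the observed networks from [infer_networks()] (same
#'   epochs, measure, and null).
#' @return An `fc_uncertainty` object: a list with `surrogates`,
#'   `edge_prob` (epochs x pairs), and `per_epoch`, a list holding for each
#'   epoch the [density_ci()] result augmented with the surrogate densities.
#' @export
assess_uncertainty <- function(ep, null, networks, q = 0.05, B_net = 100,
                               seed = NULL) {
  surr <- trial_bootstrap_networks(ep, null, q = q, B_net = B_net, seed = seed)
  prob <- edge_probability(surr)
  per_epoch <- lapply(seq_along(networks), function(e) {
    ci <- density_ci(network_density(networks[[e]]), surr$densities[e, ])
    ci$surrogate_densities <- surr$densities[e, ]
    ci
  })
  names(per_epoch) <- names(networks)
  structure(list(surrogates = surr, edge_prob = prob, per_epoch = per_epoch,
                 B_net = surr$B_net, seed = seed),
            class = "fc_uncertainty")
}

#' @export
print.fc_uncertainty <- function(x, ...) {
  cat("Network uncertainty (", x$B_net, " trial-bootstrap surrogates):\n", sep = "")
  for (nm in names(x$per_epoch)) {
    ci <- x$per_epoch[[nm]]
    cat(sprintf("  %-8s density %.3f, se %.4f, 95%% CI [%.3f, %.3f]%s\n",
                nm, ci$d_obs, ci$se, ci$lower, ci$upper,
                if (ci$below_zero) " (lower bound below 0)" else ""))
  }
  invisible(x)
}
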