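# Plotting helpers (base graphics; igraph layout when available).

#' Plot a binary functional network
#'
#' Draws the network with igraph when installed (nodes colored by region if
#' a region map is supplied), otherwise as a 0/1 adjacency image.
#'
#' @param x an `fc_network`.
#' @param region_of optional node-to-region map for coloring.
#' @param ... passed to the underlying plot call.
#' @export
plot.fc_network <- function(x, region_of = NULL, ...) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(
      d = as.data.frame(x$edges),
      directed = FALSE,
      vertices = data.frame(name = x$nodes))
    col <- "grey70"
    if (!is.null(region_of)) {
      pal <- grDevices::hcl.colors(max(region_of), "Dark 3")
      col <- pal[region_of]
    }
    igraph::plot.igraph(g, vertex.color = col, layout = igraph::layout_in_circle,
                        main = sprintf("%s network, epoch %s", x$measure, x$epoch),
                        ...)
  } else {
    A <- .adjacency(x)
    graphics::image(seq_along(x$nodes), seq_along(x$nodes),
                    A[, rev(seq_along(x$nodes))], axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("%s network, epoch %s", x$measure, x$epoch),
                    ...)
    graphics::axis(1, seq_along(x$nodes), x$nodes, las = 2)
    graphics::axis(2, seq_along(x$nodes), rev(x$nodes), las = 2)
  }
  invisible(x)
}

#' Density over time with confidence band
#'
#' For a sliding-window run, plots the observed network density against the
#' epoch midpoints with the 95% bootstrap confidence band; for a
#' before/after run, draws the two densities with whiskers.
#'
#' @param result an `fc_result` from [run_pipeline()] including an
#'   uncertainty stage.
#' @param true_density optional known density (or per-epoch vector) drawn as
#'   a reference line.
#' @param ... passed to [graphics::plot()].
#' @export
plot_density_timecourse <- function(result, true_density = NULL, ...) {
  stopifnot(inherits(result, "fc_result"))
  if (is.null(result$uncertainty)) {
    stop_arg("run the pipeline with b_net > 0 to plot confidence bands")
  }
  mids <- result$epochs$epoch_mid
  d <- result$densities
  ci <- result$uncertainty$per_epoch
  lo <- vapply(ci, `[[`, numeric(1), "lower")
  hi <- vapply(ci, `[[`, numeric(1), "upper")
  graphics::plot(mids, d, type = "n", ylim = range(0, hi, d, true_density),
                 xlab = "time relative to task onset (s)",
                 ylab = "network density", ...)
  graphics::polygon(c(mids, rev(mids)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("grey60", 0.5), border = NA)
  graphics::lines(mids, d, lwd = 2)
  if (!is.null(true_density)) {
    graphics::lines(mids, rep_len(true_density, length(mids)),
                    lty = 2, col = "firebrick")
  }
  invisible(result)
}
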