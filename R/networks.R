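#' Ground-truth network pair for a simulated session
#'
#' Bundles the "before task onset" and "after task onset" coupling structure
#' that [simulate_session()] injects into a synthetic recording, together
#' with the sensor-to-region assignment.  Region-level edge sets are always
#' the projection of the sensor-level edge sets through the region map
#' (within-region sensor edges project to nothing, since a region has no
#' self-edge).
#'
#' @param n_sensors number of sensors (nodes of the sensor-space network).
#' @param region_of integer vector of length `n_sensors` assigning each
#'   sensor to a region (1-based region indices).
#' @param before_edges,after_edges undirected sensor edge sets, as 2-column
#'   matrices (or lists of pairs) of sensor indices; stored with i < j.
#' @param labels optional sensor labels (default `"s1"`, `"s2"`, ...).
#'
#' @return An object of class `fc_truth` with fields `n_sensors`,
#'   `region_of`, `labels`, `before_edges`, `after_edges`,
#'   `region_before_edges`, `region_after_edges`.
#' @seealso [default_network_pair()] for the bundled 9-sensor example,
#'   [network_density()] for the density of an edge set.
#' @export
#' @examples
#' net <- default_network_pair()
#' nrow(net$before_edges)  # 3 sensor edges before task onset
#' nrow(net$region_after_edges)  # 1 region edge after task onset
true_network_pair <- function(n_sensors, region_of, before_edges, after_edges,
                              labels = NULL) {
  n_sensors <- as.integer(n_sensors)
  if (n_sensors < 2L) stop_arg("need at least 2 sensors")
  region_of <- as.integer(region_of)
  if (length(region_of) != n_sensors) {
    stop_arg("region_of must assign every sensor to a region")
  }
  labels <- labels %||% paste0("s", seq_len(n_sensors))
  structure(list(
    n_sensors = n_sensors,
    region_of = region_of,
    labels = labels,
    before_edges = edge_matrix(before_edges, n_sensors),
    after_edges = edge_matrix(after_edges, n_sensors),
    region_before_edges = project_edges(edge_matrix(before_edges, n_sensors), region_of),
    region_after_edges = project_edges(edge_matrix(after_edges, n_sensors), region_of)
  ), class = "fc_truth")
}

#' Default 9-sensor, 3-region ground-truth network pair
#'
#' The bundled example layout used by the default simulation: nine sensors in
#' three regions of three.  Before task onset three sensor edges are active
#' (density 3/36 = 0.083), projecting to two region edges (region density
#' 2/3); after task onset six sensor edges between regions 1 and 3 are active
#' (density 6/36 = 0.167), projecting to a single region edge (1/3).
#'
#' @return An `fc_truth` object (see [true_network_pair()]).
#' @export
default_network_pair <- function() {
  true_network_pair(
    n_sensors = 9L,
    region_of = rep(1:3, each = 3L),
    before_edges = rbind(c(1L, 4L), c(2L, 5L), c(6L, 9L)),
    after_edges = rbind(c(1L, 7L), c(1L, 8L), c(2L, 7L),
                        c(2L, 9L), c(3L, 8L), c(3L, 9L))
  )
}

#' @export
print.fc_truth <- function(x, ...) {
  cat("Ground-truth network pair:", x$n_sensors, "sensors,",
      length(unique(x$region_of)), "regions\n")
  cat("  before:", nrow(x$before_edges), "sensor edges ->",
      nrow(x$region_before_edges), "region edges\n")
  cat("  after: ", nrow(x$after_edges), "sensor edges ->",
      nrow(x$region_after_edges), "region edges\n")
  invisible(x)
}

#' Density of an undirected network
#'
#' The ratio of the number of edges to the number of possible edges,
#' `n * (n - 1) / 2`, for an undirected graph with no self-edges.
#'
#' @param net an `fc_network` (see [infer_networks()]), or an edge matrix if
#'   `n_nodes` is given.
#' @param n_nodes node count, required when `net` is a plain edge matrix.
#' @return Density in `[0, 1]`.
#' @export
#' @examples
#' network_density(rbind(c(1, 2), c(2, 3), c(1, 9)), n_nodes = 9)  # 3/36
network_density <- function(net, n_nodes = NULL) {
  if (inherits(net, "fc_network")) {
    n_nodes <- length(net$nodes)
    edges <- net$edges
  } else {
    if (is.null(n_nodes)) stop_arg("n_nodes is required for a raw edge set")
    edges <- edge_matrix(net, n_nodes)
  }
  if (n_nodes < 2L) stop_arg("density is undefined for fewer than 2 nodes")
  nrow(edges) / (n_nodes * (n_nodes - 1L) / 2)
}
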