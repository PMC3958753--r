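# Delimited-text readers and writers.  Node indices are 0-based in all
# files (stated in each header); everything is plain text so runs diff.

#' Read a multichannel recording from delimited text
#'
#' @param data_file tab- or comma-delimited voltage matrix.  With
#'   `orientation = "samples"` (the default, and what [write_recording()]
#'   produces) rows are samples and columns are channels; with
#'   `"channels"` rows are channels and columns are samples.
#' @param fs sampling rate in Hz.
#' @param onsets_file one trial-onset time (seconds) per line; optional.
#' @param region_file two-column delimited file mapping 0-based channel
#'   index to region index; optional.
#' @param orientation matrix layout of `data_file`.
#' @return An [fc_recording()].
#' @export
read_recording <- function(data_file, fs, onsets_file = NULL,
                           region_file = NULL,
                           orientation = c("samples", "channels")) {
  orientation <- match.arg(orientation)
  if (!file.exists(data_file)) stop_arg("data file not found: ", data_file)
  # samples orientation carries a channel-label header; a channels x samples
  # matrix has no header row
  dt <- data.table::fread(data_file, header = (orientation == "samples"))
  m <- as.matrix(dt)
  labels <- colnames(dt)
  if (orientation == "samples") m <- t(m) else labels <- NULL
  onsets <- numeric(0)
  if (!is.null(onsets_file)) {
    if (!file.exists(onsets_file)) {
      stop_arg("onsets file not found: ", onsets_file)
    }
    onsets <- scan(onsets_file, what = numeric(), quiet = TRUE,
                   comment.char = "#")
  }
  region_of <- NULL
  if (!is.null(region_file)) {
    if (!file.exists(region_file)) {
      stop_arg("region map file not found: ", region_file)
    }
    rm <- data.table::fread(region_file, header = TRUE)
    if (ncol(rm) < 2) {
      stop_arg(region_file, ": expected two columns (0-based node index, region)")
    }
    region_of <- integer(nrow(m))
    region_of[rm[[1]] + 1L] <- as.integer(rm[[2]])
  }
  fc_recording(m, fs = fs, onsets = onsets, region_of = region_of,
               labels = labels)
}

#' Write a recording as delimited text
#'
#' Writes `<prefix>_data.tsv` (samples in rows, one column per channel),
#' `<prefix>_onsets.txt` (one onset time in seconds per line), and, when a
#' region map is present, `<prefix>_regions.tsv` (0-based node index,
#' region).  [read_recording()] restores the result.
#'
#' @param rec an [fc_recording()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, dir, prefix = "recording") {
  stopifnot(inherits(rec, "fc_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, paste0(prefix, "_data.tsv")),
             onsets = file.path(dir, paste0(prefix, "_onsets.txt")))
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$labels)
  data.table::fwrite(dt, paths[["data"]], sep = "\t")
  writeLines(format(rec$onsets, scientific = FALSE, trim = TRUE),
             paths[["onsets"]])
  if (!is.null(rec$region_of)) {
    paths <- c(paths, regions = file.path(dir, paste0(prefix, "_regions.tsv")))
    data.table::fwrite(
      data.table::data.table(node = seq_len(nrow(rec$data)) - 1L,
                             region = rec$region_of),
      paths[["regions"]], sep = "\t")
  }
  invisible(paths)
}

# square 0/1 adjacency matrix of a network
.adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[net$edges] <- 1L
    A[net$edges[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Write inferred networks and summaries
#'
#' For each epoch writes an edge list `edges_<epoch>.tsv` (0-based
#' `node_i`, `node_j`, `p_value`) and a 0/1 adjacency table
#' `adjacency_<epoch>.tsv`, plus a `summary.json` with the run parameters
#' (q, B_null, L, seed) and the per-epoch densities; with uncertainty
#' results, also per-epoch density confidence intervals and per-pair edge
#' probabilities (`edge_probability.tsv`).
#'
#' @param result an `fc_result` from [run_pipeline()], or a list of
#'   `fc_network` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_networks <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nets <- if (inherits(result, "fc_result")) result$networks else result
  paths <- character(0)
  safe <- function(x) gsub("[^A-Za-z0-9_.-]", "", gsub("\\+", "p", x))
  for (nm in names(nets)) {
    net <- nets[[nm]]
    ep <- safe(nm)
    ef <- file.path(dir, paste0("edges_", ep, ".tsv"))
    el <- data.table::data.table(
      node_i = net$pairs[, 1L] - 1L, node_j = net$pairs[, 2L] - 1L,
      p_value = net$p, statistic = net$stat,
      edge = as.integer(seq_len(nrow(net$pairs)) %in%
                          pair_position(net$edges, length(net$nodes))))
    data.table::fwrite(el, ef, sep = "\t")
    af <- file.path(dir, paste0("adjacency_", ep, ".tsv"))
    data.table::fwrite(data.table::as.data.table(.adjacency(net)), af, sep = "\t")
    paths <- c(paths, ef, af)
  }
  summary <- list(
    package_version = as.character(packageVersion("fcnet")),
    q = nets[[1]]$q, measure = nets[[1]]$measure,
    densities = lapply(nets, network_density)
  )
  if (inherits(result, "fc_result")) {
    summary$L <- result$null$L
    summary$B_null <- result$null$B_null
    summary$seed <- result$config$seed
    if (!is.null(result$uncertainty)) {
      summary$B_net <- result$uncertainty$B_net
      summary$density_ci <- lapply(result$uncertainty$per_epoch, function(ci) {
        ci[c("d_obs", "se", "lower", "upper", "degenerate", "below_zero")]
      })
      pf <- file.path(dir, "edge_probability.tsv")
      prob <- result$uncertainty$edge_prob
      pairs <- result$uncertainty$surrogates$pairs
      pt <- data.table::data.table(node_i = pairs[, 1L] - 1L,
                                   node_j = pairs[, 2L] - 1L)
      for (e in seq_len(nrow(prob))) pt[[rownames(prob)[e]]] <- prob[e, ]
      data.table::fwrite(pt, pf, sep = "\t")
      paths <- c(paths, pf)
    }
    if (!is.null(result$truth_eval)) summary$truth_eval <- result$truth_eval
  }
  sf <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sf))
}

#' Write a ground-truth edge list
#'
#' Writes the simulated session's true sensor edges as delimited text with
#' columns `node_i`, `node_j` (0-based) and `epoch_label`
#' (`before`/`after`).
#'
#' @param truth an `fc_truth` object.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "fc_truth"))
  rows <- rbind(
    if (nrow(truth$before_edges)) {
      data.frame(node_i = truth$before_edges[, 1L] - 1L,
                 node_j = truth$before_edges[, 2L] - 1L,
                 epoch_label = "before")
    },
    if (nrow(truth$after_edges)) {
      data.frame(node_i = truth$after_edges[, 1L] - 1L,
                 node_j = truth$after_edges[, 2L] - 1L,
                 epoch_label = "after")
    })
  data.table::fwrite(rows, file, sep = "\t")
  invisible(file)
}
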