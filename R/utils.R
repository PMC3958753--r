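# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# Canonicalize an edge set into an integer matrix with columns i < j,
# duplicates removed, rows sorted.  Accepts a 2-column matrix/data.frame or
# a list of length-2 vectors; NULL/empty -> 0-row matrix.
edge_matrix <- function(edges, n_nodes = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    m <- matrix(integer(0), ncol = 2L)
  } else {
    if (is.list(edges) && !is.data.frame(edges)) {
      edges <- do.call(rbind, lapply(edges, function(e) as.integer(e[1:2])))
    }
    m <- as.matrix(edges)
    if (ncol(m) != 2L) stop_arg("an edge set needs exactly two columns (i, j)")
    storage.mode(m) <- "integer"
  }
  if (nrow(m)) {
    if (any(m[, 1L] == m[, 2L])) stop_arg("self-edges are not allowed")
    m <- cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
    m <- unique(m)
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    if (!is.null(n_nodes) && (any(m < 1L) || any(m > n_nodes))) {
      stop_arg("edge indices must lie in 1..", n_nodes)
    }
  }
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

# All unordered node pairs of an n-node graph, in column-major upper-triangle
# order.  This ordering is the pair index used throughout the package.
pair_index <- function(n) {
  if (n < 2L) stop_arg("need at least 2 nodes to enumerate pairs")
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i = i, j = j)
}

# Rows of `edges` as positions in pair_index(n).
pair_position <- function(edges, n) {
  if (!nrow(edges)) return(integer(0))
  # position of (i, j), i < j, in column-major upper triangle
  (edges[, 2L] - 1L) * (edges[, 2L] - 2L) / 2L + edges[, 1L]
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL runs in the ambient stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Project sensor edges through a sensor -> region map; within-region edges
# drop out (a region has no self-edge).
project_edges <- function(edges, region_of) {
  region_of <- as.integer(region_of)
  if (!nrow(edges)) return(edge_matrix(NULL))
  r <- cbind(region_of[edges[, 1L]], region_of[edges[, 2L]])
  r <- r[r[, 1L] != r[, 2L], , drop = FALSE]
  edge_matrix(r)
}
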