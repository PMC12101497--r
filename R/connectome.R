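#' Pearson correlation matrix of a node time-series matrix
#'
#' @param ts node x timepoint matrix with at least two timepoints; every
#'   node must have nonzero variance.
#' @return Symmetric node x node correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2) stop("need at least two timepoints", call. = FALSE)
  v <- apply(ts, 1, sd)
  if (any(v == 0)) {
    bad <- rownames(ts)[which(v == 0)[1]]
    if (is.null(bad)) bad <- which(v == 0)[1]
    stop(sprintf("node '%s' has zero variance", bad), call. = FALSE)
  }
  cor(t(ts))
}

#' Fisher's z transform of correlation coefficients
#'
#' `z = arctanh(r)`. Correlations of exactly +/-1 (typically duplicate
#' node series) are clipped to `+/-(1 - 1e-7)` with a warning so batch
#' runs do not produce infinities; values outside `[-1, 1]` are an error.
#'
#' @param r correlations (vectorized).
#' @return Fisher-z values.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warning("correlation(s) of exactly +/-1 clipped to +/-(1 - 1e-7)")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Edge index map: fixed enumeration of node pairs
#'
#' Enumerates the strict upper triangle in row-major order:
#' `(1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n)`. This single
#' convention is used everywhere an edge index appears (feature vectors,
#' consensus sets, lesioning, endpoint lookup). Indices are 1-based in R;
#' serialized edge files record the equivalent 0-based convention string
#' `"upper-row-major-0based"`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @return A list of class `edge_index_map` with fields `n_nodes`,
#'   `n_edges`, and the endpoint vectors `i`, `j` (`i < j`).
#' @examples
#' map <- edge_index_map(268)
#' map$n_edges  # 35778
#' @export
edge_index_map <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 2)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  structure(
    list(n_nodes = n_nodes, n_edges = (n_nodes * (n_nodes - 1L)) %/% 2L,
         i = i, j = as.integer(j), ordering = "upper-row-major-0based"),
    class = "edge_index_map"
  )
}

#' @export
print.edge_index_map <- function(x, ...) {
  cat(sprintf("Edge index map: %d nodes, %d edges (%s)\n",
              x$n_nodes, x$n_edges, x$ordering))
  invisible(x)
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' @param z symmetric node x node matrix.
#' @param map an [edge_index_map()]; defaults to one matching `z`.
#' @return Numeric edge vector of length `n (n - 1) / 2`, ordered per the
#'   map convention.
#' @export
vectorize_upper <- function(z, map = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("matrix must be square", call. = FALSE)
  if (is.null(map)) map <- edge_index_map(nrow(z))
  if (map$n_nodes != nrow(z)) {
    stop(sprintf("map is for %d nodes but matrix has %d",
                 map$n_nodes, nrow(z)), call. = FALSE)
  }
  z[cbind(map$i, map$j)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]; the diagonal (excluded from the edge
#' features) is set to 0.
#'
#' @param v edge vector of length `map$n_edges`.
#' @param map an [edge_index_map()].
#' @return Symmetric node x node matrix with zero diagonal.
#' @export
devectorize_upper <- function(v, map) {
  if (length(v) != map$n_edges) {
    stop(sprintf("edge vector has length %d; map expects %d",
                 length(v), map$n_edges), call. = FALSE)
  }
  z <- matrix(0, map$n_nodes, map$n_nodes)
  z[cbind(map$i, map$j)] <- v
  z[cbind(map$j, map$i)] <- v
  z
}

#' Edge index <-> node pair conversion
#'
#' `edge_endpoints()` returns the `(i, j)` node pair (with `i < j`) of
#' each edge index; `edge_index()` is its inverse.
#'
#' @param index edge indices (1-based, vectorized).
#' @param map an [edge_index_map()].
#' @return `edge_endpoints()`: a two-column integer matrix with columns
#'   `i`, `j`. `edge_index()`: integer edge indices.
#' @examples
#' map <- edge_index_map(268)
#' edge_endpoints(1, map)            # (1, 2)
#' edge_endpoints(map$n_edges, map)  # (267, 268)
#' @export
edge_endpoints <- function(index, map) {
  index <- as.integer(index)
  if (any(index < 1 | index > map$n_edges)) {
    stop(sprintf("edge index out of range [1, %d]", map$n_edges),
         call. = FALSE)
  }
  cbind(i = map$i[index], j = map$j[index])
}

#' @param i,j node indices (`i != j`; order-free).
#' @rdname edge_endpoints
#' @export
edge_index <- function(i, j, map) {
  i <- as.integer(i)
  j <- as.integer(j)
  if (any(i == j)) stop("diagonal entries are not edges", call. = FALSE)
  if (any(i < 1 | i > map$n_nodes | j < 1 | j > map$n_nodes)) {
    stop("node index out of range", call. = FALSE)
  }
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  n <- map$n_nodes
  as.integer(((lo - 1L) * (2L * n - lo)) %/% 2L + (hi - lo))
}

#' Fisher-z connectome from a node time-series matrix
#'
#' Pearson correlation between every node pair, Fisher-z transformed;
#' the diagonal is set to 0 (self-correlations carry no information and
#' are excluded from edge features).
#'
#' @param ts node x timepoint matrix.
#' @return Symmetric node x node Fisher-z matrix with zero diagonal.
#' @export
connectome_matrix <- function(ts) {
  r <- correlation_matrix(ts)
  diag(r) <- 0
  z <- fisher_z(r)
  diag(z) <- 0
  z
}

#' Subjects x edges feature matrix from a list of time series
#'
#' @param ts_list named list of node x timepoint matrices (one per
#'   subject), as from [simulate_timeseries()].
#' @param map an [edge_index_map()] matching the node count.
#' @return Numeric matrix, one row per subject, one column per edge.
#' @export
edge_matrix <- function(ts_list, map = NULL) {
  stopifnot(length(ts_list) >= 1)
  if (is.null(map)) map <- edge_index_map(nrow(ts_list[[1]]))
  X <- t(vapply(ts_list,
                function(ts) vectorize_upper(connectome_matrix(ts), map),
                numeric(map$n_edges)))
  rownames(X) <- names(ts_list)
  X
}

#' Read / write per-subject edge vectors
#'
#' Edge vectors are stored one file per subject (single numeric column,
#' no header) together with a sidecar JSON recording `n_nodes` and the
#' edge-ordering convention string.
#'
#' @param X subjects x edges matrix.
#' @param dir output directory (created if needed).
#' @param map the [edge_index_map()] used to build `X`.
#' @return `write_edge_vectors()` returns `dir`; `read_edge_vectors()`
#'   returns a list with elements `X` and `map`.
#' @export
write_edge_vectors <- function(X, dir, map) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  for (s in seq_len(nrow(X))) {
    write(formatC(X[s, ], format = "g", digits = 17),
          file.path(dir, paste0(ids[s], ".txt")), ncolumns = 1)
  }
  jsonlite::write_json(
    list(n_nodes = map$n_nodes, n_edges = map$n_edges,
         ordering = map$ordering, subjects = ids),
    file.path(dir, "edges.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_edge_vectors
#' @export
read_edge_vectors <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "edges.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$ordering, "upper-row-major-0based")) {
    stop("unsupported edge ordering: ", meta$ordering, call. = FALSE)
  }
  map <- edge_index_map(meta$n_nodes)
  X <- t(vapply(meta$subjects, function(id) {
    scan(file.path(dir, paste0(id, ".txt")), quiet = TRUE)
  }, numeric(map$n_edges)))
  rownames(X) <- meta$subjects
  list(X = X, map = map)
}
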