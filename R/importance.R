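#' Consensus features across all cross-validation folds
#'
#' Keeps only the edges selected in every fold of a LOOCV run; per edge,
#' the absolute refit weights are summed over all folds. Different folds
#' select different features, so the consensus can be empty (a warning
#' is emitted and an empty set returned).
#'
#' @param folds a `wm_fold_result` (from [loocv_predict()] or one element
#'   of `cpm_predict()$folds`), or any list with `selected` (features x
#'   folds index matrix) and `fold_weights` (matching weight matrix).
#' @return A data frame of class `wm_consensus` with columns `edge`
#'   (index, ascending) and `weight` (summed absolute weight).
#' @export
consensus_features <- function(folds) {
  sel <- folds$selected
  w <- folds$fold_weights
  if (is.null(sel) || is.null(w)) {
    stop("`folds` must carry 'selected' and 'fold_weights'", call. = FALSE)
  }
  n_folds <- ncol(sel)
  common <- Reduce(intersect, lapply(seq_len(n_folds),
                                     function(f) sel[, f]))
  common <- sort(common)
  if (length(common) == 0) {
    warning("no feature was selected in every fold; consensus is empty")
  }
  weight <- vapply(common, function(e) {
    sum(vapply(seq_len(n_folds),
               function(f) abs(w[match(e, sel[, f]), f]),
               numeric(1)))
  }, numeric(1))
  out <- data.frame(edge = as.integer(common), weight = weight)
  class(out) <- c("wm_consensus", "data.frame")
  out
}

#' Between-network edge-strength matrix
#'
#' `Edge[I, J]` sums the absolute consensus weights of all edges with one
#' endpoint in network I and the other in network J; edges inside one
#' network accumulate on the diagonal `Edge[I, I]`.
#'
#' @param consensus a [consensus_features()] result (columns `edge`,
#'   `weight`).
#' @param map the [edge_index_map()] the edge indices refer to.
#' @param atlas a `wm_atlas` partition covering all nodes.
#' @return Symmetric networks x networks nonnegative matrix.
#' @export
network_edge_matrix <- function(consensus, map, atlas) {
  if (nrow(atlas) != map$n_nodes) {
    stop("atlas and edge map disagree on the node count", call. = FALSE)
  }
  if (anyNA(atlas$network)) {
    stop("every node needs a network label", call. = FALSE)
  }
  nets <- levels(atlas$network)
  E <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  if (nrow(consensus) == 0) return(E)
  ep <- edge_endpoints(consensus$edge, map)
  a <- as.integer(atlas$network[ep[, "i"]])
  b <- as.integer(atlas$network[ep[, "j"]])
  for (r in seq_len(nrow(consensus))) {
    wgt <- abs(consensus$weight[r])
    E[a[r], b[r]] <- E[a[r], b[r]] + wgt
    if (a[r] != b[r]) E[b[r], a[r]] <- E[b[r], a[r]] + wgt
  }
  E
}

#' Relative degree of each network
#'
#' Binarizes the between-network edge matrix (nonzero -> 1) and reports
#' each network's share of the total: `RD[I] = sum_J b(Edge[I, J]) /
#' sum_I sum_J b(Edge[I, J])`, evaluated literally as an ordered double
#' sum over the symmetric matrix (the diagonal counts once per row), so
#' the RD values sum to exactly 1 whenever any entry is nonzero.
#'
#' @param E symmetric networks x networks matrix from
#'   [network_edge_matrix()].
#' @return Named numeric vector of relative degrees (attribute
#'   `all_zero` flags a degenerate all-zero input, returned as zeros).
#' @export
relative_degree <- function(E) {
  if (!isTRUE(all.equal(E, t(E)))) {
    stop("edge matrix must be symmetric", call. = FALSE)
  }
  B <- (E != 0) * 1
  total <- sum(B)
  if (total == 0) {
    warning("all-zero edge matrix; relative degree undefined")
    rd <- setNames(rep(0, nrow(E)), rownames(E))
    attr(rd, "all_zero") <- TRUE
    return(rd)
  }
  rd <- rowSums(B) / total
  attr(rd, "all_zero") <- FALSE
  rd
}

#' Node degree within a network, ranked
#'
#' Counts, for every node of the chosen network, the consensus edges
#' incident to it, and ranks nodes by decreasing degree (ties broken by
#' lower node id).
#'
#' @inheritParams network_edge_matrix
#' @param network network label to rank nodes within.
#' @return Data frame with columns `node`, `network`, `degree`, `rank`,
#'   sorted by decreasing degree.
#' @export
node_degree <- function(consensus, map, atlas, network) {
  check_network(atlas, network)
  nodes <- atlas$node[as.character(atlas$network) == network]
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(consensus) > 0) {
    ep <- edge_endpoints(consensus$edge, map)
    counts <- table(factor(c(ep[, "i"], ep[, "j"]), levels = nodes))
    degree[] <- as.integer(counts)
  }
  ord <- order(-degree, nodes)
  data.frame(node = nodes[ord], network = network,
             degree = as.integer(degree[ord]),
             rank = seq_along(nodes), row.names = NULL)
}
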