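#' Feature space after removing one network's nodes
#'
#' Returns the indices of the edges whose two endpoints both lie outside
#' the lesioned network: lesioning k of n nodes retains exactly
#' `(n - k)(n - k - 1) / 2` edges.
#'
#' @param map an [edge_index_map()].
#' @param atlas a `wm_atlas` partition.
#' @param network label of the network to remove.
#' @return Integer vector of retained edge indices.
#' @export
lesion_feature_space <- function(map, atlas, network) {
  check_network(atlas, network)
  if (nrow(atlas) != map$n_nodes) {
    stop("atlas and edge map disagree on the node count", call. = FALSE)
  }
  out <- as.character(atlas$network) != network
  which(out[map$i] & out[map$j])
}

#' Virtual-lesion scan over networks
#'
#' For each network in turn, removes its nodes from the feature space,
#' recomputes the per-mille feature counts on the reduced edge total,
#' and reruns the complete LOOCV-SVR prediction with permutation testing.
#' BH correction is applied across the whole scan family (number of
#' thresholds x number of lesioned networks); the identical permutation
#' shuffles of `y` are reused for every lesion so scans are comparable
#' and deterministic.
#'
#' @param X subjects x edges feature matrix (full, unlesioned).
#' @param y behavioral scores.
#' @param atlas a `wm_atlas` partition matching the edge count of `X`.
#' @param config a [prediction_config()].
#' @param networks networks to lesion; default all networks in the atlas.
#' @param alpha FDR level for the scan family.
#' @return An object of class `wm_lesion_scan`: a `summary` data frame
#'   with one row per (network, threshold) — columns `network`,
#'   `per_mille`, `n_features`, `r`, `p`, `q`, `significant` — plus
#'   `retained` (edge indices per network) and `fdr_family_size`.
#' @export
lesion_scan <- function(X, y, atlas, config = prediction_config(),
                        networks = NULL, alpha = 0.05) {
  map <- edge_index_map(nrow(atlas))
  if (ncol(X) != map$n_edges) {
    stop("ncol(X) does not match the atlas edge count", call. = FALSE)
  }
  if (is.null(networks)) networks <- levels(atlas$network)
  rows <- list()
  retained_list <- list()
  for (net in networks) {
    retained <- lesion_feature_space(map, atlas, net)
    retained_list[[net]] <- retained
    res <- run_engine(X[, retained, drop = FALSE], y, config$per_mille,
                      config, n_permutations = config$n_permutations)
    r_obs <- res$r[1, ]
    r_perm <- res$r[-1, , drop = FALSE]
    p <- colSums(sweep(r_perm, 2, r_obs, ">"), na.rm = TRUE) /
      config$n_permutations
    rows[[net]] <- data.frame(
      network = net, per_mille = config$per_mille,
      n_features = res$kcounts, r = r_obs, p = p)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  fdr <- fdr_correct(summary$p, alpha)
  summary$q <- fdr$q
  summary$significant <- fdr$significant
  structure(
    list(summary = summary, retained = retained_list,
         fdr_family_size = nrow(summary), config = config),
    class = "wm_lesion_scan"
  )
}

#' @export
print.wm_lesion_scan <- function(x, ...) {
  cat(sprintf("Virtual-lesion scan: %d networks x %d thresholds (FDR family %d)\n",
              length(x$retained), length(x$config$per_mille),
              x$fdr_family_size))
  agg <- aggregate(significant ~ network, x$summary, sum)
  names(agg)[2] <- "significant_thresholds"
  print(agg, row.names = FALSE)
  invisible(x)
}
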