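#' Simulate multi-subject node time series with block correlation
#'
#' Draws stationary Gaussian node time series whose population correlation
#' is `rho_within` between nodes of the same network and `rho_between`
#' between nodes of different networks. With `subject_sd > 0`, each
#' subject's within-network correlation is jittered per network
#' (truncated so the covariance stays positive definite), giving
#' trait-like between-subject variance in connectivity on top of
#' finite-scan sampling noise.
#'
#' @param n_subjects number of subjects.
#' @param atlas a `wm_atlas` partition (see [make_atlas()]).
#' @param n_timepoints scan length in samples (>= 2).
#' @param rho_within population correlation for same-network node pairs.
#' @param rho_between population correlation for different-network pairs;
#'   must satisfy `-1 < rho_between <= rho_within < 1`.
#' @param subject_sd standard deviation of the per-subject, per-network
#'   jitter added to `rho_within` (correlation units; 0 disables).
#' @param ar1 lag-1 autoregressive coefficient applied along time
#'   (default 0: temporally white, since the pipeline consumes only
#'   static correlation matrices). Innovations are scaled by
#'   `sqrt(1 - ar1^2)`, so the stationary cross-node correlation
#'   structure is unchanged.
#' @param seed integer RNG seed; identical seeds reproduce identical data.
#' @return A named list of `n_subjects` matrices (node x timepoint), with
#'   row names taken from `atlas$node`.
#' @examples
#' atlas <- make_atlas(10, c(5, 5))
#' ts <- simulate_timeseries(2, atlas, 50, 0.5, 0.1, seed = 1)
#' dim(ts[[1]])
#' @export
simulate_timeseries <- function(n_subjects, atlas, n_timepoints = 500,
                                rho_within = 0.5, rho_between = 0.1,
                                subject_sd = 0, ar1 = 0, seed = NULL) {
  stopifnot(n_subjects >= 1, n_timepoints >= 2, subject_sd >= 0,
            abs(ar1) < 1)
  if (!(rho_between > -1 && rho_between <= rho_within && rho_within < 1)) {
    stop("need -1 < rho_between <= rho_within < 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_nodes <- nrow(atlas)
  networks <- levels(atlas$network)
  net_idx <- as.integer(atlas$network)

  out <- vector("list", n_subjects)
  names(out) <- sprintf("S%03d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    rho_net <- rep(rho_within, length(networks))
    if (subject_sd > 0) {
      rho_net <- rho_net + rnorm(length(networks), 0, subject_sd)
      # keep each block's correlation inside the positive-definite range
      rho_net <- pmin(pmax(rho_net, rho_between), 0.97)
    }
    sigma <- matrix(rho_between, n_nodes, n_nodes)
    for (k in seq_along(networks)) {
      members <- which(net_idx == k)
      sigma[members, members] <- rho_net[k]
    }
    diag(sigma) <- 1
    ch <- tryCatch(chol(sigma), error = function(e) {
      stop("requested block covariance is not positive definite",
           call. = FALSE)
    })
    z <- matrix(rnorm(n_timepoints * n_nodes), n_timepoints, n_nodes)
    x <- z %*% ch  # timepoint x node, correlated across nodes
    if (ar1 != 0) {
      x <- apply(x * sqrt(1 - ar1^2), 2, function(col) {
        as.numeric(stats::filter(col, ar1, method = "recursive"))
      })
    }
    ts <- t(x)  # node x timepoint
    rownames(ts) <- atlas$node
    out[[s]] <- ts
  }
  out
}

#' Describe the ground truth of a simulated edge-behavior association
#'
#' @param signal_edges unique edge indices (1-based, row-major upper
#'   triangle; see [edge_index_map()]) that carry true association.
#' @param weights real coefficient per signal edge.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the behavioral score (>= 0).
#' @param target_network label of the network containing the signal edges.
#' @param seed integer seed used when drawing the behavioral noise.
#' @return A list of class `wm_ground_truth`.
#' @export
ground_truth <- function(signal_edges, weights, noise_sd,
                         target_network = NA_character_, seed = 1L) {
  signal_edges <- as.integer(signal_edges)
  if (anyDuplicated(signal_edges)) {
    stop("signal edge indices must be unique", call. = FALSE)
  }
  if (length(weights) != length(signal_edges)) {
    stop("one weight per signal edge required", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a nonnegative number", call. = FALSE)
  }
  structure(
    list(signal_edges = signal_edges, weights = as.numeric(weights),
         noise_sd = noise_sd, target_network = target_network,
         seed = as.integer(seed)),
    class = "wm_ground_truth"
  )
}

#' Sample signal edges inside a target network
#'
#' @param map an [edge_index_map()].
#' @param atlas a `wm_atlas` partition.
#' @param network target network label.
#' @param n_edges number of signal edges to draw.
#' @param endpoints `"both"` restricts to edges with both endpoints in the
#'   target network; `"either"` requires only one endpoint inside.
#' @param seed integer RNG seed.
#' @return Integer vector of edge indices.
#' @export
sample_signal_edges <- function(map, atlas, network, n_edges,
                                endpoints = c("both", "either"),
                                seed = NULL) {
  endpoints <- match.arg(endpoints)
  check_network(atlas, network)
  in_net <- as.character(atlas$network) == network
  inside_i <- in_net[map$i]
  inside_j <- in_net[map$j]
  candidates <- if (endpoints == "both") {
    which(inside_i & inside_j)
  } else {
    which(inside_i | inside_j)
  }
  if (length(candidates) < n_edges) {
    stop(sprintf("network '%s' offers only %d eligible edges (%d requested)",
                 network, length(candidates), n_edges), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sort(sample(candidates, n_edges))
}

#' Embed a linear edge-driven behavioral score
#'
#' Computes `y = X[, signal] %*% weights + N(0, noise_sd)` per subject,
#' with the noise drawn reproducibly from `truth$seed`.
#'
#' @param edges subjects x edges feature matrix (edge vectors as rows).
#' @param truth a [ground_truth()] description.
#' @return Numeric vector of behavioral scores, one per subject (named by
#'   `rownames(edges)` when present).
#' @export
embed_behavior <- function(edges, truth) {
  stopifnot(inherits(truth, "wm_ground_truth"))
  if (max(truth$signal_edges) > ncol(edges) || min(truth$signal_edges) < 1) {
    stop("signal edge index out of range for the supplied edge matrix",
         call. = FALSE)
  }
  signal <- as.vector(edges[, truth$signal_edges, drop = FALSE] %*%
                        truth$weights)
  set.seed(truth$seed)
  y <- signal + rnorm(nrow(edges), 0, truth$noise_sd)
  names(y) <- rownames(edges)
  y
}

#' Simulate change-detection trial counts under a guessing model
#'
#' Generates hit and false-alarm counts under the whole-display guessing
#' model: with `d = min(true_k / set_size, 1)` the probability of storing
#' the probed item, hits are Binomial(`n_change`, `d + (1 - d) * g`) and
#' false alarms Binomial(`n_nochange`, `(1 - d) * g`). Under this model
#' the expected Cowan estimate `S * (H - F)` equals `min(true_k, S)`, so
#' capacity scoring is unbiased below the set-size ceiling.
#'
#' @param true_k generating capacity in items (>= 0).
#' @param set_size number of to-be-memorized items S (>= 1).
#' @param guess_rate guessing probability g in `[0, 1]`.
#' @param n_change,n_nochange trial counts per trial type.
#' @param seed integer RNG seed.
#' @return A list of class `wm_trial_counts` with fields `set_size`,
#'   `hits`, `n_change`, `false_alarms`, `n_nochange`.
#' @examples
#' tc <- simulate_change_detection_trials(2, 4, 0.3, 1000, 1000, seed = 1)
#' cowan_k_trials(tc)  # close to 2
#' @export
simulate_change_detection_trials <- function(true_k, set_size, guess_rate,
                                             n_change, n_nochange,
                                             seed = NULL) {
  stopifnot(true_k >= 0, set_size >= 1, n_change >= 0, n_nochange >= 0)
  if (guess_rate < 0 || guess_rate > 1) {
    stop("guess_rate must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- min(true_k / set_size, 1)
  hits <- rbinom(1, n_change, d + (1 - d) * guess_rate)
  fas <- rbinom(1, n_nochange, (1 - d) * guess_rate)
  structure(
    list(set_size = set_size, hits = hits, n_change = n_change,
         false_alarms = fas, n_nochange = n_nochange),
    class = "wm_trial_counts"
  )
}

#' Simulate a complete resting-state prediction cohort
#'
#' End-to-end generator used throughout the test suite: simulates node
#' time series with trait-like connectivity variation, assembles Fisher-z
#' edge vectors, plants a sparse linear edge-behavior association inside
#' one target network, and scales the behavioral noise to a requested
#' signal-to-noise ratio.
#'
#' The defaults mirror the study scale this package emulates: 103
#' subjects, the 268-node / 10-network partition of [default_atlas()],
#' 30 signal edges confined to the 20-node cerebellum network, and
#' SNR 1.5 (defined as `sd(signal) / sd(noise)` on the behavior).
#'
#' @param n_subjects cohort size.
#' @param atlas a `wm_atlas`; defaults to [default_atlas()].
#' @param n_timepoints scan length in samples.
#' @param target_network network containing all signal edges.
#' @param n_signal_edges number of edges carrying true association.
#' @param snr ratio `sd(signal) / sd(noise)` for the behavior score; `Inf`
#'   gives a noiseless behavior.
#' @param rho_within,rho_between population block correlations.
#' @param subject_sd per-subject, per-network jitter of `rho_within`.
#' @param weight_range range of the Uniform draw for signal-edge weights.
#' @param endpoints signal-edge placement rule (see [sample_signal_edges()]).
#' @param seed master seed; all randomness derives from it.
#' @param keep_timeseries retain the raw time series in the result?
#' @return A list of class `wm_cohort`: `atlas`, `map`, `X` (subjects x
#'   edges Fisher-z feature matrix), `y` (behavior), `truth`
#'   ([ground_truth()]), and optionally `timeseries`.
#' @export
simulate_cohort <- function(n_subjects = 103, atlas = default_atlas(),
                            n_timepoints = 500,
                            target_network = "cerebellum",
                            n_signal_edges = 30, snr = 1.5,
                            rho_within = 0.5, rho_between = 0.1,
                            subject_sd = 0.05,
                            weight_range = c(0.5, 1.5),
                            endpoints = "both",
                            seed = 1L, keep_timeseries = FALSE) {
  check_network(atlas, target_network)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, 4)

  ts <- simulate_timeseries(n_subjects, atlas, n_timepoints,
                            rho_within, rho_between, subject_sd,
                            seed = sub_seeds[1])
  map <- edge_index_map(nrow(atlas))
  X <- edge_matrix(ts, map)

  edges <- sample_signal_edges(map, atlas, target_network, n_signal_edges,
                               endpoints = endpoints, seed = sub_seeds[2])
  set.seed(sub_seeds[4])
  weights <- runif(n_signal_edges, weight_range[1], weight_range[2])
  signal <- as.vector(X[, edges, drop = FALSE] %*% weights)
  noise_sd <- if (is.infinite(snr)) 0 else sd(signal) / snr

  truth <- ground_truth(edges, weights, noise_sd, target_network,
                        seed = sub_seeds[3])
  y <- embed_behavior(X, truth)

  out <- list(atlas = atlas, map = map, X = X, y = y, truth = truth,
              seed = as.integer(seed))
  if (keep_timeseries) out$timeseries <- ts
  class(out) <- "wm_cohort"
  out
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort: %d subjects, %d nodes, %d edges\n",
    "  signal: %d edges in '%s', noise sd %.3f\n"),
    nrow(x$X), x$map$n_nodes, x$map$n_edges,
    length(x$truth$signal_edges), x$truth$target_network,
    x$truth$noise_sd))
  invisible(x)
}

#' Read / write per-subject node time series
#'
#' One tab-separated file per subject (rows = nodes, columns =
#' timepoints, no header), named `<subject_id>.txt`.
#'
#' @param ts_list named list of node x timepoint matrices.
#' @param dir directory (created if needed).
#' @return `write_timeseries()` returns `dir`; `read_timeseries()`
#'   returns a named list of matrices.
#' @export
write_timeseries <- function(ts_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(ts_list)) {
    write.table(ts_list[[id]], file.path(dir, paste0(id, ".txt")),
                sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- lapply(files, function(f) as.matrix(read.delim(f, header = FALSE)))
  names(out) <- sub("\\.txt$", "", basename(files))
  lapply(out, function(m) {
    dimnames(m) <- NULL
    m
  })
}
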