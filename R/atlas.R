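#' Build a node-to-network atlas partition
#'
#' Assigns `n_nodes` parcellation nodes to named networks with fixed sizes.
#' By default nodes are assigned in contiguous blocks (nodes `1..s1` to the
#' first network, and so on); with `shuffle = TRUE` the node-to-network
#' assignment is permuted reproducibly using `seed`.
#'
#' @param n_nodes total number of nodes.
#' @param network_sizes integer vector of nodes per network; must sum to
#'   `n_nodes`.
#' @param network_names labels, one per network; defaults to
#'   `"net01"`, `"net02"`, ...
#' @param seed integer seed used only when `shuffle = TRUE`.
#' @param shuffle permute the node-to-network assignment?
#' @return A data frame of class `wm_atlas` with columns `node` (integer)
#'   and `network` (factor with one level per network, in the given order).
#' @examples
#' atlas <- make_atlas(20, c(5, 15), c("A", "B"))
#' table(atlas$network)
#' @export
make_atlas <- function(n_nodes, network_sizes, network_names = NULL,
                       seed = NULL, shuffle = FALSE) {
  n_nodes <- as.integer(n_nodes)
  network_sizes <- as.integer(network_sizes)
  if (is.null(network_names)) {
    network_names <- sprintf("net%02d", seq_along(network_sizes))
  }
  if (length(network_sizes) != length(network_names)) {
    stop("`network_sizes` and `network_names` must have the same length",
         call. = FALSE)
  }
  if (sum(network_sizes) != n_nodes) {
    stop(sprintf("network sizes sum to %d but n_nodes is %d",
                 sum(network_sizes), n_nodes), call. = FALSE)
  }
  if (anyDuplicated(network_names)) {
    stop("network names must be unique", call. = FALSE)
  }
  assignment <- rep(network_names, times = network_sizes)
  if (isTRUE(shuffle)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    assignment <- sample(assignment)
  }
  atlas <- data.frame(
    node = seq_len(n_nodes),
    network = factor(assignment, levels = network_names)
  )
  class(atlas) <- c("wm_atlas", "data.frame")
  atlas
}

#' Default 268-node, 10-network atlas partition
#'
#' A synthetic stand-in for a whole-brain 268-node parcellation grouped
#' into 10 canonical resting-state networks. Network sizes are fixed and
#' sum to 268; the cerebellum network holds 20 nodes and is the default
#' target network for simulated signal.
#'
#' @return A `wm_atlas` data frame (see [make_atlas()]).
#' @examples
#' atlas <- default_atlas()
#' nlevels(atlas$network)
#' @export
default_atlas <- function() {
  sizes <- c(
    medial_frontal = 28L, frontoparietal = 28L, default_mode = 28L,
    subcortical = 24L, motor = 28L, visual_a = 28L, visual_b = 28L,
    visual_association = 28L, salience = 28L, cerebellum = 20L
  )
  make_atlas(268L, sizes, names(sizes))
}

#' @export
print.wm_atlas <- function(x, ...) {
  cat(sprintf("Atlas partition: %d nodes, %d networks\n",
              nrow(x), nlevels(x$network)))
  print(table(x$network))
  invisible(x)
}

check_network <- function(atlas, network) {
  if (!network %in% levels(atlas$network)) {
    stop(sprintf("unknown network '%s' (atlas has: %s)", network,
                 paste(levels(atlas$network), collapse = ", ")),
         call. = FALSE)
  }
  invisible(network)
}

#' Read / write an atlas partition table
#'
#' The on-disk format is two-column tab-separated text with a header:
#' `node` (integer id) and `network` (label). Network level order follows
#' first appearance in the file.
#'
#' @param path file path.
#' @return `read_atlas()` returns a `wm_atlas` data frame.
#' @export
read_atlas <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "network") %in% names(df))) {
    stop("atlas file must have columns 'node' and 'network'", call. = FALSE)
  }
  df <- df[order(df$node), , drop = FALSE]
  atlas <- data.frame(
    node = as.integer(df$node),
    network = factor(df$network, levels = unique(df$network))
  )
  class(atlas) <- c("wm_atlas", "data.frame")
  atlas
}

#' @param atlas a `wm_atlas` data frame.
#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path) {
  write.table(data.frame(node = atlas$node,
                         network = as.character(atlas$network)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
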