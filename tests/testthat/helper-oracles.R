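# Independent reference implementations used as oracles.
# The SVR reference goes through e1071 (libsvm); everything else is
# deliberately naive brute force.

ref_svr <- function(X, y, cost = 1, epsilon = 0.1) {
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                  cost = cost, epsilon = epsilon, scale = FALSE)
  list(w = drop(crossprod(m$SV, m$coefs)), b = -m$rho, model = m)
}

# plain-R LOOCV with within-fold ranking and refit, via e1071
ref_loocv <- function(X, y, per_mille, cost = 1, epsilon = 0.1) {
  n <- nrow(X)
  k <- max(1L, floor(ncol(X) * per_mille / 1000))
  pred <- numeric(n)
  sel <- matrix(0L, k, n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    w <- ref_svr(Xtr, ytr, cost, epsilon)$w
    ord <- order(-abs(w), seq_along(w))
    s <- ord[seq_len(k)]
    sel[, i] <- s
    fit <- e1071::svm(Xtr[, s, drop = FALSE], ytr, type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    pred[i] <- predict(fit, X[i, s, drop = FALSE])
  }
  list(pred = pred, sel = sel, r = cor(pred, y))
}

# brute-force network edge matrix over consensus edges
bf_network_edge_matrix <- function(consensus, map, atlas) {
  nets <- levels(atlas$network)
  E <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  for (r in seq_len(nrow(consensus))) {
    e <- consensus$edge[r]
    i <- map$i[e]
    j <- map$j[e]
    a <- as.character(atlas$network[atlas$node == i])
    b <- as.character(atlas$network[atlas$node == j])
    E[a, b] <- E[a, b] + abs(consensus$weight[r])
    if (a != b) E[b, a] <- E[b, a] + abs(consensus$weight[r])
  }
  E
}

# brute-force node incidence degrees
bf_node_degree <- function(consensus, map, atlas, network) {
  nodes <- atlas$node[as.character(atlas$network) == network]
  vapply(nodes, function(nd) {
    sum(vapply(consensus$edge, function(e) {
      map$i[e] == nd || map$j[e] == nd
    }, logical(1)))
  }, numeric(1))
}

# small cohort used by several prediction tests
tiny_cohort <- function(n_subjects = 24, seed = 5, snr = 2,
                        n_signal_edges = 6, n_timepoints = 150) {
  atlas <- make_atlas(18, c(6, 6, 6), c("A", "B", "target"))
  simulate_cohort(n_subjects = n_subjects, atlas = atlas,
                  n_timepoints = n_timepoints, target_network = "target",
                  n_signal_edges = n_signal_edges, snr = snr, seed = seed)
}
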