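make_folds <- function(sel, w) {
  list(selected = sel, fold_weights = w)
}

test_that("consensus keeps exactly the features selected in every fold", {
  sel <- cbind(c(1L, 4L, 9L), c(4L, 9L, 2L), c(9L, 1L, 4L))
  w <- cbind(c(0.5, -0.2, 0.1), c(0.3, -0.4, 0.2), c(0.2, 0.1, -0.3))
  cons <- consensus_features(make_folds(sel, w))
  expect_equal(cons$edge, c(4L, 9L))  # 1 misses fold 2, 2 only in fold 2
  # per-edge sum of |weight| across folds
  expect_equal(cons$weight[cons$edge == 4], 0.2 + 0.3 + 0.3)
  expect_equal(cons$weight[cons$edge == 9], 0.1 + 0.4 + 0.2)

  disjoint <- cbind(1:3, 4:6)
  expect_warning(
    empty <- consensus_features(make_folds(disjoint, disjoint * 0.1)),
    "empty")
  expect_equal(nrow(empty), 0)
})

test_that("network edge matrix matches brute-force enumeration", {
  atlas <- make_atlas(9, c(3, 3, 3), c("A", "B", "C"))
  map <- edge_index_map(9)

  # single between-network edge with negative weight
  e_ab <- edge_index(1, 4, map)
  cons1 <- data.frame(edge = e_ab, weight = -0.4)
  E1 <- network_edge_matrix(cons1, map, atlas)
  expect_equal(E1["A", "B"], 0.4)
  expect_equal(E1["B", "A"], 0.4)
  expect_equal(sum(E1), 0.8)

  # empty consensus
  E0 <- network_edge_matrix(data.frame(edge = integer(), weight = numeric()),
                            map, atlas)
  expect_true(all(E0 == 0))

  # hand-placed edges, including a within-network one
  cons3 <- data.frame(edge = c(edge_index(1, 2, map),   # A-A
                               edge_index(2, 5, map),   # A-B
                               edge_index(6, 9, map)),  # B-C
                      weight = c(0.5, -1.0, 2.0))
  E3 <- network_edge_matrix(cons3, map, atlas)
  expect_equal(E3, bf_network_edge_matrix(cons3, map, atlas))
  expect_equal(E3["A", "A"], 0.5)
  expect_equal(E3["A", "B"], 1.0)
  expect_equal(E3["B", "C"], 2.0)

  # conservation: upper triangle incl. diagonal carries each edge once
  expect_equal(sum(E3[upper.tri(E3, diag = TRUE)]), sum(abs(cons3$weight)))
})

test_that("relative degree follows the binarized-share formula", {
  nets <- c("A", "B", "C")
  E <- matrix(0, 3, 3, dimnames = list(nets, nets))
  E["A", "B"] <- E["B", "A"] <- 0.7
  rd <- relative_degree(E)
  expect_equal(as.numeric(rd), c(0.5, 0.5, 0))

  Efull <- matrix(1, 3, 3, dimnames = list(nets, nets))
  expect_equal(as.numeric(relative_degree(Efull)), rep(1 / 3, 3))

  set.seed(4)
  R <- matrix(runif(9), 3)
  R <- R + t(R)
  R[sample(9, 2)] <- 0
  R <- (R + t(R)) / 2
  dimnames(R) <- list(nets, nets)
  expect_equal(sum(relative_degree(R)), 1)

  expect_warning(rd0 <- relative_degree(E * 0), "all-zero")
  expect_true(all(rd0 == 0))
  expect_true(attr(rd0, "all_zero"))
})

test_that("node degree counts incident consensus edges and ranks them", {
  atlas <- make_atlas(10, c(6, 4), c("A", "B"))
  map <- edge_index_map(10)
  cons <- data.frame(
    edge = c(edge_index(1, 2, map), edge_index(1, 3, map),
             edge_index(1, 7, map), edge_index(2, 5, map),
             edge_index(8, 9, map)),
    weight = rep(1, 5))

  dA <- node_degree(cons, map, atlas, "A")
  expect_equal(dA$node[1], 1)
  expect_equal(dA$degree[1], 3)
  expect_equal(dA$degree, sort(dA$degree, decreasing = TRUE))
  expect_equal(dA$rank, 1:6)
  expect_equal(setNames(dA$degree, dA$node)[as.character(1:6)],
               bf_node_degree(cons, map, atlas, "A")[1:6],
               ignore_attr = TRUE)

  # column total equals endpoints-in-network over consensus edges
  ep <- edge_endpoints(cons$edge, map)
  in_a <- as.character(atlas$network) == "A"
  expect_equal(sum(dA$degree), sum(in_a[ep[, "i"]]) + sum(in_a[ep[, "j"]]))

  empty_net <- node_degree(data.frame(edge = integer(), weight = numeric()),
                           map, atlas, "B")
  expect_true(all(empty_net$degree == 0))
  expect_error(node_degree(cons, map, atlas, "Z"), "unknown network")
})
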