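test_that("correlation_matrix matches a hand-computed Pearson r", {
  ts <- rbind(c(1, 2, 3, 4),
              c(2, 1, 4, 3),
              c(5, 3, 2, 1))
  r <- correlation_matrix(ts)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r, t(r))
  hand <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(r[1, 2], hand(ts[1, ], ts[2, ]))
  expect_equal(r[1, 3], hand(ts[1, ], ts[3, ]))
  expect_equal(r[2, 3], hand(ts[2, ], ts[3, ]))
})

test_that("correlation of duplicate and negated series hits +/-1", {
  base <- c(0.3, -1.2, 0.8, 2.0, -0.5)
  ts <- rbind(base, base, -base)
  r <- correlation_matrix(ts)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
})

test_that("zero-variance nodes are reported by name", {
  ts <- rbind(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_error(correlation_matrix(ts), "'b' has zero variance")
})

test_that("fisher_z is the odd, increasing arctanh with clipping at 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
})

test_that("edge counts follow n(n-1)/2, including the 268-node atlas", {
  expect_equal(edge_index_map(268)$n_edges, 35778L)
  expect_equal(edge_index_map(3)$n_edges, 3L)
  m <- matrix(rnorm(268^2), 268)
  m <- m + t(m)
  expect_length(vectorize_upper(m), 35778L)
})

test_that("edge enumeration is row-major upper-triangle and invertible", {
  map <- edge_index_map(268)
  expect_equal(edge_endpoints(1, map), cbind(i = 1L, j = 2L))
  expect_equal(edge_endpoints(map$n_edges, map), cbind(i = 267L, j = 268L))

  map10 <- edge_index_map(10)
  # exhaustive pair -> index -> pair round trip
  for (e in seq_len(map10$n_edges)) {
    ep <- edge_endpoints(e, map10)
    expect_lt(ep[, "i"], ep[, "j"])
    expect_equal(edge_index(ep[, "i"], ep[, "j"], map10), e)
    expect_equal(edge_index(ep[, "j"], ep[, "i"], map10), e)
  }
  # row-major: (1,2),(1,3),...,(1,10),(2,3),...
  expect_equal(map10$i[1:10], c(rep(1L, 9), 2L))
  expect_equal(map10$j[1:10], c(2:10, 3L))
  expect_error(edge_endpoints(0, map10), "out of range")
  expect_error(edge_endpoints(46, map10), "out of range")
})

test_that("vectorize / devectorize is a bijection on off-diagonals", {
  for (n in c(3, 5, 12)) {
    map <- edge_index_map(n)
    m <- matrix(rnorm(n * n), n)
    m <- m + t(m)
    diag(m) <- 0
    v <- vectorize_upper(m, map)
    expect_length(v, map$n_edges)
    expect_equal(devectorize_upper(v, map), m)
  }
  expect_error(vectorize_upper(matrix(0, 4, 4), edge_index_map(5)),
               "map is for 5 nodes")
})

test_that("edges are invariant to affine transforms of node series", {
  atlas <- make_atlas(8, c(4, 4))
  ts <- simulate_timeseries(1, atlas, 60, seed = 2)[[1]]
  v1 <- vectorize_upper(connectome_matrix(ts))
  ts2 <- ts
  ts2[3, ] <- 5 + 2 * ts2[3, ]
  expect_equal(vectorize_upper(connectome_matrix(ts2)), v1)
})

test_that("edge vectors survive a write/read round trip", {
  cohort <- tiny_cohort(n_subjects = 8, seed = 31)
  dir <- withr::local_tempdir()
  write_edge_vectors(cohort$X, dir, cohort$map)
  back <- read_edge_vectors(dir)
  expect_equal(back$X, cohort$X, tolerance = 1e-12)
  expect_equal(back$map$n_edges, cohort$map$n_edges)
})
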