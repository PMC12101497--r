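test_that("make_atlas partitions nodes with exact per-network counts", {
  sizes <- c(28, 28, 28, 24, 28, 28, 28, 28, 28, 20)
  atlas <- make_atlas(268, sizes)
  expect_equal(nrow(atlas), 268)
  expect_equal(nlevels(atlas$network), 10)
  expect_false(anyNA(atlas$network))
  expect_equal(as.integer(table(atlas$network)), as.integer(sizes))

  one <- make_atlas(20, 20, "all")
  expect_true(all(one$network == "all"))

  two <- make_atlas(20, c(5, 15), c("A", "B"))
  expect_equal(as.integer(table(two$network)), c(5L, 15L))

  expect_error(make_atlas(20, c(5, 16)), "sum")
  expect_error(make_atlas(20, c(5, 15), c("A", "B", "C")), "length")
})

test_that("shuffled atlas assignment is deterministic given the seed", {
  a1 <- make_atlas(30, c(10, 20), seed = 42, shuffle = TRUE)
  a2 <- make_atlas(30, c(10, 20), seed = 42, shuffle = TRUE)
  a3 <- make_atlas(30, c(10, 20), seed = 43, shuffle = TRUE)
  expect_identical(a1, a2)
  expect_false(identical(a1$network, a3$network))
})

test_that("simulated time series carry the requested block correlation", {
  atlas <- make_atlas(20, c(10, 10), c("A", "B"))
  ts <- simulate_timeseries(20, atlas, 500, rho_within = 0.5,
                            rho_between = 0.1, seed = 7)
  expect_length(ts, 20)
  same <- outer(atlas$network, atlas$network, "==")
  off <- !diag(TRUE, 20)
  within_r <- between_r <- numeric(20)
  for (s in seq_along(ts)) {
    r <- correlation_matrix(ts[[s]])
    within_r[s] <- mean(r[same & off])
    between_r[s] <- mean(r[!same])
  }
  expect_gt(mean(within_r), mean(between_r))
  expect_gt(mean(within_r), 0.35)
  expect_lt(mean(between_r), 0.25)
})

test_that("uncorrelated request yields near-zero empirical correlation", {
  atlas <- make_atlas(20, c(10, 10), c("A", "B"))
  ts <- simulate_timeseries(10, atlas, 400, rho_within = 0,
                            rho_between = 0, seed = 3)
  off <- !diag(TRUE, 20)
  vals <- unlist(lapply(ts, function(m) correlation_matrix(m)[off]))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 0.01)
})

test_that("time-series shapes and seeding contracts hold", {
  atlas <- make_atlas(12, c(6, 6))
  ts <- simulate_timeseries(3, atlas, 50, seed = 1)
  expect_length(ts, 3)
  for (m in ts) expect_equal(dim(m), c(12L, 50L))

  again <- simulate_timeseries(3, atlas, 50, seed = 1)
  expect_identical(ts, again)

  expect_error(simulate_timeseries(2, atlas, 50, rho_within = 0.1,
                                   rho_between = 0.5),
               "rho_between")
})

test_that("embed_behavior reproduces exact linear combinations", {
  set.seed(2)
  X <- matrix(rnorm(30 * 10), 30, 10)

  t1 <- ground_truth(4, 1, noise_sd = 0)
  expect_equal(embed_behavior(X, t1), X[, 4], ignore_attr = TRUE)

  t2 <- ground_truth(c(2, 7), c(2, -1), noise_sd = 0)
  expect_equal(embed_behavior(X, t2), 2 * X[, 2] - X[, 7],
               ignore_attr = TRUE)

  expect_error(embed_behavior(X, ground_truth(11, 1, 0)), "out of range")
  expect_error(ground_truth(c(3, 3), c(1, 1), 0), "unique")
  expect_error(ground_truth(1, 1, -0.5), "noise_sd")
})

test_that("behavior at SNR 2 correlates >= 0.8 with the noiseless signal", {
  cohort <- tiny_cohort(n_subjects = 60, seed = 9, snr = 2)
  signal <- as.vector(
    cohort$X[, cohort$truth$signal_edges] %*% cohort$truth$weights)
  expect_gte(cor(cohort$y, signal), 0.8)
})

test_that("cohort signal edges stay inside the target network", {
  cohort <- tiny_cohort(seed = 4)
  ep <- edge_endpoints(cohort$truth$signal_edges, cohort$map)
  nets_i <- cohort$atlas$network[ep[, "i"]]
  nets_j <- cohort$atlas$network[ep[, "j"]]
  expect_true(all(nets_i == "target" & nets_j == "target"))
})

test_that("change-detection generator matches its analytic expectations", {
  # no memory: expected hit rate equals expected false-alarm rate
  tc0 <- simulate_change_detection_trials(0, 4, 0.3, 10000, 10000, seed = 1)
  expect_lt(abs(cowan_k_trials(tc0)), 0.1)

  # capacity at the set size: d = 1, so the estimate is exactly S
  tc4 <- simulate_change_detection_trials(4, 4, 0.5, 500, 500, seed = 2)
  expect_equal(cowan_k_trials(tc4), 4)

  # capacity above the set size is ceilinged at S
  tc6 <- simulate_change_detection_trials(6, 4, 0.2, 500, 500, seed = 3)
  expect_equal(cowan_k_trials(tc6), 4)

  expect_error(simulate_change_detection_trials(2, 4, 1.3, 10, 10),
               "guess_rate")
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  c1 <- tiny_cohort(n_subjects = 8, seed = 21)
  c2 <- tiny_cohort(n_subjects = 8, seed = 21)
  expect_identical(c1$X, c2$X)
  expect_identical(c1$y, c2$y)
  expect_identical(c1$truth, c2$truth)
})

test_that("AR(1) option adds temporal autocorrelation, preserving blocks", {
  atlas <- make_atlas(10, c(5, 5))
  ts <- simulate_timeseries(4, atlas, 800, rho_within = 0.5,
                            rho_between = 0.1, ar1 = 0.4, seed = 6)
  lag1 <- mean(vapply(ts, function(m) {
    mean(apply(m, 1, function(x) cor(x[-1], x[-length(x)])))
  }, numeric(1)))
  expect_equal(lag1, 0.4, tolerance = 0.1)
  # cross-node correlation structure unchanged by the temporal filter
  same <- outer(atlas$network, atlas$network, "==") & !diag(TRUE, 10)
  within_r <- mean(vapply(ts, function(m) {
    mean(correlation_matrix(m)[same])
  }, numeric(1)))
  expect_equal(within_r, 0.5, tolerance = 0.1)
})
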