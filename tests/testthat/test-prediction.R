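test_that("feature_count uses floor with a minimum of one", {
  expect_identical(feature_count(35778, 1), 35L)
  expect_identical(feature_count(35778, 9), 322L)
  expect_identical(feature_count(1000, 5), 5L)
  expect_identical(feature_count(100, 1), 1L)  # floor would give 0
  expect_identical(feature_count(35778, c(1, 3, 5, 7, 9)),
                   c(35L, 107L, 178L, 250L, 322L))
  expect_error(feature_count(100, 0), "> 0")
})

test_that("SVR weights and fit agree with the libsvm reference", {
  skip_if_not_installed("e1071")
  set.seed(10)
  for (rep in 1:3) {
    n <- 25 + 5 * rep
    p <- 60
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.3)
    mine <- rank_features_by_svr(X, y)
    ref <- ref_svr(X, y)
    # both solvers stop at KKT violation 1e-3; agreement is to ~1e-4
    expect_equal(mine$weights, ref$w, tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("a feature collinear with y is ranked first", {
  set.seed(11)
  X <- matrix(rnorm(50 * 40), 50, 40)
  y <- X[, 17]
  rk <- rank_features_by_svr(X, y)
  expect_equal(rk$order[1], 17)
  expect_false(rk$degenerate)
})

test_that("constant targets and duplicated columns degrade gracefully", {
  set.seed(12)
  X <- matrix(rnorm(20 * 15), 20, 15)
  expect_warning(rk <- rank_features_by_svr(X, rep(1, 20)), "zero")
  expect_true(rk$degenerate)
  expect_equal(rk$order, 1:15)

  X[, 9] <- X[, 5]
  y <- X[, 5] + rnorm(20, 0, 0.1)
  rk2 <- rank_features_by_svr(X, y)
  expect_equal(rk2$weights[5], rk2$weights[9], tolerance = 1e-8)
  expect_lt(which(rk2$order == 5), which(rk2$order == 9))
})

test_that("LOOCV predictions match an independent e1071 implementation", {
  skip_if_not_installed("e1071")
  cohort <- tiny_cohort(n_subjects = 14, seed = 13)
  X <- cohort$X
  y <- cohort$y
  per_mille <- 40  # 6 of 153 features
  mine <- loocv_predict(X, y, per_mille)
  ref <- ref_loocv(X, y, per_mille)
  expect_equal(mine$n_features, 6L)
  for (i in seq_len(nrow(X))) {
    expect_setequal(mine$selected[, i], ref$sel[, i])
  }
  expect_equal(mine$predictions, ref$pred, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(mine$r_observed, ref$r, tolerance = 1e-3)
})

test_that("standardized LOOCV matches a per-fold scaled reference", {
  skip_if_not_installed("e1071")
  cohort <- tiny_cohort(n_subjects = 12, seed = 17)
  X <- cohort$X[, 1:40]
  y <- cohort$y
  cfg <- prediction_config(standardize = TRUE)
  mine <- loocv_predict(X, y, 100, cfg)  # 4 features
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    mu <- colMeans(X[-i, ])
    sds <- apply(X[-i, ], 2, sd)
    sds[sds == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
    w <- ref_svr(Xs[-i, ], y[-i])$w
    s <- order(-abs(w), seq_along(w))[1:4]
    fit <- e1071::svm(Xs[-i, s], y[-i], type = "eps-regression",
                      kernel = "linear", cost = 1, epsilon = 0.1,
                      scale = FALSE)
    pred[i] <- predict(fit, Xs[i, s, drop = FALSE])
  }
  expect_equal(mine$predictions, pred, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("held-out subjects cannot leak into selection or prediction", {
  cohort <- tiny_cohort(n_subjects = 12, seed = 14)
  X <- cohort$X
  y <- cohort$y
  base <- loocv_predict(X, y, 30)
  for (i in c(1, 5, 12)) {
    y2 <- y
    y2[i] <- y2[i] + 10
    alt <- loocv_predict(X, y2, 30)
    expect_identical(alt$selected[, i], base$selected[, i])
    expect_equal(alt$predictions[i], base$predictions[i])
  }
})

test_that("prediction results are bit-reproducible for a fixed config", {
  cohort <- tiny_cohort(n_subjects = 12, seed = 15)
  cfg <- prediction_config(per_mille = c(10, 30), n_permutations = 25,
                           seed = 99)
  r1 <- cpm_predict(cohort$X, cohort$y, cfg)
  r2 <- cpm_predict(cohort$X, cohort$y, cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$r_permuted, r2$r_permuted)
})

test_that("permutation p behaves at the boundaries", {
  cohort <- tiny_cohort(n_subjects = 20, seed = 16, snr = Inf)
  cfg1 <- prediction_config(n_permutations = 1, seed = 1)
  p1 <- permutation_test(cohort$X, cohort$y, 30, cfg1)
  expect_true(p1$p %in% c(0, 1))

  cfg <- prediction_config(n_permutations = 60, seed = 2)
  pt <- permutation_test(cohort$X, cohort$y, 30, cfg)
  expect_equal(pt$p, mean(pt$r_permuted > pt$r_observed))
  expect_equal(pt$p_corrected,
               (sum(pt$r_permuted > pt$r_observed) + 1) / 61)
  # strong noiseless signal beats every shuffle
  expect_equal(pt$p, 0)
})

test_that("fdr_correct applies Benjamini-Hochberg step-up", {
  res <- fdr_correct(c(0.01, 0.02, 0.20), alpha = 0.05)
  expect_equal(res$significant, c(TRUE, TRUE, FALSE))
  expect_equal(res$q, p.adjust(c(0.01, 0.02, 0.20), "BH"))

  expect_true(all(fdr_correct(rep(0.001, 15))$significant))
  expect_true(fdr_correct(0.049)$significant)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  # flags monotone in p
  p <- runif(20)
  fl <- fdr_correct(p)$significant
  expect_true(all(fl[order(p)] == cummin(fl[order(p)])))
})

test_that("selection never beats an oracle given the true edges", {
  cohort <- tiny_cohort(n_subjects = 20, seed = 18, snr = Inf)
  pred <- cpm_predict(cohort$X, cohort$y,
                      prediction_config(n_permutations = 1, seed = 1))
  oracle <- loocv_predict(cohort$X[, cohort$truth$signal_edges],
                          cohort$y, 1000)  # keeps all true edges
  expect_true(all(pred$summary$r <= oracle$r_observed + 1e-6))
})

test_that("minimal four-subject run emits one prediction per fold", {
  set.seed(19)
  X <- matrix(rnorm(4 * 10), 4, 10)
  y <- rnorm(4)
  res <- loocv_predict(X, y, 100)
  expect_length(res$predictions, 4)
  expect_error(loocv_predict(X[1:3, ], y[1:3], 100), ">= 4")
})
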