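#' Prediction configuration
#'
#' Bundles the tunable parameters of the LOOCV-SVR prediction procedure.
#' The SVR is always epsilon-SVR with a linear kernel (interpretable
#' weights are required for feature ranking); `cost` and `epsilon`
#' default to the libsvm defaults. Feature standardization is off by
#' default — Fisher-z edges already share a common scale — and when on
#' uses training-fold statistics only.
#'
#' @param per_mille feature-selection thresholds in per-mille of the
#'   total edge count (default 1, 3, 5, 7, 9).
#' @param n_permutations permutations for the significance test.
#' @param cost,epsilon,tol epsilon-SVR hyperparameters and SMO stopping
#'   tolerance.
#' @param standardize z-score features within each training fold?
#' @param seed integer seed governing the permutation draws.
#' @return A list of class `wm_config`.
#' @export
prediction_config <- function(per_mille = c(1, 3, 5, 7, 9),
                              n_permutations = 1000,
                              cost = 1, epsilon = 0.1, tol = 1e-3,
                              standardize = FALSE, seed = 1L) {
  per_mille <- sort(unique(as.numeric(per_mille)))
  if (any(per_mille <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  structure(
    list(per_mille = per_mille, n_permutations = as.integer(n_permutations),
         cost = cost, epsilon = epsilon, tol = tol,
         standardize = isTRUE(standardize), seed = as.integer(seed)),
    class = "wm_config"
  )
}

#' Number of features kept at a per-mille threshold
#'
#' `floor(n_features * per_mille / 1000)`, with a minimum of one feature.
#' For the 35,778-edge connectome this gives 35 features at 1 per mille
#' and 322 at 9 per mille.
#'
#' @param n_features total feature count (>= 1).
#' @param per_mille threshold(s) in per mille (> 0; vectorized).
#' @return Integer feature count(s).
#' @examples
#' feature_count(35778, c(1, 9))  # 35, 322
#' @export
feature_count <- function(n_features, per_mille) {
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  if (any(per_mille <= 0)) stop("per_mille must be > 0", call. = FALSE)
  pmax(1L, as.integer(floor(n_features * per_mille / 1000)))
}

#' Rank features by absolute linear-SVR weight
#'
#' Fits a linear epsilon-SVR on all features and orders them by
#' decreasing absolute weight, ties broken by lower feature index. A
#' constant target yields all-zero weights; the ordering then falls back
#' to index order and the result is flagged degenerate.
#'
#' @param X subjects x features matrix (>= 3 rows).
#' @param y numeric target, one value per subject.
#' @param config a [prediction_config()].
#' @return A list with `order` (feature indices, best first), `weights`
#'   (raw signed weights in original feature order), and `degenerate`.
#' @export
rank_features_by_svr <- function(X, y, config = prediction_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 training subjects", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("features and target must be finite", call. = FALSE)
  }
  if (config$standardize) {
    mu <- colMeans(X)
    sds <- apply(X, 2, sd)
    sds[sds == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sds, "/")
  }
  fit <- cpp_svr_fit(tcrossprod(X), y, config$cost, config$epsilon,
                     config$tol)
  w <- drop(crossprod(X, fit$beta))
  degenerate <- all(w == 0)
  if (degenerate) {
    warning("all SVR weights are zero (constant target?); ",
            "falling back to index order")
  }
  list(order = order(-abs(w), seq_along(w)), weights = w,
       degenerate = degenerate)
}

# permutation columns for y: n x n_permutations matrix drawn from the
# config seed (one stream, fixed draw order -> deterministic)
permute_scores <- function(y, n_permutations, seed) {
  set.seed(as.integer(seed))
  vapply(seq_len(n_permutations), function(i) sample(y), numeric(length(y)))
}

# shared driver around the compiled LOOCV sweep
run_engine <- function(X, y, per_mille, config, n_permutations = 0,
                       details = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out prediction needs >= 4 subjects",
                  call. = FALSE)
  if (length(y) != n) stop("length(y) must match nrow(X)", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("features and target must be finite", call. = FALSE)
  }
  kc <- feature_count(ncol(X), per_mille)
  if (any(diff(kc) < 0)) stop("thresholds must be ascending", call. = FALSE)
  Y <- cbind(y, if (n_permutations > 0) {
    permute_scores(y, n_permutations, config$seed)
  })
  res <- cpp_loocv_engine(X, Y, kc, config$cost, config$epsilon, config$tol,
                          config$standardize, details)
  res$kcounts <- kc
  res
}

#' Leave-one-out cross-validated SVR prediction at one threshold
#'
#' For each fold, features are ranked by absolute SVR weight on the
#' training subjects only, the top `feature_count(ncol(X), per_mille)`
#' are retained, a fresh SVR is fitted on the selected columns and the
#' held-out subject is predicted. Prediction accuracy is the Pearson
#' correlation between predicted and actual scores across all subjects.
#'
#' @param X subjects x edges feature matrix (>= 4 subjects).
#' @param y behavioral scores.
#' @param per_mille a single feature-selection threshold.
#' @param config a [prediction_config()].
#' @return A list of class `wm_fold_result`: `per_mille`, `n_features`,
#'   `r_observed`, `predictions`, `selected` (features x folds index
#'   matrix), `fold_weights` (refit weights per selected feature), and
#'   `degenerate_folds`.
#' @export
loocv_predict <- function(X, y, per_mille, config = prediction_config()) {
  stopifnot(length(per_mille) == 1)
  res <- run_engine(X, y, per_mille, config, n_permutations = 0,
                    details = TRUE)
  pred <- drop(res$pred)
  structure(
    list(per_mille = per_mille, n_features = res$kcounts[1],
         r_observed = res$r[1, 1], predictions = pred,
         actual = y,
         selected = res$selected[[1]],
         fold_weights = res$fold_weights[[1]],
         degenerate_folds = which(!is.finite(pred))),
    class = "wm_fold_result"
  )
}

#' Permutation test of LOOCV prediction accuracy
#'
#' Reshuffles the scores `n_permutations` times (seeded from the config)
#' and reruns the complete LOOCV procedure — including within-fold
#' feature re-selection — on each shuffle. The primary p-value is the
#' proportion of permuted correlations strictly exceeding the observed
#' one (and can be exactly 0); the bias-corrected `(k + 1) / (n + 1)`
#' variant is reported alongside.
#'
#' @inheritParams loocv_predict
#' @return A list with `r_observed`, `r_permuted`, `p` (proportion
#'   exceeding), and `p_corrected`.
#' @export
permutation_test <- function(X, y, per_mille, config = prediction_config()) {
  stopifnot(length(per_mille) == 1)
  res <- run_engine(X, y, per_mille, config,
                    n_permutations = config$n_permutations)
  r_obs <- res$r[1, 1]
  r_perm <- res$r[-1, 1]
  exceed <- sum(r_perm > r_obs, na.rm = TRUE)
  list(r_observed = r_obs, r_permuted = r_perm,
       p = exceed / config$n_permutations,
       p_corrected = (exceed + 1) / (config$n_permutations + 1))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A list with `q` (BH-adjusted p-values) and `significant`
#'   (logical flags, monotone in `p`).
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.20))
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Connectome-based prediction across all thresholds, with permutations
#'
#' Runs the full procedure once per feature-selection threshold: LOOCV
#' SVR prediction with within-fold feature selection, a permutation null
#' for the predicted-vs-actual correlation (the identical shuffles are
#' applied at every threshold), and BH correction across the thresholds
#' of this run. Per-fold selections and refit weights are retained so
#' consensus features and network importance can be derived.
#'
#' @inheritParams loocv_predict
#' @param config a [prediction_config()].
#' @param alpha FDR level for the threshold family.
#' @return An object of class `wm_prediction`: `summary` data frame
#'   (`per_mille`, `n_features`, `r`, `p`, `p_corrected`, `q`,
#'   `significant`), `folds` (per-threshold [loocv_predict()]-style
#'   detail), `r_permuted` matrix, `config`.
#' @export
cpm_predict <- function(X, y, config = prediction_config(), alpha = 0.05) {
  res <- run_engine(X, y, config$per_mille, config,
                    n_permutations = config$n_permutations, details = TRUE)
  nT <- length(config$per_mille)
  r_obs <- res$r[1, ]
  r_perm <- res$r[-1, , drop = FALSE]
  exceed <- colSums(sweep(r_perm, 2, r_obs, ">"), na.rm = TRUE)
  p <- exceed / config$n_permutations
  fdr <- fdr_correct(p, alpha)

  folds <- lapply(seq_len(nT), function(t) {
    pred <- res$pred[, t]
    structure(
      list(per_mille = config$per_mille[t], n_features = res$kcounts[t],
           r_observed = r_obs[t], predictions = pred, actual = y,
           selected = res$selected[[t]], fold_weights = res$fold_weights[[t]],
           degenerate_folds = which(!is.finite(pred))),
      class = "wm_fold_result"
    )
  })
  structure(
    list(summary = data.frame(
           per_mille = config$per_mille, n_features = res$kcounts,
           r = r_obs, p = p,
           p_corrected = (exceed + 1) / (config$n_permutations + 1),
           q = fdr$q, significant = fdr$significant),
         folds = folds, r_permuted = r_perm, config = config),
    class = "wm_prediction"
  )
}

#' @export
print.wm_prediction <- function(x, ...) {
  cat(sprintf(
    "LOOCV SVR prediction (%d subjects, %d permutations)\n",
    length(x$folds[[1]]$predictions), x$config$n_permutations))
  df <- x$summary
  df$r <- round(df$r, 3)
  df$q <- round(df$q, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
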