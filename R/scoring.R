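#' Cowan's K capacity estimate for change detection
#'
#' `K = S * (H - F)` with set size `S`, hit rate `H` and false-alarm rate
#' `F`. Vectorized over `hit_rate` / `fa_rate`.
#'
#' @param set_size number of to-be-memorized items (>= 1).
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @return Capacity estimate in items, in `[-S, S]`.
#' @examples
#' cowan_k(4, 0.90, 0.15)  # 3
#' @export
cowan_k <- function(set_size, hit_rate, fa_rate) {
  if (any(set_size < 1)) stop("set_size must be >= 1", call. = FALSE)
  if (any(hit_rate < 0 | hit_rate > 1) || any(fa_rate < 0 | fa_rate > 1)) {
    stop("hit and false-alarm rates must lie in [0, 1]", call. = FALSE)
  }
  set_size * (hit_rate - fa_rate)
}

#' @param trials a `wm_trial_counts` object (see
#'   [simulate_change_detection_trials()]).
#' @rdname cowan_k
#' @export
cowan_k_trials <- function(trials) {
  stopifnot(inherits(trials, "wm_trial_counts"))
  cowan_k(trials$set_size,
          trials$hits / trials$n_change,
          trials$false_alarms / trials$n_nochange)
}

#' Working-memory capacity as the maximum K across load conditions
#'
#' @param per_load_k capacities, one per set-size condition (non-empty).
#' @return The maximum element.
#' @export
k_max <- function(per_load_k) {
  if (length(per_load_k) == 0) {
    stop("per_load_k must be non-empty", call. = FALSE)
  }
  max(per_load_k)
}

#' Effective number of tracked objects (multiple-object tracking)
#'
#' `K = S * (2P - 1)` with target count `S` and tracking accuracy `P`.
#'
#' @param set_size number of tracked targets (>= 1).
#' @param accuracy tracking accuracy in `[0, 1]`.
#' @return Tracked capacity in items.
#' @examples
#' scholl_k(6, 0.75)  # 3
#' @export
scholl_k <- function(set_size, accuracy) {
  if (any(set_size < 1)) stop("set_size must be >= 1", call. = FALSE)
  if (any(accuracy < 0 | accuracy > 1)) {
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  }
  set_size * (2 * accuracy - 1)
}

#' Winsorize univariate outliers at 3 standard deviations
#'
#' Values beyond `mean(x) + 3 sd(x)` (or below `mean(x) - 3 sd(x)`) are
#' replaced with the cutoff. Cutoffs are computed once from the original
#' vector (grand mean and sample SD) and not iterated, so the operation
#' is idempotent with respect to those frozen cutoffs. A constant vector
#' (SD 0) is returned unchanged.
#'
#' @param x numeric vector of at least two finite values.
#' @return Vector of the same length with outliers replaced.
#' @export
winsorize_3sd <- function(x) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  m <- mean(x)
  s <- sd(x)
  if (s == 0) return(x)
  pmin(pmax(x, m - 3 * s), m + 3 * s)
}

#' Default working-memory composite structure
#'
#' Maps first-order factors to their member tasks and second-order
#' factors to first-order factors: the biological-motion (`BM`) and
#' non-biological-motion (`NBM`) event factors each average two
#' change-detection tasks, the event component `EVENT` averages `BM` and
#' `NBM`, `OBJECT` averages the three object and two binding tasks, and
#' `CE` averages the two executive tasks. Entries are resolved in list
#' order, so later composites may reference earlier ones.
#'
#' @return Named list of character vectors.
#' @export
wm_structure <- function() {
  list(
    BM     = c("pld_bm", "solid_bm"),
    NBM    = c("rec_move", "cir_move"),
    EVENT  = c("BM", "NBM"),
    OBJECT = c("color", "shape", "location",
               "color_location", "color_letter"),
    CE     = c("anti_saccade", "n_back")
  )
}

#' Composite component scores from task-level measures
#'
#' Z-scores each task across subjects (sample SD), then forms each
#' composite as the unweighted mean of its members. A member may name a
#' task or a previously computed composite, so hierarchical structures
#' such as `EVENT = 0.5 * (BM + NBM)` with `BM = 0.5 * (zPLD + zSolid)`
#' are expressed by listing `BM` and `NBM` before `EVENT`.
#'
#' @param task_table long-format data frame with columns `subject_id`,
#'   `task`, `score` (one row per subject x task).
#' @param structure named list of character vectors; defaults to
#'   [wm_structure()].
#' @return Data frame with `subject_id` and one column per composite
#'   (z-units).
#' @examples
#' tt <- expand.grid(subject_id = sprintf("s%02d", 1:10),
#'                   task = c("a", "b"), stringsAsFactors = FALSE)
#' tt$score <- rnorm(nrow(tt))
#' composite_scores(tt, list(AB = c("a", "b")))
#' @export
composite_scores <- function(task_table, structure = wm_structure()) {
  stopifnot(all(c("subject_id", "task", "score") %in% names(task_table)))
  subjects <- unique(task_table$subject_id)
  if (length(subjects) < 2) {
    stop("z-scoring needs at least two subjects", call. = FALSE)
  }
  tasks <- unique(unlist(structure))
  tasks <- setdiff(tasks, names(structure))

  wide <- matrix(NA_real_, length(subjects), length(tasks),
                 dimnames = list(subjects, tasks))
  tab <- task_table[task_table$task %in% tasks, , drop = FALSE]
  wide[cbind(match(tab$subject_id, subjects), match(tab$task, tasks))] <-
    tab$score
  if (anyNA(wide)) {
    miss <- which(is.na(wide), arr.ind = TRUE)[1, ]
    stop(sprintf("missing score for subject '%s', task '%s'",
                 subjects[miss[1]], tasks[miss[2]]), call. = FALSE)
  }

  z <- scale(wide)  # per-task z-scores across subjects (sample SD)
  if (any(!is.finite(z))) {
    stop("a task has zero variance across subjects; z-score undefined",
         call. = FALSE)
  }
  pool <- as.data.frame(z)

  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (comp in names(structure)) {
    members <- structure[[comp]]
    missing <- setdiff(members, names(pool))
    if (length(missing)) {
      stop(sprintf("composite '%s' references unknown member(s): %s",
                   comp, paste(missing, collapse = ", ")), call. = FALSE)
    }
    val <- rowMeans(pool[, members, drop = FALSE])
    pool[[comp]] <- val
    out[[comp]] <- val
  }
  out
}

#' Read / write composite or behavior score tables
#'
#' Tab-separated text with a header; first column `subject_id`, remaining
#' columns numeric scores.
#'
#' @param path file path.
#' @return `read_scores()` returns a data frame.
#' @export
read_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @param scores data frame with a `subject_id` column.
#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
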