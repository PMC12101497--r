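#' Segment an ROI time course by trial onsets and average per condition
#'
#' Cuts the series into onset-aligned windows (`window_s` seconds,
#' sampled every `tr` seconds, sample time = index * tr from onset) and
#' averages the windows of each condition. Trials whose window would run
#' past the end of the series are dropped with a warning; a condition
#' losing all its trials is an error.
#'
#' @param values ROI signal, one value per timepoint.
#' @param tr sampling interval in seconds (> 0).
#' @param onsets trial onset times in seconds.
#' @param conditions condition label per onset.
#' @param window_s window length in seconds after each onset.
#' @return Condition x time matrix; column names give the within-trial
#'   time in seconds.
#' @export
segment_and_average <- function(values, tr, onsets, conditions, window_s) {
  stopifnot(tr > 0, length(onsets) == length(conditions), window_s >= 0)
  n_samp <- floor(window_s / tr) + 1
  start <- floor(onsets / tr) + 1
  keep <- start + n_samp - 1 <= length(values)
  if (any(!keep)) {
    warning(sprintf("%d trial(s) dropped: window exceeds the series",
                    sum(!keep)))
  }
  conds <- unique(conditions)
  lost <- setdiff(conds, unique(conditions[keep]))
  if (length(lost)) {
    stop(sprintf("condition '%s' lost all trials", lost[1]), call. = FALSE)
  }
  out <- matrix(NA_real_, length(conds), n_samp,
                dimnames = list(conds,
                                format((seq_len(n_samp) - 1) * tr)))
  for (cond in conds) {
    idx <- which(conditions == cond & keep)
    seg <- vapply(idx, function(k) {
      values[start[k]:(start[k] + n_samp - 1)]
    }, numeric(n_samp))
    out[cond, ] <- rowMeans(matrix(seg, nrow = n_samp))
  }
  out
}

#' Percent signal change relative to a baseline time course
#'
#' `psc[t] = (condition[t] - baseline[t]) / baseline[t]`, timepoint-wise.
#'
#' @param condition_tc,baseline_tc equal-length numeric time courses;
#'   the baseline must be nonzero at every timepoint.
#' @return Percent-signal-change time course (proportion units).
#' @examples
#' percent_signal_change(rep(101, 5), rep(100, 5))  # 0.01 everywhere
#' @export
percent_signal_change <- function(condition_tc, baseline_tc) {
  if (length(condition_tc) != length(baseline_tc)) {
    stop("condition and baseline must have equal length", call. = FALSE)
  }
  zero <- which(baseline_tc == 0)
  if (length(zero)) {
    stop(sprintf("baseline is zero at timepoint %d", zero[1]), call. = FALSE)
  }
  (condition_tc - baseline_tc) / baseline_tc
}

#' Mean percent signal change over the delay-phase window
#'
#' Averages the samples whose onset-aligned time `index * tr` (0-based
#' index) falls inside `[t_start, t_end]`, endpoints included. The
#' default 13-15 s window targets the delay phase of a change-detection
#' trial, after the encoding response and before the probe response.
#'
#' @param psc percent-signal-change time course (onset-aligned).
#' @param tr sampling interval in seconds.
#' @param t_start,t_end window bounds in seconds (inclusive).
#' @return Mean PSC over the window.
#' @export
delay_window_mean <- function(psc, tr, t_start = 13, t_end = 15) {
  stopifnot(tr > 0, t_end >= t_start)
  times <- (seq_along(psc) - 1) * tr
  idx <- which(times >= t_start & times <= t_end)
  if (length(idx) == 0) {
    stop("no timepoint falls inside the requested window", call. = FALSE)
  }
  mean(psc[idx])
}

#' Read an ROI time course from single-column delimited text
#'
#' @param path file path (one signal value per line, no header).
#' @return Numeric vector.
#' @export
read_roi_series <- function(path) {
  scan(path, quiet = TRUE)
}

#' Read a trial-events table
#'
#' Three-column tab-separated text with a header: `onset_s`,
#' `duration_s`, `condition`.
#'
#' @param path file path.
#' @return Data frame with those columns.
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "condition")
  if (!all(need %in% names(ev))) {
    stop("events file must have columns onset_s, duration_s, condition",
         call. = FALSE)
  }
  ev
}
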