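# Treadmill speed -> stationary / locomotion / excluded frame labels.

#' Resample raw treadmill samples onto the imaging frame grid
#'
#' Linear interpolation of raw encoder samples (nominally 12 kHz) onto a
#' uniform grid at `target_hz`. If positions are supplied, speed is the
#' discrete derivative of position before interpolation. Output speed is
#' clipped at 0.
#'
#' @param raw_times Strictly increasing sample times, seconds.
#' @param raw_speeds Speed samples, cm/s (alternative to `raw_positions`).
#' @param raw_positions Position samples, cm (speed taken as the discrete
#'   derivative).
#' @param target_hz Target frame rate, Hz (default 40).
#' @param duration_s Optional output duration; defaults to the raw span.
#' @return A `speed_series` data.frame (`time_s`, `speed_cm_s`) with
#'   attribute `frame_hz`.
#' @export
resample_speed <- function(raw_times, raw_speeds = NULL, raw_positions = NULL,
                           target_hz = 40, duration_s = NULL) {
  if (any(diff(raw_times) <= 0)) {
    stop("`raw_times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(raw_speeds)) {
    if (is.null(raw_positions)) {
      stop("supply `raw_speeds` or `raw_positions`", call. = FALSE)
    }
    dt <- diff(raw_times)
    v <- diff(raw_positions) / dt
    raw_times <- (raw_times[-1] + raw_times[-length(raw_times)]) / 2
    raw_speeds <- v
  }
  if (is.null(duration_s)) duration_s <- max(raw_times)
  grid <- seq(0, duration_s, by = 1 / target_hz)
  sp <- stats::approx(raw_times, raw_speeds, xout = grid, rule = 2)$y
  out <- data.frame(time_s = grid, speed_cm_s = pmax(sp, 0))
  attr(out, "frame_hz") <- target_hz
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Segment behavior into stationary / locomotion / excluded frames
#'
#' Implements the three-criterion locomotion rule at the imaging frame rate:
#' a frame is locomotion when (i) instantaneous speed >= `v_thresh`, (ii)
#' `lp_cutoff_hz` low-pass-filtered speed >= `v_thresh`, and (iii) the mean
#' speed over a `window_s` window centered on the frame (truncated at trace
#' edges) >= `v_thresh`. Inter-locomotion gaps strictly shorter than
#' `merge_gap_s` are relabelled locomotion. Frames with instantaneous speed
#' below `v_thresh` are stationary unless they fall within `excl_after_s`
#' after or `excl_before_s` before a (merged) locomotion period, in which
#' case they are excluded from analysis. Frames at or above `v_thresh` that
#' fail the smoothed or windowed criteria fit neither definition and are
#' excluded as well.
#'
#' @param speed A `speed_series` data.frame or numeric speed vector (cm/s).
#' @param v_thresh Speed threshold, cm/s (default 0.1) for all three
#'   criteria.
#' @param lp_cutoff_hz Low-pass cutoff for criterion (ii), Hz (default 0.25).
#' @param lp_order FIR order for the low-pass (default 60).
#' @param window_s Averaging window for criterion (iii), seconds (default 2).
#' @param merge_gap_s Maximum gap merged into locomotion, seconds (default
#'   0.5, strict).
#' @param excl_after_s,excl_before_s Exclusion windows around locomotion,
#'   seconds (defaults 3 and 0.2).
#' @param frame_hz Frame rate when `speed` is a bare vector (default 40).
#' @return Factor of per-frame labels with levels `STATIONARY`, `LOCOMOTION`,
#'   `EXCLUDED`.
#' @export
segment_states <- function(speed, v_thresh = 0.1, lp_cutoff_hz = 0.25,
                           lp_order = 60L, window_s = 2, merge_gap_s = 0.5,
                           excl_after_s = 3, excl_before_s = 0.2,
                           frame_hz = 40) {
  if (is.data.frame(speed)) {
    frame_hz <- attr(speed, "frame_hz") %||% frame_hz
    speed <- speed$speed_cm_s
  }
  n <- length(speed)
  if (n == 0) stop("speed series is empty", call. = FALSE)
  if (n < window_s * frame_hz) {
    stop("speed series shorter than the averaging window", call. = FALSE)
  }

  lp <- smooth_lowpass(speed, lp_cutoff_hz, lp_order, frame_hz)
  half <- as.integer(round(window_s * frame_hz / 2))
  cs <- cumsum(c(0, speed))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  win_mean <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  loco <- speed >= v_thresh & lp >= v_thresh & win_mean >= v_thresh

  # merge inter-locomotion gaps strictly shorter than merge_gap_s
  max_gap <- merge_gap_s * frame_hz
  gaps <- true_runs(!loco)
  for (k in seq_len(nrow(gaps))) {
    g <- gaps[k, ]
    interior <- g$start > 1L && g$end < n
    if (interior && (g$end - g$start + 1L) < max_gap) {
      loco[g$start:g$end] <- TRUE
    }
  }

  labels <- rep("EXCLUDED", n)
  labels[loco] <- "LOCOMOTION"
  stationary_ok <- !loco & speed < v_thresh
  # exclusion windows around final locomotion periods
  runs <- true_runs(loco)
  excluded <- logical(n)
  n_after <- as.integer(round(excl_after_s * frame_hz))
  n_before <- as.integer(round(excl_before_s * frame_hz))
  for (k in seq_len(nrow(runs))) {
    r <- runs[k, ]
    if (r$end < n) {
      excluded[(r$end + 1L):min(r$end + n_after, n)] <- TRUE
    }
    if (r$start > 1L) {
      excluded[max(r$start - n_before, 1L):(r$start - 1L)] <- TRUE
    }
  }
  labels[stationary_ok & !excluded] <- "STATIONARY"
  factor(labels, levels = c("STATIONARY", "LOCOMOTION", "EXCLUDED"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate behavioral epochs
#'
#' Maximal runs of identical state labels, in temporal order.
#'
#' @param labels Factor from [segment_states()] (or any vector of labels).
#' @return data.frame with `state`, `start_frame`, `end_frame` (1-based,
#'   inclusive).
#' @export
enumerate_epochs <- function(labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start_frame = ends - r$lengths + 1L,
             end_frame = ends,
             stringsAsFactors = FALSE)
}
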