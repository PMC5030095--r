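# Independent brute-force oracles and small shared fixtures.

# Frame-by-frame application of the three-criterion locomotion rule, gap
# merging, and exclusion windows. Deliberately naive: per-frame loops, no
# reuse of the pipeline's run-length machinery.
oracle_segment <- function(speed, frame_hz = 40, v_thresh = 0.1,
                           window_s = 2, merge_gap_s = 0.5,
                           excl_after_s = 3, excl_before_s = 0.2) {
  n <- length(speed)
  lp <- smooth_lowpass(speed, cutoff_hz = 0.25, order = 60L,
                       rate_hz = frame_hz)
  half <- round(window_s * frame_hz / 2)
  loco <- logical(n)
  for (i in seq_len(n)) {
    wm <- mean(speed[max(1, i - half):min(n, i + half)])
    loco[i] <- speed[i] >= v_thresh && lp[i] >= v_thresh && wm >= v_thresh
  }
  merged <- loco
  i <- 1L
  while (i <= n) {
    if (!loco[i]) {
      j <- i
      while (j <= n && !loco[j]) j <- j + 1L
      if (i > 1L && j <= n && (j - i) < merge_gap_s * frame_hz) {
        merged[i:(j - 1L)] <- TRUE
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  n_after <- round(excl_after_s * frame_hz)
  n_before <- round(excl_before_s * frame_hz)
  lab <- rep("EXCLUDED", n)
  for (i in seq_len(n)) {
    if (merged[i]) {
      lab[i] <- "LOCOMOTION"
    } else if (speed[i] < v_thresh) {
      after <- i > 1L && any(merged[max(1L, i - n_after):(i - 1L)])
      before <- i < n && any(merged[(i + 1L):min(n, i + n_before)])
      if (!after && !before) lab[i] <- "STATIONARY"
    }
  }
  lab
}

# Random speed traces with structure that exercises every segmentation rule:
# bouts, short gaps, sub-threshold crawls, and noise near the thresholds.
random_speed_trace <- function(n_frames, frame_hz = 40) {
  segs <- list()
  total <- 0L
  while (total < n_frames) {
    len <- sample(4:120, 1)
    v <- sample(c(0, 0, 0.05, 0.12, 1, 3, 5), 1)
    segs[[length(segs) + 1L]] <- rep(v, len)
    total <- total + len
  }
  sp <- unlist(segs)[seq_len(n_frames)]
  pmax(sp + rnorm(n_frames, 0, 0.02), 0)
}

# dFF trace that is a deterministic function of the behavioral state:
# baseline `base`, multiplied by `gain` on locomotion frames.
state_driven_dff <- function(labels, base = 0.1, gain = 3) {
  ifelse(labels == "LOCOMOTION", base * gain, base)
}

# Labels with a prescribed run-length pattern, for LMI identity tests.
labels_from_pattern <- function(...) {
  runs <- list(...)
  factor(unlist(lapply(runs, function(r) rep(r$state, r$frames))),
         levels = c("STATIONARY", "LOCOMOTION", "EXCLUDED"))
}

# Small shared simulated session (built once per test run).
tiny_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gts <- list(ground_truth("VIP_LIKE", neuron_id = "n1"),
                  ground_truth("SST_LIKE", neuron_id = "n2"),
                  ground_truth("NULL", neuron_id = "n3"))
      cache <<- simulate_population(gts, n_trials_dark = 5,
                                    n_trials_stim = 6, seed = 42)
    }
    cache
  }
})
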