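# Synthetic session generator: behavior, stimulus, spiking, fluorescence.
#
# The generator states a "world" matching the statistics the analysis assumes:
# head-fixed mice running in bouts that occupy ~26% of time in darkness and
# ~41% during visual stimulation, 60 s trials at 40 Hz with dark and grating
# trials randomly interleaved, and neurons whose firing rate is multiplied by
# a context-specific locomotion gain — which makes the ground-truth locomotion
# modulation index analytic: LMI = (g - 1)/(g + 1) under a linear readout.

#' Locomotion bout model
#'
#' Parameters of the alternating bout/gap renewal process used to generate
#' treadmill speed. Gap means are derived per context from the target run
#' fractions: `mean_gap = mean_bout * (1 - p) / p`.
#'
#' @param p_run_dark Fraction of time running in darkness (default 0.26).
#' @param p_run_stim Fraction of time running during visual stimulation
#'   trials (default 0.41).
#' @param mean_bout_s Mean locomotion bout duration in seconds (default 10).
#' @param speed_mean_cm_s Mean running speed within bouts, cm/s (default 5).
#' @param speed_sd_cm_s Within-bout speed variability, cm/s (default 1.5).
#' @return A `bout_model` list.
#' @export
bout_model <- function(p_run_dark = 0.26, p_run_stim = 0.41,
                       mean_bout_s = 10, speed_mean_cm_s = 5,
                       speed_sd_cm_s = 1.5) {
  if (p_run_dark < 0 || p_run_dark >= 1 || p_run_stim < 0 || p_run_stim >= 1) {
    stop("run fractions must lie in [0, 1)", call. = FALSE)
  }
  stopifnot_scalar(mean_bout_s, "mean_bout_s", positive = TRUE)
  stopifnot_scalar(speed_mean_cm_s, "speed_mean_cm_s", positive = TRUE)
  if (speed_sd_cm_s < 0) stop("`speed_sd_cm_s` must be >= 0", call. = FALSE)
  structure(list(p_run_dark = p_run_dark, p_run_stim = p_run_stim,
                 mean_bout_s = mean_bout_s,
                 speed_mean_cm_s = speed_mean_cm_s,
                 speed_sd_cm_s = speed_sd_cm_s),
            class = "bout_model")
}

#' Generate a stimulus schedule
#'
#' Builds a per-frame stimulus schedule of 60 s trials at `frame_hz`, with
#' dark and visual-stimulation trials randomly interleaved. Each stimulation
#' trial starts and ends with a grey screen and contains repeated grating
#' presentations of one direction: a static phase of `static_s` seconds
#' followed by a drifting phase of `drift_s` seconds. Trial directions are
#' drawn without replacement from the 8 equally spaced directions within each
#' block of 8 stimulation trials.
#'
#' @param n_trials_dark,n_trials_stim Number of dark / stimulation trials.
#' @param static_s Static grating duration, seconds (in `[4, 5]`, default 4.5).
#' @param drift_s Drifting grating duration, seconds (default 2).
#' @param trial_s Trial duration, seconds (default 60).
#' @param grey_lead_s Grey screen at the start of each stimulation trial,
#'   seconds (default 3); the trial also ends with >= this much grey.
#' @param frame_hz Frame rate, Hz (default 40).
#' @param seed Integer seed for trial interleaving and direction order.
#' @return A data.frame of class `stim_schedule` with one row per frame:
#'   `frame`, `time_s`, `trial`, `trial_type` ("DARK"/"STIM"), `context`
#'   ("DARK"/"GREY"/"GRATING"), `direction` (degrees or `NA`), `phase`
#'   ("STATIC"/"DRIFTING" or `NA`). Frame rate stored in attribute
#'   `frame_hz`.
#' @export
generate_schedule <- function(n_trials_dark, n_trials_stim, static_s = 4.5,
                              drift_s = 2, trial_s = 60, grey_lead_s = 3,
                              frame_hz = 40, seed = 1L) {
  if (n_trials_dark < 0 || n_trials_stim < 0) {
    stop("trial counts must be non-negative", call. = FALSE)
  }
  if (n_trials_dark + n_trials_stim == 0) {
    stop("at least one trial is required", call. = FALSE)
  }
  if (static_s < 4 || static_s > 5) {
    stop("`static_s` must lie in [4, 5]", call. = FALSE)
  }
  stopifnot_scalar(drift_s, "drift_s", positive = TRUE)
  fpt <- as.integer(round(trial_s * frame_hz))
  dirs8 <- seq(0, 315, by = 45)

  with_seed(seed, {
    types <- sample(c(rep("DARK", n_trials_dark), rep("STIM", n_trials_stim)))
    n_stim <- sum(types == "STIM")
    # directions without replacement per block of 8 stimulation trials
    trial_dir <- unlist(lapply(seq_len(ceiling(n_stim / 8)), function(b) {
      sample(dirs8)
    }))[seq_len(n_stim)]

    stim_i <- 0L
    per_trial <- lapply(seq_along(types), function(ti) {
      if (types[ti] == "DARK") {
        return(data.frame(trial = ti, trial_type = "DARK", context = "DARK",
                          direction = NA_real_, phase = NA_character_,
                          stringsAsFactors = FALSE)[rep(1L, fpt), ])
      }
      stim_i <<- stim_i + 1L
      dir <- trial_dir[stim_i]
      ctx <- rep("GREY", fpt)
      phase <- rep(NA_character_, fpt)
      lead <- as.integer(round(grey_lead_s * frame_hz))
      pres_frames <- as.integer(round((static_s + drift_s) * frame_hz))
      static_frames <- as.integer(round(static_s * frame_hz))
      pos <- lead
      while (pos + pres_frames + lead <= fpt) {
        ctx[(pos + 1):(pos + pres_frames)] <- "GRATING"
        phase[(pos + 1):(pos + static_frames)] <- "STATIC"
        phase[(pos + static_frames + 1):(pos + pres_frames)] <- "DRIFTING"
        pos <- pos + pres_frames
      }
      data.frame(trial = ti, trial_type = "STIM", context = ctx,
                 direction = ifelse(ctx == "GRATING", dir, NA_real_),
                 phase = phase, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_trial)
    out$frame <- seq_len(nrow(out))
    out$time_s <- (out$frame - 1) / frame_hz
    rownames(out) <- NULL
    out <- out[, c("frame", "time_s", "trial", "trial_type", "context",
                   "direction", "phase")]
    attr(out, "frame_hz") <- frame_hz
    class(out) <- c("stim_schedule", "data.frame")
    out
  })
}

#' Generate a treadmill speed trace
#'
#' Simulates the alternating locomotion-bout / stationary-gap renewal process
#' at the schedule's frame rate: a two-state chain whose per-frame hazards are
#' the exact discretization of exponential bout and gap durations. The gap
#' hazard is context-conditional so that the long-run fraction of time spent
#' running converges to `p_run_dark` in dark trials and `p_run_stim` in
#' stimulation trials. Within bouts, speed is a 1 Hz low-pass-smoothed
#' Gaussian around `speed_mean_cm_s`, floored at 0.5 cm/s so that every
#' within-bout frame robustly exceeds the 0.1 cm/s segmentation criteria;
#' outside bouts speed is exactly 0.
#'
#' @param model A [bout_model()].
#' @param schedule A [generate_schedule()] data.frame.
#' @param seed Integer seed.
#' @return A data.frame of class `speed_series` with `time_s` and
#'   `speed_cm_s`; attributes `frame_hz` and `bout` (the ground-truth logical
#'   running indicator per frame).
#' @export
generate_speed <- function(model, schedule, seed = 1L) {
  stopifnot(inherits(model, "bout_model"), inherits(schedule, "stim_schedule"))
  n <- nrow(schedule)
  if (n == 0) stop("schedule is empty", call. = FALSE)
  frame_hz <- attr(schedule, "frame_hz")
  dt <- 1 / frame_hz
  p_run <- ifelse(schedule$trial_type == "STIM",
                  model$p_run_stim, model$p_run_dark)
  # exact discretization of exponential durations: P(exit state per frame)
  p_stop <- 1 - exp(-dt / model$mean_bout_s)
  mean_gap <- ifelse(p_run > 0,
                     model$mean_bout_s * (1 - p_run) / pmax(p_run, 1e-12),
                     Inf)
  p_start <- 1 - exp(-dt / mean_gap)          # 0 where p_run == 0

  with_seed(seed, {
    u <- runif(n)
    bout <- logical(n)
    running <- FALSE
    for (i in seq_len(n)) {
      running <- if (running) u[i] >= p_stop else u[i] < p_start[i]
      if (p_run[i] == 0) running <- FALSE   # no bouts possible in context
      bout[i] <- running
    }
    noise <- smooth_lowpass(rnorm(n, 0, model$speed_sd_cm_s),
                            cutoff_hz = 1, order = 60L, rate_hz = frame_hz)
    speed <- ifelse(bout, pmax(model$speed_mean_cm_s + noise, 0.5), 0)
    out <- data.frame(time_s = schedule$time_s, speed_cm_s = speed)
    attr(out, "frame_hz") <- frame_hz
    attr(out, "bout") <- bout
    class(out) <- c("speed_series", "data.frame")
    out
  })
}

#' Ground-truth parameters for one synthetic neuron
#'
#' Archetype defaults emulate the qualitative response classes observed in
#' mouse V1: `VIP_LIKE` (strong context-independent locomotion drive),
#' `SST_LIKE` (locomotion drive gated by visual input), `PV_LIKE` (moderate
#' context-independent drive), `EXC_LIKE` (visually tuned, modest locomotion
#' drive), and `NULL` (no locomotion modulation). Any field can be
#' overridden.
#'
#' @param archetype One of "EXC_LIKE", "VIP_LIKE", "SST_LIKE", "PV_LIKE",
#'   "NULL".
#' @param neuron_id Identifier.
#' @param ... Overrides for `baseline_rate_hz`, `visual_gain`,
#'   `tuning_pref_deg`, `tuning_width`, `loco_gain_dark`, `loco_gain_stim`,
#'   `gating_flag`, `neuropil_alpha`, `noise_sd`.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(archetype = c("EXC_LIKE", "VIP_LIKE", "SST_LIKE",
                                       "PV_LIKE", "NULL"),
                         neuron_id = 1L, ...) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    EXC_LIKE = list(baseline_rate_hz = 0.5, visual_gain = 2,
                    tuning_pref_deg = 0, tuning_width = 2,
                    loco_gain_dark = 1.2, loco_gain_stim = 1.6,
                    gating_flag = FALSE),
    VIP_LIKE = list(baseline_rate_hz = 1, visual_gain = 0,
                    tuning_pref_deg = 0, tuning_width = 0,
                    loco_gain_dark = 4, loco_gain_stim = 4,
                    gating_flag = FALSE),
    SST_LIKE = list(baseline_rate_hz = 0.5, visual_gain = 1,
                    tuning_pref_deg = 0, tuning_width = 0,
                    loco_gain_dark = 1, loco_gain_stim = 2,
                    gating_flag = TRUE),
    PV_LIKE = list(baseline_rate_hz = 1, visual_gain = 1,
                   tuning_pref_deg = 0, tuning_width = 0,
                   loco_gain_dark = 2, loco_gain_stim = 2,
                   gating_flag = FALSE),
    `NULL` = list(baseline_rate_hz = 0.5, visual_gain = 0,
                  tuning_pref_deg = 0, tuning_width = 0,
                  loco_gain_dark = 1, loco_gain_stim = 1,
                  gating_flag = FALSE))
  gt <- utils::modifyList(
    c(list(neuron_id = neuron_id, archetype = archetype), defaults,
      list(neuropil_alpha = 0, noise_sd = 2)),
    list(...))
  if (gt$baseline_rate_hz < 0 || gt$visual_gain < 0 ||
      gt$loco_gain_dark < 0 || gt$loco_gain_stim < 0) {
    stop("rates and gains must be >= 0", call. = FALSE)
  }
  structure(gt, class = "ground_truth")
}

#' Expected locomotion modulation index for a multiplicative gain
#'
#' Under a rate-linear readout a locomotion gain `g` yields
#' `LMI = (g - 1)/(g + 1)`.
#'
#' @param g Multiplicative locomotion gain (>= 0).
#' @return Expected LMI.
#' @export
expected_lmi <- function(g) (g - 1) / (g + 1)

# Cosine-power direction tuning bump: 1 at pref, 0 opposite, sharper with
# larger width exponent; width 0 means untuned (bump == 1 everywhere).
tuning_bump <- function(direction_deg, pref_deg, width) {
  if (width == 0) return(rep(1, length(direction_deg)))
  ((1 + cos((direction_deg - pref_deg) * pi / 180)) / 2)^width
}

#' Generate per-frame spike counts for one neuron
#'
#' Inhomogeneous Poisson counts with frame-wise constant rate
#' `lambda(t) = baseline_rate * tuning(t) * G(t)`, where `tuning(t)` is
#' `1 + visual_gain * bump(direction)` on grating frames (1 elsewhere) and
#' `G(t)` is the context-specific locomotion gain on frames inside a
#' ground-truth running bout — unless `gating_flag` is set, in which case the
#' gain applies only when visual drive is present (stimulation-trial frames).
#'
#' @param gt A [ground_truth()] object.
#' @param speed A [generate_speed()] series (its `bout` attribute defines
#'   running frames).
#' @param schedule The matching [generate_schedule()] data.frame.
#' @param seed Integer seed.
#' @return Integer vector of spike counts, one per frame.
#' @export
generate_spikes <- function(gt, speed, schedule, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  n <- nrow(schedule)
  if (nrow(speed) != n) stop("speed and schedule lengths differ", call. = FALSE)
  frame_hz <- attr(schedule, "frame_hz")
  bout <- attr(speed, "bout")
  if (is.null(bout)) bout <- speed$speed_cm_s > 0

  tuning <- rep(1, n)
  gr <- schedule$context == "GRATING"
  if (any(gr)) {
    tuning[gr] <- 1 + gt$visual_gain *
      tuning_bump(schedule$direction[gr], gt$tuning_pref_deg, gt$tuning_width)
  }
  gain <- rep(1, n)
  stim_frame <- schedule$trial_type == "STIM"
  if (gt$gating_flag) {
    gain[bout & stim_frame] <- gt$loco_gain_stim
  } else {
    gain[bout & stim_frame] <- gt$loco_gain_stim
    gain[bout & !stim_frame] <- gt$loco_gain_dark
  }
  lambda <- gt$baseline_rate_hz * tuning * gain / frame_hz
  with_seed(seed, rpois(n, lambda))
}

#' Generate a shared slow neuropil signal
#'
#' Low-frequency (0.2 Hz low-pass) nonnegative signal shared by all neurons
#' of a field of view, in raw fluorescence units.
#'
#' @param n_frames Number of frames.
#' @param frame_hz Frame rate in Hz.
#' @param mean_f,sd_f Mean and slow-fluctuation amplitude (fluorescence
#'   units).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_frames`, all values >= 0.
#' @export
generate_neuropil <- function(n_frames, frame_hz = 40, mean_f = 20, sd_f = 5,
                              seed = 1L) {
  with_seed(seed, {
    slow <- smooth_lowpass(rnorm(n_frames, 0, sd_f * sqrt(frame_hz / 2)),
                           cutoff_hz = 0.2, order = 60L, rate_hz = frame_hz)
    pmax(mean_f + slow, 0)
  })
}

#' Calcium-indicator forward model
#'
#' Converts spike counts into a raw fluorescence trace:
#' `F = offset * (1 + kernel_amp * (spikes (*) exp kernel)) +
#' neuropil_alpha * neuropil + Gaussian noise`. The kernel has instantaneous
#' rise and single-exponential decay with time constant `kernel_decay_s`
#' (GCaMP6f-like defaults: 20% dFF per spike, 0.7 s decay).
#'
#' @param spikes Integer spike counts per frame.
#' @param frame_hz Frame rate, Hz.
#' @param kernel_decay_s Decay time constant, seconds (default 0.7).
#' @param kernel_amp Fractional fluorescence change per spike (default 0.2).
#' @param neuropil Optional shared neuropil trace (same length as `spikes`).
#' @param neuropil_alpha Contamination weight (default 0).
#' @param noise_sd Gaussian noise SD in fluorescence units (default 2).
#' @param offset Baseline fluorescence, must be > 0 (default 100).
#' @param seed Integer seed.
#' @return Numeric fluorescence trace.
#' @export
spikes_to_fluorescence <- function(spikes, frame_hz = 40, kernel_decay_s = 0.7,
                                   kernel_amp = 0.2, neuropil = NULL,
                                   neuropil_alpha = 0, noise_sd = 2,
                                   offset = 100, seed = 1L) {
  stopifnot_scalar(kernel_decay_s, "kernel_decay_s", positive = TRUE)
  if (offset <= 0) stop("`offset` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  a <- exp(-1 / (frame_hz * kernel_decay_s))
  conv <- as.numeric(stats::filter(spikes, a, method = "recursive"))
  f <- offset * (1 + kernel_amp * conv)
  if (neuropil_alpha != 0) {
    if (is.null(neuropil) || length(neuropil) != length(spikes)) {
      stop("`neuropil` must match the spike series length", call. = FALSE)
    }
    f <- f + neuropil_alpha * neuropil
  }
  if (noise_sd > 0) {
    f <- f + with_seed(seed, rnorm(length(spikes), 0, noise_sd))
  }
  f
}

#' Simulate a population of neurons with shared behavior
#'
#' Convenience wrapper: one schedule and speed trace per animal, spike and
#' fluorescence generation per neuron, and a ground-truth table. All
#' randomness derives from `seed`.
#'
#' @param ground_truths List of [ground_truth()] objects.
#' @param n_trials_dark,n_trials_stim Trials per type (defaults 10 / 16, the
#'   midpoints of typical session designs).
#' @param model A [bout_model()].
#' @param animal_id,cell_type,layer Metadata recycled across neurons.
#' @param neuropil_alpha Contamination weight applied to every neuron
#'   (overrides per-neuron ground truth when not `NULL`).
#' @param seed Integer root seed.
#' @param ... Passed to [generate_schedule()].
#' @return List with `traces` (frames x neurons matrix), `neuropil`,
#'   `schedule`, `speed`, `ground_truth` (list), and `meta` (data.frame:
#'   neuron_id, animal_id, cell_type, layer, archetype).
#' @export
simulate_population <- function(ground_truths, n_trials_dark = 10,
                                n_trials_stim = 16, model = bout_model(),
                                animal_id = "m1", cell_type = "EXC",
                                layer = "L2/3", neuropil_alpha = NULL,
                                seed = 1L, ...) {
  schedule <- generate_schedule(n_trials_dark, n_trials_stim,
                                seed = derive_seed(seed, 1L), ...)
  speed <- generate_speed(model, schedule, seed = derive_seed(seed, 2L))
  n_frames <- nrow(schedule)
  frame_hz <- attr(schedule, "frame_hz")
  neuropil <- generate_neuropil(n_frames, frame_hz,
                                seed = derive_seed(seed, 3L))
  n_neurons <- length(ground_truths)
  traces <- matrix(NA_real_, n_frames, n_neurons)
  for (j in seq_len(n_neurons)) {
    gt <- ground_truths[[j]]
    alpha <- if (is.null(neuropil_alpha)) gt$neuropil_alpha else neuropil_alpha
    sp <- generate_spikes(gt, speed, schedule,
                          seed = derive_seed(seed, 10L + 2L * j))
    traces[, j] <- spikes_to_fluorescence(
      sp, frame_hz, neuropil = neuropil, neuropil_alpha = alpha,
      noise_sd = gt$noise_sd, seed = derive_seed(seed, 11L + 2L * j))
  }
  ids <- vapply(ground_truths, function(g) as.character(g$neuron_id), "")
  colnames(traces) <- ids
  meta <- data.frame(
    neuron_id = ids,
    animal_id = rep_len(animal_id, n_neurons),
    cell_type = rep_len(cell_type, n_neurons),
    layer = rep_len(layer, n_neurons),
    archetype = vapply(ground_truths, function(g) g$archetype, ""),
    stringsAsFactors = FALSE)
  list(traces = traces, neuropil = neuropil, schedule = schedule,
       speed = speed, ground_truth = ground_truths, meta = meta)
}
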