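# Locomotion modulation index, autocorrelation-adjusted bootstrap,
# responsiveness classification, speed cross-correlation, tuning indices.

#' Context masks from a stimulus schedule
#'
#' The three analysis contexts: `DARK` (frames of dark trials), `GREY` (grey
#' screen frames within stimulation trials), `STIM` (grating frames, static
#' and drifting pooled), plus `ALL`.
#'
#' @param schedule A [generate_schedule()] data.frame.
#' @return Named list of logical per-frame masks.
#' @export
context_masks <- function(schedule) {
  list(DARK = schedule$context == "DARK",
       GREY = schedule$context == "GREY",
       STIM = schedule$context == "GRATING",
       ALL = rep(TRUE, nrow(schedule)))
}

#' Locomotion modulation index (point estimate)
#'
#' `LMI = (R_L - R_S) / (R_L + R_S)` where `R_L` and `R_S` are the mean dFF0
#' over locomotion and stationary frames within the context; excluded frames
#' are ignored. The result is flagged invalid when either state has fewer
#' than `min_state_s` seconds of data in the context or when
#' `R_L + R_S <= 0` (the index is unbounded there and is not clipped).
#'
#' @param dff Numeric dFF0 trace.
#' @param labels State factor from [segment_states()].
#' @param context_mask Logical per-frame mask (default: all frames).
#' @param min_state_s Minimum seconds of each state required (default 5).
#' @param frame_hz Frame rate, Hz (default 40).
#' @return List: `r_l`, `r_s`, `lmi` (`NA` when invalid), `n_frames_loco`,
#'   `n_frames_stat`, `valid`.
#' @export
compute_lmi <- function(dff, labels, context_mask = NULL, min_state_s = 5,
                        frame_hz = 40) {
  n <- length(dff)
  if (length(labels) != n) stop("`dff` and `labels` lengths differ",
                                call. = FALSE)
  if (is.null(context_mask)) context_mask <- rep(TRUE, n)
  il <- context_mask & labels == "LOCOMOTION"
  is_ <- context_mask & labels == "STATIONARY"
  nl <- sum(il); ns <- sum(is_)
  r_l <- if (nl > 0) mean(dff[il]) else NA_real_
  r_s <- if (ns > 0) mean(dff[is_]) else NA_real_
  valid <- nl >= min_state_s * frame_hz && ns >= min_state_s * frame_hz &&
    isTRUE(r_l + r_s > 0)
  lmi <- if (valid) (r_l - r_s) / (r_l + r_s) else NA_real_
  list(r_l = r_l, r_s = r_s, lmi = lmi,
       n_frames_loco = nl, n_frames_stat = ns, valid = valid)
}

#' Extract 1 s bootstrap samples
#'
#' Splits the recording into maximal periods that are homogeneous in both
#' behavioral state (locomotion or stationary) and visual stimulus
#' (context, and for gratings direction and phase), then draws 1 s bins from
#' each period of length >= 1 s: the first bin starts at the period onset and
#' successive bin starts are 2 s apart (so consecutive samples of one period
#' are no less than 2 s apart, reflecting the ~2 s autocorrelation of the
#' calcium signal). Each sample is the mean dFF0 over its bin.
#'
#' @param dff Numeric dFF0 trace.
#' @param labels State factor from [segment_states()].
#' @param schedule Stimulus schedule data.frame.
#' @param context_mask Logical mask restricting to one context.
#' @param frame_hz Frame rate, Hz (default 40).
#' @param bin_s Bin length, seconds (default 1).
#' @param spacing_s Minimum start-to-start spacing, seconds (default 2).
#' @return data.frame: `value`, `state`, `stim`, `start_frame`.
#' @export
extract_samples <- function(dff, labels, schedule, context_mask = NULL,
                            frame_hz = 40, bin_s = 1, spacing_s = 2) {
  n <- length(dff)
  if (is.null(context_mask)) context_mask <- rep(TRUE, n)
  stim_id <- paste(schedule$context,
                   ifelse(is.na(schedule$direction), "", schedule$direction),
                   ifelse(is.na(schedule$phase), "", schedule$phase),
                   sep = "|")
  state <- as.character(labels)
  usable <- context_mask & state %in% c("STATIONARY", "LOCOMOTION")
  # homogeneous periods: maximal runs of identical (state, stimulus, usable)
  key <- paste(state, stim_id, usable)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bin_f <- as.integer(round(bin_s * frame_hz))
  gap_f <- as.integer(round(spacing_s * frame_hz))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    if (!usable[starts[k]]) next
    s0 <- starts[k]; s1 <- ends[k]
    bstarts <- seq(s0, s1, by = gap_f)
    bstarts <- bstarts[bstarts + bin_f - 1L <= s1]
    if (!length(bstarts)) next
    vals <- vapply(bstarts,
                   function(b) mean(dff[b:(b + bin_f - 1L)]), numeric(1))
    out[[k]] <- data.frame(value = vals, state = state[s0],
                           stim = stim_id[s0], start_frame = bstarts,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(value = numeric(0), state = character(0),
                      stim = character(0), start_frame = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap confidence interval for the locomotion modulation index
#'
#' Resamples the 1 s bins with replacement, stratified by behavioral state so
#' every iteration has both states represented. Because consecutive samples
#' are not fully independent (inter-sample correlation `R`, default 0.35),
#' each iteration draws only `round((1 - R) * n)` samples per state. The LMI
#' is recomputed from the resampled state means; the confidence interval is
#' the equal-tailed percentile interval of the `n_boot` replicates.
#'
#' @param samples data.frame from [extract_samples()].
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param R Assumed inter-sample correlation (default 0.35); the resample
#'   fraction is `1 - R`.
#' @param ci_level Confidence level (default 0.95).
#' @param min_samples Minimum bins per state (default 5); fewer flags the
#'   result invalid.
#' @param seed Integer seed.
#' @return List: `ci_low`, `ci_high`, `boot` (replicate LMIs), `n_loco`,
#'   `n_stat`, `n_draw_loco`, `n_draw_stat`, `valid`.
#' @export
bootstrap_lmi <- function(samples, n_boot = 10000L, R = 0.35,
                          ci_level = 0.95, min_samples = 5L, seed = 1L) {
  if (R < 0 || R >= 1) stop("`R` must lie in [0, 1)", call. = FALSE)
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  frac <- 1 - R
  vl <- samples$value[samples$state == "LOCOMOTION"]
  vs <- samples$value[samples$state == "STATIONARY"]
  nl <- length(vl); ns <- length(vs)
  kl <- max(1L, as.integer(round(frac * nl)))
  ks <- max(1L, as.integer(round(frac * ns)))
  if (nl < min_samples || ns < min_samples) {
    return(list(ci_low = NA_real_, ci_high = NA_real_, boot = numeric(0),
                n_loco = nl, n_stat = ns, n_draw_loco = kl, n_draw_stat = ks,
                valid = FALSE))
  }
  boot <- with_seed(seed, {
    ml <- rowMeans(matrix(vl[sample.int(nl, n_boot * kl, replace = TRUE)],
                          n_boot, kl))
    ms <- rowMeans(matrix(vs[sample.int(ns, n_boot * ks, replace = TRUE)],
                          n_boot, ks))
    (ml - ms) / (ml + ms)
  })
  alpha <- (1 - ci_level) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], boot = boot, n_loco = nl, n_stat = ns,
       n_draw_loco = kl, n_draw_stat = ks, valid = TRUE)
}

#' Classify locomotion responsiveness
#'
#' A neuron is positively locomotion responsive when its 95% bootstrap CI
#' excludes 0 from above (`ci_low > 0`) and its LMI exceeds `lmi_thresh`
#' (0.2, i.e. at least a 50% change in dFF0); negative responsiveness is the
#' mirrored rule.
#'
#' @param lmi Point LMI.
#' @param ci_low,ci_high Bootstrap CI bounds.
#' @param lmi_thresh Magnitude threshold (default 0.2).
#' @return One of `"POSITIVE"`, `"NEGATIVE"`, `"NONE"` (also `"NONE"` for
#'   invalid/`NA` input).
#' @export
classify_responsiveness <- function(lmi, ci_low, ci_high, lmi_thresh = 0.2) {
  if (is.na(lmi) || is.na(ci_low) || is.na(ci_high)) return("NONE")
  if (ci_low > 0 && lmi > lmi_thresh) return("POSITIVE")
  if (ci_high < 0 && lmi < -lmi_thresh) return("NEGATIVE")
  "NONE"
}

#' Cross-correlation between dFF0 and running speed
#'
#' Pearson correlation at integer frame lags in `[-max_lag_s, max_lag_s]`.
#' Positive lags mean the neural signal lags the behavior:
#' `corr(lag) = cor(dff(t), speed(t - lag))`.
#'
#' @param dff Numeric dFF0 trace.
#' @param speed Numeric speed trace (cm/s) or `speed_series` data.frame.
#' @param max_lag_s Maximum lag, seconds (default 10).
#' @param frame_hz Frame rate, Hz (default 40).
#' @return List: `lag_s`, `corr`, `zero_time_corr`, `peak_lag_s`.
#' @export
cross_correlate <- function(dff, speed, max_lag_s = 10, frame_hz = 40) {
  if (is.data.frame(speed)) speed <- speed$speed_cm_s
  n <- length(dff)
  if (length(speed) != n) stop("series lengths differ", call. = FALSE)
  if (sd(dff) == 0 || sd(speed) == 0) {
    stop("zero-variance input: constant speed or silent neuron",
         call. = FALSE)
  }
  max_lag <- as.integer(round(max_lag_s * frame_hz))
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      cor(dff[(1 + l):n], speed[1:(n - l)])
    } else {
      cor(dff[1:(n + l)], speed[(1 - l):n])
    }
  }, numeric(1))
  lag_s <- lags / frame_hz
  list(lag_s = lag_s, corr = cc, zero_time_corr = cc[max_lag + 1L],
       peak_lag_s = lag_s[which.max(cc)])
}

#' Orientation and direction selectivity indices
#'
#' From mean drifting-phase responses to 8 equally spaced directions:
#' `DSI = (R_pref - R_opp) / (R_pref + R_opp)` and
#' `OSI = (R_pref - R_ortho) / (R_pref + R_ortho)`, where `R_pref` is the
#' maximal response, `R_opp` the response 180 deg away, and `R_ortho` the
#' mean of the two orthogonal directions.
#'
#' @param direction_means Nonnegative mean responses, one per direction.
#' @param directions Direction angles in degrees (default 8 equally spaced).
#' @return List: `pref_direction_deg`, `osi`, `dsi`, `valid` (`FALSE` for
#'   all-zero or negative input, indices `NA`).
#' @export
compute_osi_dsi <- function(direction_means,
                            directions = seq(0, 315, by = 45)) {
  if (length(direction_means) != length(directions)) {
    stop("one mean per direction required", call. = FALSE)
  }
  if (any(is.na(direction_means)) || all(direction_means == 0) ||
      any(direction_means < 0)) {
    return(list(pref_direction_deg = NA_real_, osi = NA_real_,
                dsi = NA_real_, valid = FALSE))
  }
  i_pref <- which.max(direction_means)
  pref <- directions[i_pref]
  r_pref <- direction_means[i_pref]
  r_opp <- direction_means[match((pref + 180) %% 360, directions)]
  ortho <- c((pref + 90) %% 360, (pref + 270) %% 360)
  r_ortho <- mean(direction_means[match(ortho, directions)])
  list(pref_direction_deg = pref,
       osi = (r_pref - r_ortho) / (r_pref + r_ortho),
       dsi = (r_pref - r_opp) / (r_pref + r_opp),
       valid = TRUE)
}

#' Per-direction mean drifting-phase responses
#'
#' Mean dFF0 over drifting-grating frames, split by direction.
#'
#' @param dff Numeric dFF0 trace.
#' @param schedule Stimulus schedule data.frame.
#' @return Named numeric vector of mean responses (names = directions, deg).
#' @export
direction_means <- function(dff, schedule) {
  sel <- !is.na(schedule$phase) & schedule$phase == "DRIFTING"
  if (!any(sel)) stop("schedule contains no drifting-grating frames",
                      call. = FALSE)
  tapply(dff[sel], schedule$direction[sel], mean)
}
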