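# Locomotion modulation index, samples, bootstrap, responsiveness,
# cross-correlation, tuning indices.

test_that("LMI identities: 3x change is 0.5, no change is 0, 50% is 0.2", {
  hz <- 40
  lab <- labels_from_pattern(list(state = "STATIONARY", frames = 10 * hz),
                             list(state = "LOCOMOTION", frames = 10 * hz))
  a <- 0.37
  dff3 <- ifelse(lab == "LOCOMOTION", 3 * a, a)
  expect_equal(compute_lmi(dff3, lab)$lmi, 0.5)
  dff1 <- rep(a, length(lab))
  expect_equal(compute_lmi(dff1, lab)$lmi, 0)
  dff15 <- ifelse(lab == "LOCOMOTION", 1.5, 1.0)
  expect_equal(compute_lmi(dff15, lab)$lmi, 0.2)
})

test_that("LMI is antisymmetric under state relabeling", {
  set.seed(21)
  hz <- 40
  lab <- labels_from_pattern(list(state = "STATIONARY", frames = 8 * hz),
                             list(state = "LOCOMOTION", frames = 6 * hz),
                             list(state = "EXCLUDED", frames = 2 * hz),
                             list(state = "STATIONARY", frames = 7 * hz),
                             list(state = "LOCOMOTION", frames = 9 * hz))
  for (k in 1:10) {
    dff <- runif(length(lab), 0.05, 1)
    swapped <- factor(ifelse(lab == "LOCOMOTION", "STATIONARY",
                             ifelse(lab == "STATIONARY", "LOCOMOTION",
                                    "EXCLUDED")),
                      levels = levels(lab))
    expect_equal(compute_lmi(dff, swapped)$lmi, -compute_lmi(dff, lab)$lmi,
                 tolerance = 1e-12)
  }
})

test_that("degenerate LMIs are flagged invalid, not clipped", {
  hz <- 40
  lab <- labels_from_pattern(list(state = "STATIONARY", frames = 10 * hz),
                             list(state = "LOCOMOTION", frames = 10 * hz))
  dff <- ifelse(lab == "LOCOMOTION", -0.3, 0.1)   # r_l + r_s < 0
  res <- compute_lmi(dff, lab)
  expect_false(res$valid)
  expect_true(is.na(res$lmi))
  # insufficient state duration
  lab2 <- labels_from_pattern(list(state = "STATIONARY", frames = 10 * hz),
                              list(state = "LOCOMOTION", frames = 2 * hz))
  expect_false(compute_lmi(rep(0.1, length(lab2)), lab2)$valid)
})

test_that("sample extraction follows the 1 s bin / 2 s spacing rule", {
  hz <- 40
  sch <- generate_schedule(1, 0, seed = 1)    # all dark: stimulus constant
  n <- nrow(sch)
  mk <- function(frames_per_state) {
    labels_from_pattern(list(state = "STATIONARY", frames = frames_per_state),
                        list(state = "LOCOMOTION",
                             frames = n - frames_per_state))
  }
  # 0.9 s homogeneous period -> no samples from it
  lab <- mk(round(0.9 * hz))
  s <- extract_samples(rep(0.2, n), lab, sch)
  expect_equal(sum(s$state == "STATIONARY"), 0)
  # 5.0 s period -> 3 samples starting at 0, 2, 4 s
  lab5 <- mk(5 * hz)
  s5 <- extract_samples(rep(0.2, n), lab5, sch)
  st <- s5[s5$state == "STATIONARY", ]
  expect_equal(nrow(st), 3)
  expect_equal(st$start_frame, c(1, 81, 161))
  # constant dFF -> every sample equals the constant
  expect_true(all(s5$value == 0.2))
})

test_that("samples are homogeneous in state and stimulus", {
  sim <- tiny_session()
  lab <- segment_states(sim$speed)
  dff <- process_trace(sim$traces[, 1], sim$schedule$trial)$dff
  m <- context_masks(sim$schedule)
  for (ctx in c("DARK", "STIM")) {
    s <- extract_samples(dff, lab, sim$schedule, m[[ctx]])
    expect_gt(nrow(s), 0)
    for (i in seq_len(nrow(s))) {
      frames <- s$start_frame[i]:(s$start_frame[i] + 39)
      expect_equal(length(unique(as.character(lab[frames]))), 1)
      expect_true(all(m[[ctx]][frames]))
      key <- paste(sim$schedule$context[frames],
                   sim$schedule$direction[frames],
                   sim$schedule$phase[frames])
      expect_equal(length(unique(key)), 1)
    }
  }
})

test_that("bootstrap resamples 1 - R of the samples, stratified by state", {
  s <- data.frame(value = rep(c(3, 1), each = 20),
                  state = rep(c("LOCOMOTION", "STATIONARY"), each = 20),
                  stim = "x", start_frame = 1:40)
  b <- bootstrap_lmi(s, n_boot = 50, R = 0.35, seed = 1)
  expect_equal(b$n_draw_loco, round(0.65 * 20))
  expect_equal(b$n_draw_stat, round(0.65 * 20))
  # degenerate distributions: every replicate LMI is exactly 0.5
  expect_true(all(b$boot == 0.5))
  expect_equal(c(b$ci_low, b$ci_high), c(0.5, 0.5))
  # the degenerate CI contains the point estimate
  expect_true(b$ci_low <= 0.5 && b$ci_high >= 0.5)
})

test_that("bootstrap is deterministic under a fixed seed", {
  set.seed(31)
  s <- data.frame(value = runif(60, 0.05, 0.5),
                  state = rep(c("LOCOMOTION", "STATIONARY"), 30),
                  stim = "x", start_frame = 1:60)
  b1 <- bootstrap_lmi(s, n_boot = 200, seed = 9)
  b2 <- bootstrap_lmi(s, n_boot = 200, seed = 9)
  expect_identical(b1$boot, b2$boot)
  b3 <- bootstrap_lmi(s, n_boot = 200, seed = 10)
  expect_false(identical(b3$boot, b1$boot))
})

test_that("null samples give near-nominal CI coverage", {
  # state-independent noise: the CI should contain 0 in at least ~95% of
  # replicates (the reduced resample fraction makes it conservative;
  # measured coverage ~0.97)
  set.seed(32)
  cover <- replicate(200, {
    s <- data.frame(value = rnorm(40, 0.2, 0.05),
                    state = rep(c("LOCOMOTION", "STATIONARY"), each = 20),
                    stim = "x", start_frame = 1:40)
    b <- bootstrap_lmi(s, n_boot = 400, seed = sample.int(2^30, 1))
    b$ci_low <= 0 && b$ci_high >= 0
  })
  expect_gte(mean(cover), 0.93)
})

test_that("CI width shrinks with more samples at full resampling", {
  set.seed(33)
  width <- sapply(c(20, 80, 320), function(n) {
    s <- data.frame(value = rnorm(2 * n, 0.3, 0.05),
                    state = rep(c("LOCOMOTION", "STATIONARY"), each = n),
                    stim = "x", start_frame = seq_len(2 * n))
    b <- bootstrap_lmi(s, n_boot = 1000, R = 0, seed = 5)
    b$ci_high - b$ci_low
  })
  expect_true(all(diff(width) < 0))
})

test_that("too few samples invalidate the bootstrap", {
  s <- data.frame(value = c(1, 1, 3, 3, 3, 3, 3),
                  state = c(rep("STATIONARY", 2), rep("LOCOMOTION", 5)),
                  stim = "x", start_frame = 1:7)
  b <- bootstrap_lmi(s, n_boot = 10, seed = 1)
  expect_false(b$valid)
  expect_true(is.na(b$ci_low))
})

test_that("responsiveness needs both the CI rule and the 0.2 threshold", {
  expect_equal(classify_responsiveness(0.5, 0.3, 0.7), "POSITIVE")
  expect_equal(classify_responsiveness(0.15, 0.05, 0.25), "NONE")
  expect_equal(classify_responsiveness(-0.4, -0.6, -0.2), "NEGATIVE")
  expect_equal(classify_responsiveness(0.5, -0.1, 0.8), "NONE")
  expect_equal(classify_responsiveness(NA, NA, NA), "NONE")
})

test_that("cross-correlation sign convention and null level", {
  set.seed(41)
  sp <- pmax(smooth_lowpass(rnorm(4000, 1, 2), cutoff_hz = 0.5), 0)
  cc <- cross_correlate(sp, sp, max_lag_s = 2)
  expect_equal(cc$zero_time_corr, 1)
  expect_equal(cc$peak_lag_s, 0)

  # dff delayed by 1 s: peak at +1 s (neural signal lags behavior)
  dff <- c(rep(0, 40), sp[1:(length(sp) - 40)])
  cc2 <- cross_correlate(dff, sp, max_lag_s = 3)
  expect_equal(cc2$peak_lag_s, 1)

  # independent white noise at large n
  cc3 <- cross_correlate(rnorm(1e5), rnorm(1e5, 1, 1), max_lag_s = 0.25)
  expect_lt(abs(cc3$zero_time_corr), 0.02)

  expect_error(cross_correlate(rep(1, 100), rnorm(100)), "zero-variance")
})

test_that("OSI/DSI follow the preferred/opposite/orthogonal convention", {
  dirs <- seq(0, 315, by = 45)
  only_pref <- c(2, 0, 0, 0, 0, 0, 0, 0)
  r <- compute_osi_dsi(only_pref, dirs)
  expect_equal(c(r$osi, r$dsi), c(1, 1))
  expect_equal(r$pref_direction_deg, 0)

  uniform <- rep(1, 8)
  r2 <- compute_osi_dsi(uniform, dirs)
  expect_equal(c(r2$osi, r2$dsi), c(0, 0))

  # R_pref = 2 at 90 deg, all others 1: DSI = OSI = 1/3
  resp <- rep(1, 8); resp[dirs == 90] <- 2
  r3 <- compute_osi_dsi(resp, dirs)
  expect_equal(r3$dsi, 1 / 3)
  expect_equal(r3$osi, 1 / 3)
  expect_equal(r3$pref_direction_deg, 90)

  expect_false(compute_osi_dsi(rep(0, 8), dirs)$valid)
})

test_that("direction means feed tuning indices from schedule frames", {
  sch <- generate_schedule(1, 8, seed = 13)   # full 8-direction block
  dff <- cos((sch$direction - 45) * pi / 180)
  dff[is.na(dff)] <- 0
  dm <- direction_means(dff + 1, sch)
  r <- compute_osi_dsi(as.numeric(dm), as.numeric(names(dm)))
  expect_equal(r$pref_direction_deg, 45)
  expect_true(r$dsi > 0.9)
})
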