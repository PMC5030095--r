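# Synthetic-data generator: schedule, speed, spikes, fluorescence.

test_that("schedule covers every frame and respects grating structure", {
  sch <- generate_schedule(3, 8, static_s = 4, seed = 7)
  expect_equal(nrow(sch), 11 * 60 * 40)
  expect_false(any(is.na(sch$context)))

  # each of the 8 directions appears exactly once in a block of 8 stim trials
  dirs <- unique(sch[sch$trial_type == "STIM", c("trial", "direction")])
  dirs <- dirs[!is.na(dirs$direction), ]
  per_trial <- tapply(dirs$direction, dirs$trial,
                      function(d) length(unique(d)))
  expect_true(all(per_trial == 1))  # one direction per trial
  expect_setequal(unique(dirs$direction), seq(0, 315, by = 45))
  expect_equal(length(unique(dirs$trial)), 8)

  # every grating presentation: static 4 s then drifting 2 s = 240 frames
  gr <- rle(paste(sch$context, sch$phase))
  pres <- gr$lengths[grepl("GRATING", gr$values)]
  static <- gr$lengths[grepl("STATIC", gr$values)]
  drift <- gr$lengths[grepl("DRIFTING", gr$values)]
  expect_true(all(static == 160) && all(drift == 80))
  expect_equal(sum(pres), sum(static) + sum(drift))

  # stim trials start and end with grey
  for (ti in unique(sch$trial[sch$trial_type == "STIM"])[1:3]) {
    ctx <- sch$context[sch$trial == ti]
    expect_equal(ctx[1], "GREY")
    expect_equal(ctx[length(ctx)], "GREY")
  }
})

test_that("degenerate schedules behave as stated", {
  sch <- generate_schedule(1, 0, seed = 1)
  expect_true(all(sch$context == "DARK"))
  expect_error(generate_schedule(-1, 2), "non-negative")
  expect_error(generate_schedule(2, 2, static_s = 3.5), "static_s")
})

test_that("speed generation is seeded, nonnegative, and bout-confined", {
  sch <- generate_schedule(3, 3, seed = 2)
  sp1 <- generate_speed(bout_model(), sch, seed = 5)
  sp2 <- generate_speed(bout_model(), sch, seed = 5)
  sp3 <- generate_speed(bout_model(), sch, seed = 6)
  expect_identical(sp1$speed_cm_s, sp2$speed_cm_s)
  expect_false(identical(sp1$speed_cm_s, sp3$speed_cm_s))
  expect_true(all(sp1$speed_cm_s >= 0))
  expect_true(all(sp1$speed_cm_s[!attr(sp1, "bout")] == 0))

  # degenerate model: no bouts possible in darkness
  sp0 <- generate_speed(bout_model(p_run_dark = 0), sch, seed = 5)
  expect_true(all(sp0$speed_cm_s[sch$trial_type == "DARK"] == 0))
})

test_that("long-run locomotion fraction matches the bout model target", {
  # 2 simulated hours of darkness; fraction measured by the segmentation
  sch <- generate_schedule(120, 0, seed = 3)
  sp <- generate_speed(bout_model(), sch, seed = 8)
  lab <- segment_states(sp)
  expect_equal(mean(lab == "LOCOMOTION"), 0.26, tolerance = 0.03 / 0.26)
})

test_that("spike rates realize the multiplicative gain model", {
  sch <- generate_schedule(6, 6, seed = 4)
  sp <- generate_speed(bout_model(), sch, seed = 9)
  bout <- attr(sp, "bout")

  # gated archetype: gain 3 during stimulation trials only
  gt <- ground_truth("SST_LIKE", neuron_id = 1, loco_gain_stim = 3,
                     visual_gain = 0, baseline_rate_hz = 5)
  spk <- generate_spikes(gt, sp, sch, seed = 10)
  stim <- sch$trial_type == "STIM"
  ratio_stim <- mean(spk[stim & bout]) / mean(spk[stim & !bout])
  ratio_dark <- mean(spk[!stim & bout]) / mean(spk[!stim & !bout])
  expect_equal(ratio_stim, 3, tolerance = 0.15)
  expect_equal(ratio_dark, 1, tolerance = 0.15)

  # no locomotion gain: counts uncorrelated with speed
  gt0 <- ground_truth("NULL", neuron_id = 2, baseline_rate_hz = 5)
  spk0 <- generate_spikes(gt0, sp, sch, seed = 11)
  expect_lt(abs(cor(spk0, sp$speed_cm_s)), 0.02)

  # silent neuron
  gtz <- ground_truth("NULL", neuron_id = 3, baseline_rate_hz = 0)
  expect_true(all(generate_spikes(gtz, sp, sch, seed = 12) == 0))
})

test_that("fluorescence forward model follows the kernel definition", {
  # no spikes, no noise: F is exactly the offset
  f <- spikes_to_fluorescence(rep(0L, 400), noise_sd = 0, offset = 50)
  expect_equal(f, rep(50, 400))

  # single spike decays to 1/e of its peak in kernel_decay_s
  spk <- rep(0L, 400); spk[100] <- 1L
  f1 <- spikes_to_fluorescence(spk, kernel_decay_s = 0.7, noise_sd = 0,
                               offset = 100)
  peak <- f1[100] - 100
  at_tau <- f1[100 + round(0.7 * 40)] - 100
  expect_equal(at_tau / peak, exp(-1), tolerance = 1e-6)

  # linearity: doubling counts doubles F - offset
  f2 <- spikes_to_fluorescence(2L * spk, kernel_decay_s = 0.7, noise_sd = 0,
                               offset = 100)
  expect_equal(f2 - 100, 2 * (f1 - 100), tolerance = 1e-9)

  expect_error(spikes_to_fluorescence(spk, offset = 0), "positive")
})

test_that("simulated series are bit-for-bit reproducible under a seed", {
  gts <- list(ground_truth("VIP_LIKE", neuron_id = 1))
  a <- simulate_population(gts, n_trials_dark = 2, n_trials_stim = 2,
                           seed = 77)
  b <- simulate_population(gts, n_trials_dark = 2, n_trials_stim = 2,
                           seed = 77)
  expect_identical(a$traces, b$traces)
  expect_identical(a$speed$speed_cm_s, b$speed$speed_cm_s)
})
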