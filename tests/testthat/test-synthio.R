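test_that("identical config gives bit-identical recording and annotation", {
  cfg <- synth_config(duration_s = 5, seed = 42)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a, b)
  cfg2 <- synth_config(duration_s = 5, seed = 43)
  expect_false(identical(generate_recording(cfg2)$ground_truth$spikes,
                         a$ground_truth$spikes))
})

test_that("annotation is sound for every preset and artefact class", {
  presets <- c("spontaneous", "nmda", "electrical", "optomotor")
  for (p in presets) {
    gt <- generate_recording(synth_config(duration_s = 8, preset = p,
                                          seed = 7))$ground_truth
    expect_silent(check_ground_truth(gt))
    expect_true(all(gt$spikes$time_s >= 0))
  }
  for (a in c("erratic_burst", "dual_frequency", "incoherent",
              "stim_artefact")) {
    gt <- generate_recording(synth_config(duration_s = 6, artefacts = a,
                                          seed = 8))$ground_truth
    expect_silent(check_ground_truth(gt))
    expect_true(a %in% gt$artefacts$type)
  }
})

test_that("right bursts lag left by half a cycle at 180 degrees anti-phase", {
  out <- fixed_freq_recording(25, noise_sd = 0, seed = 5, duration_s = 2.2)
  b <- out$ground_truth$bursts
  midL <- (b$start_s + b$end_s)[b$channel == "left"] / 2
  midR <- (b$start_s + b$end_s)[b$channel == "right"] / 2
  k <- min(length(midL), length(midR), 5)
  # half of a 40 ms cycle = 20 ms
  expect_equal(midR[1:k] - midL[1:k], rep(0.020, k), tolerance = 1e-6)
})

test_that("electrical preset yields non-increasing trajectories starting above 30 Hz", {
  gt <- generate_recording(synth_config(duration_s = 40, preset = "electrical",
                                        seed = 2))$ground_truth
  expect_gt(nrow(gt$bouts), 1)
  for (b in unique(gt$freq_trajectory$bout)) {
    f <- gt$freq_trajectory$freq_hz[gt$freq_trajectory$bout == b]
    expect_true(all(diff(f) <= 1e-9))
    expect_gt(f[1], 30)
  }
})

test_that("preset frequency statistics mirror the treatment contrasts", {
  collect_freqs <- function(preset, n_rec = 12) {
    unlist(lapply(seq_len(n_rec), function(s) {
      generate_recording(synth_config(duration_s = 30, preset = preset,
                                      seed = 100 + s))$ground_truth$bouts$mean_freq_hz
    }))
  }
  f_nmda <- collect_freqs("nmda")
  f_opto <- collect_freqs("optomotor")
  expect_gte(length(f_nmda) + length(f_opto), 100)
  expect_lt(median(f_nmda), 20)
  expect_gt(sum(f_opto > 30), 5)
  expect_gt(sum(f_opto < 30), 5)
})

test_that("generation fails loudly when the duration cannot hold a bout", {
  expect_error(generate_recording(synth_config(duration_s = 0.4, seed = 1)),
               "too short")
  expect_error(synth_config(freq_range_hz = c(5, 40)), "within")
  expect_error(synth_config(freq_trajectory = "wiggly"), "freq_trajectory")
  expect_error(synth_config(artefacts = "ghost"), "artefacts")
  expect_error(synth_config(sampling_rate_hz = 2000), "sampling_rate")
})

test_that("calcium traces carry the injected lag and resolve sequential bouts", {
  gt <- generate_recording(synth_config(duration_s = 20,
                                        bout_rate_per_min = 12,
                                        seed = 3))$ground_truth
  # near-instant kernel isolates the pure time shift: the raw
  # cross-correlation against the bout indicator peaks at the lag
  ca <- generate_calcium(gt, n_rois = 3, lag_s = 0.3, frame_rate_hz = 50,
                         kernel_tau_s = 0.02, noise_sd = 0, seed = 9)
  ind <- fictiveswim:::bout_indicator(gt$bouts, ca$frame_times_s)
  y <- rowMeans(ca$f)
  dt <- 1 / ca$frame_rate_hz
  shifts <- 0:as.integer(1 / dt)
  cc <- vapply(shifts, function(k) {
    n <- length(y)
    stats::cor(y[(1 + k):n], ind[1:(n - k)])
  }, numeric(1))
  lag_hat <- shifts[which.max(cc)] * dt
  expect_lt(abs(lag_hat - 0.3), 0.05)
  expect_equal(ca$lag_s, 0.3)

  # a 0.3 s kernel decays below 4% within 1 s, so bouts >= 1 s apart give
  # separate transients: count local maxima of the ROI-average above
  # 40% of max
  ca2 <- generate_calcium(gt, n_rois = 3, lag_s = 0.3, frame_rate_hz = 50,
                          kernel_tau_s = 0.3, noise_sd = 0, seed = 9)
  sep <- diff(gt$bouts$start_s)
  expect_true(any(sep >= 1))
  y2 <- rowMeans(ca2$f)
  yz <- y2 - min(y2)
  pk <- pracma::findpeaks(yz, minpeakheight = 0.4 * max(yz),
                          minpeakdistance = as.integer(0.5 / dt))
  expect_gte(nrow(pk), nrow(gt$bouts) - 1)
  expect_lt(exp(-1 / 0.3), 0.04)
})

test_that("degenerate calcium configurations behave per contract", {
  gt <- generate_recording(synth_config(duration_s = 5, seed = 3))$ground_truth
  ca0 <- generate_calcium(gt, n_rois = 0, lag_s = 0.3, frame_rate_hz = 30)
  expect_equal(ncol(ca0$f), 0)
  expect_gt(length(ca0$frame_times_s), 100)
  expect_error(generate_calcium(gt, n_rois = 2, kernel_tau_s = 0),
               "kernel_tau_s")
  expect_error(generate_calcium(gt, n_rois = 2, frame_rate_hz = 1e6),
               "frame_rate")
})
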