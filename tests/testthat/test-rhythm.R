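fs <- 10000

test_that("envelope trace oscillates at the tail-beat frequency", {
  out <- fixed_freq_recording(25, noise_sd = 0, seed = 51, duration_s = 3)
  den <- wavelet_denoise(out$recording)
  e <- extract_episodes(den)$episodes[[1]]
  env <- envelope_activity_trace(den, "left", e$start_s, e$end_s)
  v <- env$value - mean(env$value)
  n <- length(v)
  spec <- Mod(stats::fft(v))[1:(n %/% 2)]
  fgrid <- (0:(n %/% 2 - 1)) * fs / n
  peak <- fgrid[which.max(spec)]
  expect_lt(abs(peak - 25), 1)
  # apex times align with burst midpoints within a quarter cycle
  pk <- pracma::findpeaks(env$value, minpeakheight = 0.3 * max(env$value),
                          minpeakdistance = as.integer(0.02 * fs))
  apex <- env$time_s[pk[, 2]]
  gt <- out$ground_truth$bursts
  mids <- (gt$start_s + gt$end_s)[gt$channel == "left"] / 2
  err <- vapply(apex, function(a) min(abs(a - mids)), numeric(1))
  expect_gt(mean(err <= 0.25 / 25), 0.9)
})

test_that("the 10-40 Hz band-pass shapes the envelope trace as specified", {
  # 5 Hz burst modulation is attenuated relative to 25 Hz modulation
  t <- (0:29999) / fs
  mk <- function(fmod) {
    x <- (0.5 + 0.5 * sin(2 * pi * fmod * t)) * sin(2 * pi * 500 * t)
    new_recording(t, x, numeric(length(t)), fs)
  }
  amp_of <- function(rec) {
    env <- envelope_activity_trace(rec, "left", 0.5, 2.5)
    stats::sd(env$value)
  }
  expect_lt(amp_of(mk(5)), 0.1 * amp_of(mk(25)))
  # zero input gives a zero trace
  z <- new_recording(t, numeric(length(t)), numeric(length(t)), fs)
  expect_equal(max(abs(envelope_activity_trace(z, "left", 0.5, 2.5)$value)), 0)
  # windows shorter than 3 slow cycles are refused
  expect_error(envelope_activity_trace(z, "left", 0.5, 0.7), "3 cycles")
})

test_that("periodicity trace conserves fast modulation the envelope band removes", {
  t <- (0:29999) / fs
  mk <- function(fmod) {
    x <- (0.5 + 0.5 * sin(2 * pi * fmod * t)) * sin(2 * pi * 500 * t)
    new_recording(t, x, numeric(length(t)), fs)
  }
  mod_power <- function(trace, fmod) {
    v <- trace$value - mean(trace$value)
    n <- length(v)
    spec <- Mod(stats::fft(v))[1:(n %/% 2)]
    fgrid <- (0:(n %/% 2 - 1)) * fs / n
    max(spec[abs(fgrid - fmod) < 2])
  }
  p50 <- periodicity_trace(mk(50), "left", 0.5, 2.5)
  p25 <- periodicity_trace(mk(25), "left", 0.5, 2.5)
  # 50 Hz modulation survives within 20% of the 25 Hz gain
  expect_gt(mod_power(p50, 50) / mod_power(p25, 25), 0.8)
  # zero input -> constant ~0 and scaled to [0, ~1]
  z <- new_recording(t, numeric(length(t)), numeric(length(t)), fs)
  expect_lt(max(abs(periodicity_trace(z, "left", 0.5, 2.5)$value)), 1e-9)
  expect_lte(max(p25$value), 1.5)
})

test_that("ridge of a chirped bout tracks the injected trajectory", {
  out <- generate_recording(synth_config(
    duration_s = 3, bout_rate_per_min = 20, freq_trajectory = "increasing",
    noise_sd = 0, seed = 61))
  den <- wavelet_denoise(out$recording)
  e <- extract_episodes(den)$episodes[[1]]
  fr <- episode_frequency_trace(den, e)
  gt <- out$ground_truth$freq_trajectory
  inj <- stats::approx(gt$time_s, gt$freq_hz, xout = fr$time_s, rule = 2)$y
  expect_lt(stats::median(abs(fr$freq_hz - inj)), 2)
  # monotone trend: the smoothed ridge rises by most of the injected span
  sm <- stats::runmed(fr$freq_hz, 21)
  core <- sm[seq(5, length(sm) - 4)]
  expect_gt(stats::cor(core, seq_along(core)), 0.95)
})

test_that("dual-frequency artefact shows as a left-right ridge discrepancy", {
  out <- generate_recording(synth_config(
    duration_s = 3, bout_rate_per_min = 20, freq_trajectory = "continuous",
    noise_sd = 0, artefacts = "dual_frequency", seed = 71))
  den <- wavelet_denoise(out$recording)
  e <- extract_episodes(den)$episodes[[1]]
  fl <- episode_frequency_trace(den, e, "left")
  fr <- episode_frequency_trace(den, e, "right")
  n <- min(length(fl$freq_hz), length(fr$freq_hz))
  expect_gt(stats::median(abs(fl$freq_hz[1:n] - fr$freq_hz[1:n])), 5)
})

test_that("phase and coherence behave per their circular definitions", {
  # identical traces: 0 degrees, coherence exactly 1
  set.seed(8)
  v <- abs(rnorm(5000)) + sin(2 * pi * 25 * (0:4999) / fs)^2
  a <- trace_from_values(v, fs, "left")
  b <- trace_from_values(v, fs, "right")
  ph <- phase_coherence(a, b)
  expect_equal(ph$mean_phase_deg, 0)
  expect_identical(ph$coherence, 1)
  # a trace against itself delayed by half a 25 Hz period: 180 +- 3 deg
  t <- (0:49999) / fs
  burst <- function(tt) (0.5 + 0.5 * sin(2 * pi * 25 * tt))^3
  a <- trace_from_values(burst(t), fs, "left")
  b <- trace_from_values(burst(t - 0.020), fs, "right")
  ph <- phase_coherence(a, b)
  expect_lt(min(abs(ph$mean_phase_deg - 180)), 3)
  expect_gt(ph$coherence, 0.9)
  # unequal windows are refused
  expect_error(phase_coherence(a, trace_from_values(burst(t)[1:100], fs)),
               "unequal")
  # independent noise has low coherence (frozen empirical bound)
  for (s in 1:3) {
    set.seed(s)
    x <- trace_from_values(abs(rnorm(20000)), fs, "left")
    y <- trace_from_values(abs(rnorm(20000)), fs, "right")
    expect_lt(phase_coherence(x, y)$coherence, 0.2)
  }
})

test_that("bout classification follows the trajectory taxonomy", {
  mk_freq <- function(f_of_t, dur = 1, fs_r = 1000) {
    tt <- seq(0, dur, by = 1 / fs_r)
    structure(list(time_s = tt, freq_hz = f_of_t(tt),
                   power = rep(1, length(tt)), band_hz = c(10, 60)),
              class = "frequency_trace")
  }
  up <- classify_bout(mk_freq(function(t) 20 + 20 * t))
  expect_equal(up$label, "increasing")
  expect_true(up$crosses_30hz)
  const <- classify_bout(mk_freq(function(t) rep(25, length(t))))
  expect_equal(const$label, "continuous")
  expect_false(const$crosses_30hz)
  expect_equal(const$mean_freq_hz, 25, tolerance = 1e-6)
  tri <- classify_bout(mk_freq(function(t) 20 + 20 * (1 - abs(2 * t - 1))))
  expect_equal(tri$label, "rise_fall")
  dn <- classify_bout(mk_freq(function(t) 40 - 20 * t))
  expect_equal(dn$label, "decreasing")
  # supplied low coherence overrides the trajectory label
  inc <- classify_bout(mk_freq(function(t) rep(25, length(t))),
                       coherence = 0.1)
  expect_equal(inc$label, "incoherent")
  expect_error(classify_bout(mk_freq(function(t) numeric(0), dur = 0)),
               "empty")
})

test_that("30 Hz bookkeeping does not depend on the smoothing width", {
  out <- generate_recording(synth_config(
    duration_s = 3, bout_rate_per_min = 20, freq_trajectory = "increasing",
    noise_sd = 0.15, seed = 81))
  den <- wavelet_denoise(out$recording)
  e <- extract_episodes(den)$episodes[[1]]
  fr <- episode_frequency_trace(den, e)
  c1 <- classify_bout(fr, rhythm_params(ridge_smooth_s = 0.03))
  c2 <- classify_bout(fr, rhythm_params(ridge_smooth_s = 0.08))
  expect_identical(c1$crosses_30hz, c2$crosses_30hz)
})

test_that("bout summaries aggregate proportions, crossings and penalties", {
  tab <- tibble::tibble(
    group = "a",
    label = c(rep("continuous", 4), rep("increasing", 3),
              rep("rise_fall", 2), "decreasing"),
    crosses_30hz = c(rep(TRUE, 4), rep(FALSE, 6)),
    mean_freq_hz = seq(20, 38, by = 2),
    mean_phase_deg = rep(180, 10),
    coherence = rep(0.9, 10),
    alternation_penalty = rep(0.2, 10),
    simultaneous_penalty = rep(0.1, 10)
  )
  s <- summarize_bouts(tab)
  expect_equal(s$frac_crossing_30hz, 0.4)
  expect_equal(s$prop_continuous + s$prop_increasing + s$prop_decreasing +
                 s$prop_rise_fall + s$prop_incoherent, 1)
  expect_equal(s$alternation_penalty_mean, 0.2)
  expect_equal(s$pooled_phase_deg, 180)

  # optomotor bouts cross the 30 Hz boundary more often than NMDA bouts
  frac_cross <- function(preset) {
    gts <- lapply(1:6, function(s) {
      generate_recording(synth_config(duration_s = 30, preset = preset,
                                      seed = 300 + s))$ground_truth$bouts
    })
    b <- dplyr::bind_rows(gts)
    mean(b$crosses_30hz)
  }
  expect_gt(frac_cross("optomotor"), frac_cross("nmda"))
})
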