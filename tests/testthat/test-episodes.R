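fs <- 10000

test_that("peak detection handles silence and isolated spikes", {
  zr <- new_recording((0:9999) / fs, numeric(10000), numeric(10000), fs)
  tr <- detect_peaks(zr)
  expect_equal(nrow(tr$left), 0)
  expect_equal(nrow(tr$right), 0)

  t <- (0:29999) / fs
  x <- numeric(30000)
  for (s in c(1.000, 1.040)) {
    x <- x + fictiveswim:::spike_waveform(t - s, 1)
  }
  rec <- new_recording(t, x, numeric(30000), fs)
  tr <- detect_peaks(rec)
  expect_equal(nrow(tr$left), 2)
  expect_equal(tr$left$time_s, c(1.000, 1.040), tolerance = 1.5 / fs)
})

test_that("a noiseless burst train yields one peak per spike", {
  # 30 bursts/s for 1 s, one spike per burst
  t <- (0:14999) / fs
  x <- numeric(15000)
  times <- 0.2 + (0:29) / 30
  for (s in times) x <- x + fictiveswim:::spike_waveform(t - s, 1)
  tr <- detect_peaks(new_recording(t, x, numeric(15000), fs))
  expect_equal(nrow(tr$left), 30)
})

test_that("episode clustering applies the 100 ms rule exactly", {
  mk_train <- function(times) tibble::tibble(time_s = times,
                                             amplitude = rep(1, length(times)))
  empty <- mk_train(numeric(0))
  # spikes spanning 80 ms only -> excluded
  out <- cluster_episodes(mk_train(seq(1, 1.08, by = 0.01)), empty)
  expect_length(out$episodes, 0)
  expect_equal(out$n_dropped_short, 1L)
  # two 300 ms clusters separated by 1 s -> exactly two episodes at the
  # first/last spike of each cluster
  c1 <- seq(0.5, 0.8, by = 0.02)
  c2 <- seq(1.8, 2.1, by = 0.02)
  out <- cluster_episodes(mk_train(c(c1, c2)), empty)
  expect_length(out$episodes, 2)
  expect_equal(out$episodes[[1]]$start_s, 0.5)
  expect_equal(out$episodes[[1]]$end_s, 0.8)
  expect_equal(out$episodes[[2]]$start_s, 1.8)
  expect_equal(out$episodes[[2]]$end_s, 2.1)
  # no spikes at all
  out <- cluster_episodes(empty, empty)
  expect_length(out$episodes, 0)
  # every emitted episode satisfies the hard 100 ms invariant
  set.seed(3)
  for (i in 1:20) {
    times <- sort(runif(40, 0, 3))
    out <- cluster_episodes(mk_train(times), empty)
    for (e in out$episodes) expect_gte(e$duration_s, 0.1)
  }
})

test_that("burst segmentation follows the 8 ms gap rule", {
  # 3 spikes at 0, 4, 8 ms then next at 40 ms
  spikes <- tibble::tibble(
    time_s = c(0, 0.004, 0.008, 0.040, 0.044, 0.120, 0.124),
    amplitude = 1, channel = "left"
  )
  ep <- structure(list(start_s = 0, end_s = 0.124, duration_s = 0.124,
                       spikes = spikes, bursts = NULL,
                       params = detection_params()),
                  class = "swim_episode")
  ep <- segment_bursts(ep)
  b <- ep$bursts
  expect_equal(nrow(b), 3)
  expect_equal(b$duration_s[1], 0.008)
  expect_equal(b$spike_count[1], 3L)
  expect_equal(b$within_burst_freq_hz[1], 2 / 0.008)
  # single isolated spike: a zero-duration one-spike burst
  ep1 <- structure(list(start_s = 0, end_s = 0, duration_s = 0,
                        spikes = tibble::tibble(time_s = 0.5, amplitude = 1,
                                                channel = "right"),
                        bursts = NULL, params = detection_params()),
                   class = "swim_episode")
  b1 <- segment_bursts(ep1)$bursts
  expect_equal(b1$spike_count, 1L)
  expect_equal(b1$duration_s, 0)
  expect_true(is.na(b1$within_burst_freq_hz))
})

test_that("detected burst midpoints track the annotation within 3 ms", {
  out <- fixed_freq_recording(25, noise_sd = 0.1, seed = 31, duration_s = 3)
  den <- wavelet_denoise(out$recording)
  eps <- extract_episodes(den)
  expect_length(eps$episodes, 1)
  det <- eps$episodes[[1]]$bursts
  gt <- out$ground_truth$bursts
  hits <- 0
  for (i in seq_len(nrow(gt))) {
    mid_gt <- (gt$start_s[i] + gt$end_s[i]) / 2
    same <- det[det$channel == gt$channel[i], ]
    mid_det <- (same$start_s + same$end_s) / 2
    if (any(abs(mid_det - mid_gt) <= 0.003)) hits <- hits + 1
  }
  expect_gte(hits / nrow(gt), 0.95)
})

test_that("penalty scores follow their defining formulas", {
  expect_equal(alternation_penalty(
    episode_from_sides(c("left", "right", "left", "right", "left", "right"))), 0)
  expect_equal(alternation_penalty(
    episode_from_sides(c("left", "left", "right", "right"))), 0.5)
  for (n in c(2, 5, 8)) {
    expect_equal(alternation_penalty(episode_from_sides(rep("left", n))),
                 (n - 1) / n)
  }
  # interleaved anti-phase bursts never overlap
  ep <- episode_from_sides(rep(c("left", "right"), 4))
  expect_equal(simultaneous_penalty(ep), 0)
  # one exactly coincident left-right pair among 4 bursts -> 2/4
  ep <- episode_from_bursts(
    starts = c(0, 0, 0.10, 0.20), ends = c(0.05, 0.05, 0.15, 0.25),
    channels = c("left", "right", "left", "right")
  )
  expect_equal(simultaneous_penalty(ep), 0.5)
  # a pair overlapping by 50% of each is below the 70% criterion
  ep <- episode_from_bursts(
    starts = c(0, 0.02), ends = c(0.04, 0.06),
    channels = c("left", "right")
  )
  expect_equal(simultaneous_penalty(ep), 0)
  # empty episodes are undefined, not zero
  ep0 <- structure(list(start_s = 0, end_s = 0, duration_s = 0,
                        spikes = tibble::tibble(time_s = numeric(0),
                                                amplitude = numeric(0),
                                                channel = character(0)),
                        bursts = NULL, params = detection_params()),
                   class = "swim_episode")
  ep0 <- segment_bursts(ep0)
  expect_error(alternation_penalty(ep0), "undefined")
  expect_error(simultaneous_penalty(ep0), "undefined")
})

test_that("penalties are invariant to time shifts and side swaps", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    sides <- sample(c("left", "right"), n, replace = TRUE)
    starts <- cumsum(runif(n, 0.01, 0.04))
    ends <- starts + runif(n, 0.005, 0.03)
    ep <- episode_from_bursts(starts, ends, sides)
    ep_shift <- episode_from_bursts(starts + 5, ends + 5, sides)
    swapped <- ifelse(sides == "left", "right", "left")
    ep_swap <- episode_from_bursts(starts, ends, swapped)
    expect_equal(alternation_penalty(ep), alternation_penalty(ep_shift))
    expect_equal(alternation_penalty(ep), alternation_penalty(ep_swap))
    expect_equal(simultaneous_penalty(ep), simultaneous_penalty(ep_shift))
    expect_equal(simultaneous_penalty(ep), simultaneous_penalty(ep_swap))
  }
})

test_that("episode extraction is symmetric in channel labels", {
  out <- generate_recording(synth_config(duration_s = 4, noise_sd = 0.15,
                                         bout_rate_per_min = 20, seed = 77))
  den <- wavelet_denoise(out$recording)
  tr <- detect_peaks(den)
  a <- cluster_episodes(tr$left, tr$right)
  b <- cluster_episodes(tr$right, tr$left)
  expect_equal(length(a$episodes), length(b$episodes))
  for (i in seq_along(a$episodes)) {
    expect_equal(a$episodes[[i]]$start_s, b$episodes[[i]]$start_s)
    expect_equal(a$episodes[[i]]$end_s, b$episodes[[i]]$end_s)
  }
})

test_that("clean anti-phase data scores zero penalties; incoherent data scores higher", {
  out <- fixed_freq_recording(25, noise_sd = 0, seed = 41, duration_s = 3)
  den <- wavelet_denoise(out$recording)
  eps <- extract_episodes(den)
  clean <- penalty_scores(eps$episodes[[1]])
  expect_equal(clean$alternation_penalty, 0)
  expect_equal(clean$simultaneous_penalty, 0)

  inc <- generate_recording(synth_config(duration_s = 4, noise_sd = 0,
                                         bout_rate_per_min = 20,
                                         artefacts = "incoherent", seed = 41))
  den_i <- wavelet_denoise(inc$recording)
  eps_i <- extract_episodes(den_i)
  expect_gt(length(eps_i$episodes), 0)
  pen_i <- dplyr::bind_rows(lapply(eps_i$episodes, penalty_scores))
  expect_gt(mean(pen_i$alternation_penalty), clean$alternation_penalty)
  expect_gt(mean(pen_i$simultaneous_penalty), clean$simultaneous_penalty)
})
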