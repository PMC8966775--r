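make_traces <- function(f, frame_rate = 30) {
  ft <- (seq_len(nrow(f)) - 1) / frame_rate
  structure(list(frame_times_s = ft, f = f, frame_rate_hz = frame_rate,
                 lag_s = NA_real_, kernel_tau_s = NA_real_),
            class = "calcium_traces")
}

test_that("dF/F obeys its definition on constant and step traces", {
  const <- make_traces(matrix(100, 400, 1))
  expect_equal(max(abs(compute_dff(const)$dff)), 0)
  # step from 100 to 150: plateau dF/F = 0.5
  step <- make_traces(matrix(c(rep(100, 200), rep(150, 200)), 400, 1))
  expect_equal(max(compute_dff(step)$dff), 0.5)
  # nonpositive baseline is an error naming the ROI
  bad <- matrix(c(rep(-5, 200), rep(10, 200)), 400, 1)
  colnames(bad) <- "roi_7"
  expect_error(compute_dff(make_traces(bad)), "roi_7")
})

test_that("dF/F is exactly invariant to multiplicative gain", {
  gt <- generate_recording(synth_config(duration_s = 15,
                                        bout_rate_per_min = 12,
                                        seed = 3))$ground_truth
  ca <- generate_calcium(gt, n_rois = 4, lag_s = 0.3, frame_rate_hz = 40,
                         seed = 6)
  d1 <- compute_dff(ca)
  ca$f <- ca$f * 7.3
  d2 <- compute_dff(ca)
  expect_equal(d1$dff, d2$dff)
})

test_that("each ROI shows one transient per bout", {
  gt <- generate_recording(synth_config(duration_s = 20,
                                        bout_rate_per_min = 12,
                                        seed = 13))$ground_truth
  ca <- generate_calcium(gt, n_rois = 3, lag_s = 0.3, frame_rate_hz = 50,
                         noise_sd = 0.005, seed = 2)
  d <- compute_dff(ca)
  for (r in seq_len(ncol(d$dff))) {
    y <- d$dff[, r]
    pk <- pracma::findpeaks(y, minpeakheight = 0.4 * max(y),
                            minpeakdistance = as.integer(0.6 * 50))
    expect_equal(nrow(pk), nrow(gt$bouts))
  }
})

test_that("lag recovery is unbiased to within one frame period", {
  gt <- generate_recording(synth_config(duration_s = 20,
                                        bout_rate_per_min = 15,
                                        seed = 21))$ground_truth
  for (frame_rate in c(30, 100)) {
    for (lag in c(0.1, 0.5)) {
      ca <- generate_calcium(gt, n_rois = 6, lag_s = lag,
                             frame_rate_hz = frame_rate, seed = 5)
      est <- estimate_lag(compute_dff(ca), gt$bouts)
      expect_lt(abs(est$lag_s - lag), 1 / frame_rate)
    }
  }
  # zero lag, noiseless
  ca0 <- generate_calcium(gt, n_rois = 6, lag_s = 0, frame_rate_hz = 60,
                          noise_sd = 0, seed = 5)
  est0 <- estimate_lag(compute_dff(ca0), gt$bouts)
  expect_lt(abs(est0$lag_s), 1 / 60)
  # onset-difference method lands in the same neighbourhood
  ca3 <- generate_calcium(gt, n_rois = 6, lag_s = 0.3, frame_rate_hz = 60,
                          noise_sd = 0, seed = 5)
  on <- estimate_lag(compute_dff(ca3), gt$bouts, method = "onset_diff")
  expect_lt(abs(on$lag_s - 0.3), 0.15)
})

test_that("lag estimation refuses fewer than 3 bouts", {
  gt <- generate_recording(synth_config(duration_s = 20,
                                        bout_rate_per_min = 15,
                                        seed = 21))$ground_truth
  ca <- generate_calcium(gt, n_rois = 2, lag_s = 0.3, frame_rate_hz = 30,
                         seed = 1)
  expect_error(estimate_lag(compute_dff(ca), gt$bouts[1:2, ]), "3 bouts")
})

test_that("alignment scores driven ROIs high and silent ROIs near zero", {
  gt <- generate_recording(synth_config(duration_s = 20,
                                        bout_rate_per_min = 15,
                                        seed = 21))$ground_truth
  ca <- generate_calcium(gt, n_rois = 4, lag_s = 0.3, frame_rate_hz = 30,
                         seed = 4)
  # append one silent ROI (noise around baseline)
  set.seed(99)
  silent <- 100 + rnorm(nrow(ca$f))
  ca$f <- cbind(ca$f, roi_silent = silent)
  d <- compute_dff(ca)
  lag <- estimate_lag(d, gt$bouts)
  al <- align_and_export(d, gt$bouts, lag)
  driven <- al$per_roi$correlation[al$per_roi$roi != "roi_silent"]
  expect_true(all(driven > 0.8))
  expect_lt(abs(al$per_roi$correlation[al$per_roi$roi == "roi_silent"]), 0.2)
  # empty episode list: warning and empty table
  expect_warning(empty <- align_and_export(d, gt$bouts[0, ], lag),
                 "no episodes")
  expect_equal(nrow(empty$per_episode), 0)
})
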