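#' Generate synthetic per-ROI calcium fluorescence traces
#'
#' Emulates somatic GCaMP recordings of motor neurons during fictive
#' swimming: each ROI's fluorescence is a baseline plus the bout-activity
#' indicator convolved with a single-exponential decay kernel, shifted by a
#' fixed calcium-onset lag, sampled on the imaging frame grid, with additive
#' Gaussian noise. The injected lag is recorded in the returned object (and
#' in the annotation) so lag-estimation accuracy can be scored.
#'
#' @param ground_truth a [new_ground_truth()] providing bout intervals and
#'   recording duration.
#' @param n_rois number of ROIs (0 gives an empty trace set with valid
#'   frame times).
#' @param lag_s nonnegative calcium-after-ephys lag in seconds (default
#'   0.311, the scale of published GCaMP5G onset lags).
#' @param frame_rate_hz imaging frame rate; must not exceed the recording
#'   sampling rate (30-100 Hz is the usual range).
#' @param kernel_tau_s decay time constant of the calcium kernel (s); must
#'   be positive.
#' @param noise_sd SD of additive fluorescence noise, in baseline units.
#' @param baseline_f mean baseline fluorescence (arbitrary units).
#' @param seed integer seed.
#' @return object of class `calcium_traces`: list with `frame_times_s`,
#'   `f` (frames x ROIs fluorescence matrix), `frame_rate_hz`, `lag_s`,
#'   `kernel_tau_s`.
#' @examples
#' gt <- generate_recording(synth_config(duration_s = 6, seed = 2))$ground_truth
#' ca <- generate_calcium(gt, n_rois = 4, lag_s = 0.3, frame_rate_hz = 30)
#' dim(ca$f)
#' @export
generate_calcium <- function(ground_truth, n_rois = 12L, lag_s = 0.311,
                             frame_rate_hz = 30, kernel_tau_s = 0.3,
                             noise_sd = 0.02, baseline_f = 100,
                             seed = 1L) {
  stopifnot(inherits(ground_truth, "swim_ground_truth"),
            n_rois >= 0, lag_s >= 0, frame_rate_hz > 0, baseline_f > 0)
  if (kernel_tau_s <= 0) stop("kernel_tau_s must be positive")
  if (frame_rate_hz > ground_truth$sampling_rate_hz) {
    stop("frame_rate_hz exceeds the recording sampling rate")
  }
  with_local_seed(seed, {
    dur <- ground_truth$duration_s
    fs_fine <- 1000 # internal grid for the convolution (Hz)
    t_fine <- seq(0, dur, by = 1 / fs_fine)
    ind <- bout_indicator(ground_truth$bouts, t_fine)
    # causal single-exponential kernel, unit peak
    kt <- seq(0, 6 * kernel_tau_s, by = 1 / fs_fine)
    kern <- exp(-kt / kernel_tau_s)
    conv <- stats::convolve(ind, rev(kern), type = "open")[seq_along(t_fine)]
    conv <- conv / (fs_fine * kernel_tau_s) # ~1 at sustained activity
    frame_times <- seq(0, dur, by = 1 / frame_rate_hz)
    f <- matrix(numeric(0), nrow = length(frame_times), ncol = 0)
    if (n_rois > 0) {
      gains <- stats::runif(n_rois, 0.5, 1.5) # peak dF/F per ROI
      f <- vapply(seq_len(n_rois), function(r) {
        sig <- stats::approx(t_fine + lag_s, conv, xout = frame_times,
                             yleft = 0, yright = 0)$y
        b0 <- baseline_f * stats::runif(1, 0.8, 1.2)
        b0 * (1 + gains[r] * sig) +
          if (noise_sd > 0) stats::rnorm(length(frame_times),
                                         0, noise_sd * baseline_f)
          else 0
      }, numeric(length(frame_times)))
      colnames(f) <- paste0("roi_", seq_len(n_rois))
    }
    structure(
      list(frame_times_s = frame_times, f = f,
           frame_rate_hz = frame_rate_hz, lag_s = lag_s,
           kernel_tau_s = kernel_tau_s),
      class = "calcium_traces"
    )
  })
}

#' @export
print.calcium_traces <- function(x, ...) {
  cat(sprintf("<calcium_traces> %d ROIs x %d frames at %g Hz (lag %g s)\n",
              ncol(x$f), length(x$frame_times_s), x$frame_rate_hz, x$lag_s))
  invisible(x)
}

# 0/1 bout-activity indicator sampled on a time grid.
bout_indicator <- function(bouts, time_s) {
  ind <- numeric(length(time_s))
  for (i in seq_len(nrow(bouts))) {
    ind[time_s >= bouts$start_s[i] & time_s <= bouts$end_s[i]] <- 1
  }
  ind
}
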