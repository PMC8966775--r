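#' Denoising parameters
#'
#' Settings for wavelet denoising and for the conventional band-pass
#' baseline it is compared against.
#'
#' `threshold_rule = "sd_multiple"` (the default) thresholds coefficient
#' magnitudes at `threshold_k` times the noise scale \eqn{\sigma} estimated
#' by the median absolute deviation of the finest-scale coefficients; the
#' default `threshold_k = 3.5` preserves low-amplitude spikes while keeping
#' surviving noise excursions sparse enough that they cannot chain into
#' spurious episode clusters downstream. `"universal"` uses \eqn{\sigma \sqrt{2 \ln N}}; it yields
#' the cleanest baseline but, because a one-cycle extracellular transient
#' has no matched-filter gain under a Morlet, it suppresses spikes below
#' roughly five noise SDs and therefore defeats the method's purpose of
#' preserving low-amplitude units.
#'
#' @param wavelet wavelet family; only `"morlet"` is implemented (the
#'   analytic Morlet of [morlet_cwt()]).
#' @param threshold_rule `"universal"` or `"sd_multiple"`.
#' @param threshold_k multiplier for `"sd_multiple"`.
#' @param bandpass_low_hz,bandpass_high_hz corner frequencies of the
#'   conventional band-pass baseline (defaults 100 and 1000 Hz).
#' @param denoise_low_hz lower edge of the wavelet analysis band (Hz); the
#'   upper edge is half the Nyquist frequency.
#' @param voices_per_octave density of the log-spaced scale grid.
#' @return list of class `denoise_params`.
#' @export
denoise_params <- function(wavelet = "morlet",
                           threshold_rule = c("sd_multiple", "universal"),
                           threshold_k = 3.5,
                           bandpass_low_hz = 100,
                           bandpass_high_hz = 1000,
                           denoise_low_hz = 50,
                           voices_per_octave = 16L) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(identical(wavelet, "morlet"), threshold_k > 0,
            bandpass_low_hz > 0, bandpass_high_hz > bandpass_low_hz,
            denoise_low_hz > 0, voices_per_octave >= 4)
  structure(
    list(wavelet = wavelet, threshold_rule = threshold_rule,
         threshold_k = threshold_k, bandpass_low_hz = bandpass_low_hz,
         bandpass_high_hz = bandpass_high_hz,
         denoise_low_hz = denoise_low_hz,
         voices_per_octave = as.integer(voices_per_octave)),
    class = "denoise_params"
  )
}

#' Wavelet denoising of a dual-channel recording
#'
#' Denoises each channel by analytic Morlet CWT over a log-spaced scale
#' grid spanning `denoise_low_hz` to one quarter of the sampling rate,
#' hard-thresholding of coefficient magnitudes, and single-integral (delta)
#' reconstruction with an analytically computed in-band gain constant.
#' Baseline segments come out near zero while spike transients keep their
#' timing, which is what makes subsequent threshold-free episode
#' clustering possible.
#'
#' The scale grid and thresholding operate per channel; with the
#' Torrence-Compo normalization white noise has flat expected coefficient
#' power across scales, so a single noise estimate (MAD of the finest-scale
#' coefficients) sets the threshold everywhere.
#'
#' @param recording a [new_recording()] with finite samples, at least 64
#'   samples long.
#' @param params a [denoise_params()].
#' @return denoised recording (same class, length and sampling rate).
#' @examples
#' out <- generate_recording(synth_config(duration_s = 4, seed = 1))
#' den <- wavelet_denoise(out$recording)
#' @export
wavelet_denoise <- function(recording, params = denoise_params()) {
  stopifnot(inherits(recording, "swim_recording"),
            inherits(params, "denoise_params"))
  n <- length(recording$time_s)
  if (n < 64L) stop("signal too short to denoise (need >= 64 samples)")
  if (!all(is.finite(recording$left_v)) || !all(is.finite(recording$right_v))) {
    stop("recording contains non-finite samples")
  }
  fs <- recording$sampling_rate_hz
  f_hi <- fs / 4
  if (params$denoise_low_hz >= f_hi) {
    stop("denoise_low_hz must be below a quarter of the sampling rate")
  }
  freqs <- cwt_freq_grid(params$denoise_low_hz, f_hi, params$voices_per_octave)
  with_channels(
    recording,
    denoise_channel(recording$left_v, fs, freqs, params),
    denoise_channel(recording$right_v, fs, freqs, params)
  )
}

# Streaming per-scale denoise: never holds the full coefficient matrix.
denoise_channel <- function(x, fs, freqs, params) {
  n <- length(x)
  scales <- morlet_scale(freqs)
  pre <- cwt_prepare(x, fs, max(scales))
  # finest scale first: it sets the noise estimate for all scales
  ord <- order(scales)
  acc <- numeric(n)
  thr <- NULL
  for (j in ord) {
    w <- cwt_one_scale(pre, scales[j], 6)
    if (is.null(thr)) {
      sigma <- mad_sd(Re(w))
      thr <- if (params$threshold_rule == "universal") {
        sigma * sqrt(2 * log(n))
      } else {
        sigma * params$threshold_k
      }
    }
    w[Mod(w) < thr] <- 0i
    acc <- acc + Re(w) / sqrt(scales[j])
  }
  acc * cwt_recon_factor(scales, 1 / fs)
}

#' Conventional band-pass baseline
#'
#' Zero-phase (forward-backward Butterworth) band-pass between
#' `bandpass_low_hz` and `bandpass_high_hz`, the conventional treatment of
#' extracellular ventral-root recordings that wavelet denoising is
#' benchmarked against.
#'
#' @inheritParams wavelet_denoise
#' @return filtered recording (same class, length and sampling rate).
#' @export
bandpass_baseline <- function(recording, params = denoise_params()) {
  stopifnot(inherits(recording, "swim_recording"),
            inherits(params, "denoise_params"))
  if (!all(is.finite(recording$left_v)) || !all(is.finite(recording$right_v))) {
    stop("recording contains non-finite samples")
  }
  fs <- recording$sampling_rate_hz
  if (params$bandpass_high_hz >= fs / 2) {
    stop("bandpass_high_hz must be below the Nyquist frequency (", fs / 2, " Hz)")
  }
  with_channels(
    recording,
    zero_phase_bandpass(recording$left_v, fs, params$bandpass_low_hz,
                        params$bandpass_high_hz),
    zero_phase_bandpass(recording$right_v, fs, params$bandpass_low_hz,
                        params$bandpass_high_hz)
  )
}
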