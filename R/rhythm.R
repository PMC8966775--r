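#' Activity-trace and rhythm-analysis parameters
#'
#' @param envelope_band_hz band of the burst-timing envelope trace
#'   (default 10-40 Hz, the conventional band for alternation analysis).
#' @param analysis_band_hz band of the wavelet frequency analysis
#'   (default 10-60 Hz, covering the larval tail-beat output range).
#' @param envelope_method `"peak_spline"` (cubic interpolation through
#'   detected local maxima — an upper envelope in the literal sense) or
#'   `"analytic"` (magnitude of the analytic signal).
#' @param periodicity_lowpass_hz cutoff of the zero-phase low-pass that
#'   smooths the rectified trace into the periodicity trace (default
#'   90 Hz): one smooth bump per burst, under 10% amplitude distortion
#'   across the whole 10-60 Hz tail-beat band, and ~70 dB suppression of
#'   the ~250 Hz within-burst spike structure that would otherwise
#'   dominate the analytic phase.
#' @param ridge_smooth_s running-median half-width applied to the CWT ridge
#'   before bout classification (default 20 ms; the trend fit is already a
#'   power-weighted least squares over the whole bout, so only light
#'   smoothing is needed and heavier widths flatten short interior peaks).
#' @param ridge_pad_s quiescent margin included around an episode when its
#'   ridge is extracted (default 0.15 s); letting the wavelet see the bout
#'   switch off keeps the ridge honest inside the low-frequency cone of
#'   influence at the bout edges. The ridge itself is then restricted to
#'   the episode window.
#' @param slope_thresh_hz_per_s trend slope below which a bout is
#'   `continuous` (default 5 Hz/s).
#' @param rise_fall_edge_hz minimum drop from an interior ridge maximum to
#'   both edges for a `rise_fall` label (default 5 Hz).
#' @param rise_fall_margin_s minimum distance of the ridge maximum from
#'   both bout edges (default 0.1 s).
#' @param incoherent_coherence maximal left-right coherence below which a
#'   bout is flagged `incoherent` (default 0.3).
#' @param mean_freq_weighting `"power"` (default) or `"unweighted"` mean of
#'   the ridge.
#' @return list of class `rhythm_params`.
#' @export
rhythm_params <- function(envelope_band_hz = c(10, 40),
                          analysis_band_hz = c(10, 60),
                          envelope_method = c("peak_spline", "analytic"),
                          periodicity_lowpass_hz = 90,
                          ridge_smooth_s = 0.02,
                          ridge_pad_s = 0.15,
                          slope_thresh_hz_per_s = 5,
                          rise_fall_edge_hz = 5,
                          rise_fall_margin_s = 0.1,
                          incoherent_coherence = 0.3,
                          mean_freq_weighting = c("power", "unweighted")) {
  envelope_method <- match.arg(envelope_method)
  mean_freq_weighting <- match.arg(mean_freq_weighting)
  stopifnot(length(envelope_band_hz) == 2L, envelope_band_hz[1] > 0,
            diff(envelope_band_hz) > 0, length(analysis_band_hz) == 2L,
            analysis_band_hz[1] > 0, diff(analysis_band_hz) > 0,
            periodicity_lowpass_hz > 0, slope_thresh_hz_per_s > 0)
  structure(
    list(envelope_band_hz = envelope_band_hz,
         analysis_band_hz = analysis_band_hz,
         envelope_method = envelope_method,
         periodicity_lowpass_hz = periodicity_lowpass_hz,
         ridge_smooth_s = ridge_smooth_s, ridge_pad_s = ridge_pad_s,
         slope_thresh_hz_per_s = slope_thresh_hz_per_s,
         rise_fall_edge_hz = rise_fall_edge_hz,
         rise_fall_margin_s = rise_fall_margin_s,
         incoherent_coherence = incoherent_coherence,
         mean_freq_weighting = mean_freq_weighting),
    class = "rhythm_params"
  )
}

new_activity_trace <- function(time_s, value, kind, channel, fs) {
  structure(list(time_s = time_s, value = value, kind = kind,
                 channel = channel, sampling_rate_hz = fs),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace:%s> channel %s, %.3f-%.3f s (%d samples)\n",
              x$kind, x$channel, min(x$time_s), max(x$time_s),
              length(x$time_s)))
  invisible(x)
}

# Extract one channel's denoised samples inside an episode window.
episode_window <- function(denoised, channel, start_s, end_s) {
  i <- which(denoised$time_s >= start_s & denoised$time_s <= end_s)
  list(time_s = denoised$time_s[i], x = channel_of(denoised, channel)[i],
       fs = denoised$sampling_rate_hz)
}

#' Band-passed envelope activity trace
#'
#' Upper envelope of the denoised window (cubic interpolation through the
#' local maxima of the rectified trace, or the analytic-signal magnitude),
#' then zero-phase band-passed to `envelope_band_hz` (default 10-40 Hz).
#' Apexes of the result align with burst activity and troughs with
#' inter-burst periods, which is what makes it suitable for burst timing
#' and alternation analysis — and unsuitable for frequency analysis, since
#' the band-pass removes part of the tail-beat output range.
#'
#' @param denoised a denoised [new_recording()].
#' @param channel `"left"` or `"right"`.
#' @param start_s,end_s episode window; must span at least 3 cycles of the
#'   envelope band's lower edge.
#' @param params a [rhythm_params()].
#' @return `activity_trace` of kind `bandpassed_envelope`.
#' @export
envelope_activity_trace <- function(denoised, channel, start_s, end_s,
                                    params = rhythm_params()) {
  w <- episode_window(denoised, channel, start_s, end_s)
  min_dur <- 3 / params$envelope_band_hz[1]
  if ((end_s - start_s) < min_dur) {
    stop("window shorter than 3 cycles at ", params$envelope_band_hz[1],
         " Hz (need >= ", signif(min_dur, 3), " s)")
  }
  env <- upper_envelope(w$x, w$fs, params$envelope_method)
  bp <- zero_phase_bandpass(env, w$fs, params$envelope_band_hz[1],
                            params$envelope_band_hz[2])
  new_activity_trace(w$time_s, bp, "bandpassed_envelope", channel, w$fs)
}

# Upper envelope of a rectified trace.
upper_envelope <- function(x, fs, method = "peak_spline") {
  r <- abs(x)
  if (all(r == 0)) return(r)
  if (method == "analytic") return(Mod(analytic_signal(x)))
  pk <- pracma::findpeaks(r, minpeakheight = 1e-3 * max(r),
                          minpeakdistance = max(1L, as.integer(fs * 5e-4)))
  if (is.null(pk) || nrow(pk) < 3L) return(r)
  idx <- sort(pk[, 2])
  # anchor the ends so the spline does not extrapolate wildly
  idx <- unique(c(1L, idx, length(r)))
  sf <- stats::splinefun(idx, r[idx], method = "natural")
  env <- sf(seq_along(r))
  pmax(env, 0)
}

#' Periodicity activity trace
#'
#' Rectified-amplitude trace smoothed by a zero-phase low-pass well above
#' the tail-beat band and scaled to approximately \[0, 1\]: high during
#' neural activity, low in quiescence, one smooth bump per burst. No
#' band-selective filtering touches the 10-60 Hz range itself, so
#' modulation anywhere in the tail-beat band is conserved (gain distortion
#' under 10% across the band with the 90 Hz default cutoff); this is the
#' trace used for phase-shift analysis and time-frequency extraction.
#'
#' @inheritParams envelope_activity_trace
#' @return `activity_trace` of kind `periodicity`.
#' @export
periodicity_trace <- function(denoised, channel, start_s, end_s,
                              params = rhythm_params()) {
  w <- episode_window(denoised, channel, start_s, end_s)
  min_dur <- 3 / params$envelope_band_hz[1]
  if ((end_s - start_s) < min_dur) {
    stop("window shorter than 3 cycles at ", params$envelope_band_hz[1],
         " Hz (need >= ", signif(min_dur, 3), " s)")
  }
  bf <- signal::butter(4, params$periodicity_lowpass_hz / (w$fs / 2),
                       type = "low")
  sm <- pmax(as.numeric(signal::filtfilt(bf, abs(w$x))), 0)
  top <- stats::quantile(sm, 0.99, names = FALSE)
  val <- if (top > 0) pmin(sm / top, 1.5) else sm
  new_activity_trace(w$time_s, val, "periodicity", channel, w$fs)
}

#' Instantaneous tail-beat frequency by CWT ridge extraction
#'
#' Morlet CWT of the mean-removed periodicity trace over the analysis band
#' (default 10-60 Hz); the ridge is the frequency of maximal power at each
#' time point. The trace is decimated internally to ~1 kHz (the band's
#' content is far below that) to keep the transform cheap at long
#' recordings; ridge and power are returned on the decimated grid.
#'
#' @param trace an `activity_trace` of kind `periodicity`.
#' @param params a [rhythm_params()].
#' @param freq_step_hz spacing of the analysis frequency grid (default
#'   0.25 Hz).
#' @return `frequency_trace`: list with `time_s`, `freq_hz` (ridge),
#'   `power`, `band_hz`.
#' @export
cwt_frequency <- function(trace, params = rhythm_params(),
                          freq_step_hz = 0.25) {
  stopifnot(inherits(trace, "activity_trace"))
  if (trace$kind != "periodicity") {
    stop("cwt_frequency expects a periodicity-kind trace")
  }
  band <- params$analysis_band_hz
  x <- trace$value
  fs <- trace$sampling_rate_hz
  dec <- max(1L, as.integer(floor(fs / 1000)))
  x <- x[seq(1L, length(x), by = dec)]
  tt <- trace$time_s[seq(1L, length(trace$value), by = dec)]
  fs <- fs / dec
  if (length(x) < fs / band[1]) {
    stop("trace too short for the lowest analysis frequency (", band[1], " Hz)")
  }
  freqs <- seq(band[1], band[2], by = freq_step_hz)
  cw <- morlet_cwt(x - mean(x), fs, freqs)
  pw <- Mod(cw$coef)^2
  ridge_i <- max.col(pw, ties.method = "first")
  structure(
    list(time_s = tt, freq_hz = freqs[ridge_i],
         power = pw[cbind(seq_along(ridge_i), ridge_i)], band_hz = band),
    class = "frequency_trace"
  )
}

#' @export
print.frequency_trace <- function(x, ...) {
  cat(sprintf("<frequency_trace> %.3f-%.3f s, ridge %.1f-%.1f Hz\n",
              min(x$time_s), max(x$time_s), min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

#' Left-right phase shift and coherence
#'
#' Instantaneous phase of each mean-removed periodicity trace via the
#' analytic signal; the per-sample left-minus-right phase differences are
#' wrapped to \[0, 360) and summarized by their circular mean and mean
#' resultant length. Because instantaneous phase is only well defined for
#' narrow-band signals, both traces are first confined to a band around
#' their common dominant tail-beat frequency (0.6-1.6 times the left
#' trace's spectral peak in the analysis band) by a zero-phase filter; this
#' removes the burst-shape harmonics that would otherwise bias the phase
#' difference. Identical traces are compared directly and give 0 degrees
#' at coherence exactly 1. 180 degrees with coherence near 1 is perfect
#' anti-phase alternation; identical traces give 0 degrees at coherence
#' exactly 1. This is the quantity drawn in polar plots: resultant angle =
#' phase shift, resultant length = coherence.
#'
#' @param left,right `activity_trace`s of kind `periodicity` over the same
#'   window.
#' @return `phase_summary`: list with `mean_phase_deg` in \[0, 360),
#'   `coherence` in \[0, 1\], `n_samples`, `n_cycles` (window duration times
#'   median ridge-free cycle estimate from the phase slope).
#' @export
phase_coherence <- function(left, right) {
  stopifnot(inherits(left, "activity_trace"), inherits(right, "activity_trace"))
  if (left$kind != "periodicity" || right$kind != "periodicity") {
    stop("phase_coherence expects periodicity-kind traces")
  }
  if (length(left$value) != length(right$value)) {
    stop("left and right windows have unequal length")
  }
  params <- rhythm_params()
  fs <- left$sampling_rate_hz
  xl <- left$value - mean(left$value)
  xr <- right$value - mean(right$value)
  if (!isTRUE(all.equal(xl, xr)) && stats::sd(xl) > 0) {
    f0 <- dominant_frequency(xl, fs, params$analysis_band_hz)
    if (is.finite(f0)) {
      lo <- max(0.6 * f0, 1)
      hi <- min(1.6 * f0, 0.45 * fs)
      xl <- zero_phase_bandpass(xl, fs, lo, hi)
      xr <- zero_phase_bandpass(xr, fs, lo, hi)
    }
  }
  al <- analytic_signal(xl)
  ar <- analytic_signal(xr)
  dphi <- wrap_deg((Arg(al) - Arg(ar)) * 180 / pi)
  s <- circ_summary(dphi)
  # cycles traversed: total unwrapped phase advance of the left trace
  n_cycles <- abs(sum(diff(Arg(al)) %% (2 * pi) -
                        2 * pi * (diff(Arg(al)) %% (2 * pi) > pi))) / (2 * pi)
  structure(
    list(mean_phase_deg = s$mean_deg, coherence = s$resultant,
         n_samples = length(dphi), n_cycles = n_cycles),
    class = "phase_summary"
  )
}

# Spectral peak (Hz) of a mean-removed trace within a band.
dominant_frequency <- function(x, fs, band_hz) {
  n <- length(x)
  if (n < 16L) return(NA_real_)
  X <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]
  fgrid <- (0:(n %/% 2)) * fs / n
  inb <- fgrid >= band_hz[1] & fgrid <= band_hz[2]
  if (!any(inb)) return(NA_real_)
  fgrid[inb][which.max(X[inb])]
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> %.1f deg, coherence %.3f (%d samples)\n",
              x$mean_phase_deg, x$coherence, x$n_samples))
  invisible(x)
}

#' Classify a bout by its frequency trajectory
#'
#' Labels the bout `increasing`, `decreasing`, `continuous` or `rise_fall`
#' from its (median-smoothed, power-weighted) CWT ridge: `rise_fall` when
#' the ridge maximum is interior (at least `rise_fall_margin_s` from both
#' edges) and both edge values sit at least `rise_fall_edge_hz` below it;
#' otherwise by the sign of the power-weighted least-squares slope, with
#' magnitudes below `slope_thresh_hz_per_s` labelled `continuous`. A bout
#' whose left-right coherence is below `incoherent_coherence` is labelled
#' `incoherent` when a coherence is supplied. The 30 Hz bookkeeping is
#' exact: `crosses_30hz` is true iff the smoothed ridge has values on both
#' sides of 30 Hz.
#'
#' @param freq a `frequency_trace` from [cwt_frequency()].
#' @param params a [rhythm_params()].
#' @param coherence optional left-right coherence of the bout; `NA` skips
#'   the incoherent rule.
#' @return `bout_class`: list with `label`, `crosses_30hz`, `mean_freq_hz`,
#'   `slope_hz_per_s`.
#' @export
classify_bout <- function(freq, params = rhythm_params(), coherence = NA_real_) {
  stopifnot(inherits(freq, "frequency_trace"))
  if (!length(freq$freq_hz)) stop("empty frequency trace")
  tt <- freq$time_s - freq$time_s[1]
  f <- freq$freq_hz
  wpow <- freq$power / max(freq$power)
  # trim the cone-of-influence edges where the ridge is biased, when the
  # bout is long enough to afford it
  dur <- max(tt)
  trim <- min(0.075, dur / 8)
  keep <- tt >= trim & tt <= dur - trim
  tt <- tt[keep]; f <- f[keep]; wpow <- wpow[keep]
  # median-filter width scales down for short bouts so a brief interior
  # peak is not flattened away
  f_sm <- smooth_ridge(f, stats::median(diff(tt)),
                       min(params$ridge_smooth_s, dur / 10))
  mean_freq <- switch(params$mean_freq_weighting,
    power = sum(wpow * f_sm) / sum(wpow),
    unweighted = mean(f_sm)
  )
  crosses <- min(f_sm) < 30 && max(f_sm) > 30
  label <- if (!is.na(coherence) && coherence < params$incoherent_coherence) {
    "incoherent"
  } else {
    classify_trajectory(tt, f_sm, wpow, params)
  }
  fit <- stats::lm(f_sm ~ tt, weights = wpow)
  structure(
    list(label = label, crosses_30hz = crosses, mean_freq_hz = mean_freq,
         slope_hz_per_s = unname(stats::coef(fit)[2])),
    class = "bout_class"
  )
}

smooth_ridge <- function(f, dt, half_width_s) {
  if (length(f) < 5L || half_width_s <= 0) return(f)
  k <- max(1L, as.integer(round(half_width_s / dt)))
  stats::runmed(f, k = min(2L * k + 1L, length(f) - (1 - length(f) %% 2)))
}

classify_trajectory <- function(tt, f_sm, wpow, params) {
  dur <- max(tt) - min(tt)
  imax <- which.max(f_sm)
  interior <- tt[imax] - min(tt) >= params$rise_fall_margin_s &&
    max(tt) - tt[imax] >= params$rise_fall_margin_s
  edges_low <- (f_sm[imax] - f_sm[1] >= params$rise_fall_edge_hz) &&
    (f_sm[imax] - f_sm[length(f_sm)] >= params$rise_fall_edge_hz)
  if (interior && edges_low) return("rise_fall")
  slope <- unname(stats::coef(stats::lm(f_sm ~ tt, weights = wpow))[2])
  if (abs(slope) < params$slope_thresh_hz_per_s) return("continuous")
  if (slope > 0) "increasing" else "decreasing"
}

#' @export
print.bout_class <- function(x, ...) {
  cat(sprintf("<bout_class> %s, mean %.1f Hz, crosses 30 Hz: %s\n",
              x$label, x$mean_freq_hz, x$crosses_30hz))
  invisible(x)
}

#' Frequency trace of one episode, with quiescent padding
#'
#' Extracts the CWT ridge of an episode from a periodicity trace computed
#' over the episode window padded by `ridge_pad_s` of surrounding
#' quiescence, then restricts ridge and power to the episode itself. The
#' padding matters at the bout edges: without it the wavelet's cone of
#' influence at low tail-beat frequencies (roughly ±90 ms at 15 Hz) drags
#' the edge ridge toward the bout interior.
#'
#' @param denoised a denoised [new_recording()].
#' @param episode a `swim_episode`.
#' @param channel channel to analyse (default left).
#' @param params a [rhythm_params()].
#' @return a `frequency_trace` covering the episode window.
#' @export
episode_frequency_trace <- function(denoised, episode, channel = "left",
                                    params = rhythm_params()) {
  stopifnot(inherits(episode, "swim_episode"))
  t0 <- max(min(denoised$time_s), episode$start_s - params$ridge_pad_s)
  t1 <- min(max(denoised$time_s), episode$end_s + params$ridge_pad_s)
  tr <- periodicity_trace(denoised, channel, t0, t1, params)
  fr <- cwt_frequency(tr, params)
  keep <- fr$time_s >= episode$start_s & fr$time_s <= episode$end_s
  fr$time_s <- fr$time_s[keep]
  fr$freq_hz <- fr$freq_hz[keep]
  fr$power <- fr$power[keep]
  fr
}

#' Per-episode rhythm analysis
#'
#' Runs periodicity traces, ridge extraction, phase/coherence and bout
#' classification for each episode of a denoised recording.
#'
#' @param denoised a denoised [new_recording()].
#' @param eplist an `episode_list` from [extract_episodes()].
#' @param params a [rhythm_params()].
#' @return tibble with one row per analysable episode: episode_id, label,
#'   crosses_30hz, mean_freq_hz, mean_phase_deg, coherence, duration_s.
#'   Episodes shorter than the minimum analysis window are skipped.
#' @export
analyze_rhythm <- function(denoised, eplist, params = rhythm_params()) {
  stopifnot(inherits(eplist, "episode_list"))
  rows <- list()
  for (i in seq_along(eplist$episodes)) {
    e <- eplist$episodes[[i]]
    min_dur <- 3 / params$envelope_band_hz[1]
    if (e$duration_s < min_dur) next
    pl <- periodicity_trace(denoised, "left", e$start_s, e$end_s, params)
    pr <- periodicity_trace(denoised, "right", e$start_s, e$end_s, params)
    ph <- phase_coherence(pl, pr)
    fr <- episode_frequency_trace(denoised, e, "left", params)
    bc <- classify_bout(fr, params, coherence = ph$coherence)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      episode_id = i, label = bc$label, crosses_30hz = bc$crosses_30hz,
      mean_freq_hz = bc$mean_freq_hz, mean_phase_deg = ph$mean_phase_deg,
      coherence = ph$coherence, duration_s = e$duration_s
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(
      episode_id = integer(0), label = character(0), crosses_30hz = logical(0),
      mean_freq_hz = numeric(0), mean_phase_deg = numeric(0),
      coherence = numeric(0), duration_s = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Summarize bouts per group
#'
#' Aggregates per-bout classifications, penalties and phase summaries the
#' way treatment groups are compared: bout-type proportions, fraction of
#' bouts crossing the 30 Hz speed-module boundary, penalty means and SDs,
#' and the pooled circular phase/coherence.
#'
#' @param bout_table tibble with columns `label`, `crosses_30hz`,
#'   `mean_freq_hz`, `mean_phase_deg`, `coherence` and (optionally)
#'   `alternation_penalty`, `simultaneous_penalty`, plus a grouping column.
#' @param group_by name of the grouping column (default `"group"`); groups
#'   with zero bouts are omitted.
#' @return tibble with one row per group and nested proportions.
#' @export
summarize_bouts <- function(bout_table, group_by = "group") {
  stopifnot(nrow(bout_table) >= 1L, group_by %in% names(bout_table))
  has_pen <- all(c("alternation_penalty", "simultaneous_penalty") %in%
                   names(bout_table))
  bout_table |>
    dplyr::group_by(.data[[group_by]]) |>
    dplyr::summarise(
      n_bouts = dplyr::n(),
      prop_increasing = mean(.data$label == "increasing"),
      prop_decreasing = mean(.data$label == "decreasing"),
      prop_continuous = mean(.data$label == "continuous"),
      prop_rise_fall = mean(.data$label == "rise_fall"),
      prop_incoherent = mean(.data$label == "incoherent"),
      frac_crossing_30hz = mean(.data$crosses_30hz),
      mean_freq_hz = mean(.data$mean_freq_hz),
      alternation_penalty_mean = if (has_pen) mean(.data$alternation_penalty) else NA_real_,
      alternation_penalty_sd = if (has_pen) stats::sd(.data$alternation_penalty) else NA_real_,
      simultaneous_penalty_mean = if (has_pen) mean(.data$simultaneous_penalty) else NA_real_,
      simultaneous_penalty_sd = if (has_pen) stats::sd(.data$simultaneous_penalty) else NA_real_,
      pooled_phase_deg = circ_summary(.data$mean_phase_deg,
                                      weights = .data$coherence)$mean_deg,
      pooled_coherence = circ_summary(.data$mean_phase_deg,
                                      weights = .data$coherence)$resultant,
      .groups = "drop"
    )
}
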