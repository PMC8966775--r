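#' Baseline-normalized fluorescence (dF/F)
#'
#' Computes per-ROI dF/F = (F - F0) / F0 with a rolling low-percentile
#' baseline F0 (default: 8th percentile over a 10 s centred window), the
#' usual guard against slow drift and against activity inflating the
#' baseline. dF/F is exactly invariant to multiplicative gain on the raw
#' trace, because the percentile baseline scales with the trace.
#'
#' @param traces a `calcium_traces` object ([generate_calcium()] or
#'   [read_calcium_csv()]).
#' @param baseline_percentile percentile defining F0 (default 8).
#' @param baseline_window_s rolling window length in seconds (default 10);
#'   windows longer than the recording fall back to the whole-trace
#'   percentile.
#' @return `dff_result`: list with `dff` (frames x ROIs matrix),
#'   `baseline` (same shape), `mean_dff`, `sd_dff` (per frame, across
#'   ROIs), `frame_times_s`.
#' @export
compute_dff <- function(traces, baseline_percentile = 8,
                        baseline_window_s = 10) {
  stopifnot(inherits(traces, "calcium_traces"),
            baseline_percentile > 0, baseline_percentile < 50,
            baseline_window_s > 0)
  f <- traces$f
  nf <- length(traces$frame_times_s)
  if (ncol(f) == 0L) {
    z <- matrix(numeric(0), nrow = nf, ncol = 0)
    return(structure(list(dff = z, baseline = z,
                          mean_dff = rep(NA_real_, nf),
                          sd_dff = rep(NA_real_, nf),
                          frame_times_s = traces$frame_times_s),
                     class = "dff_result"))
  }
  win <- as.integer(round(baseline_window_s * traces$frame_rate_hz))
  p <- baseline_percentile / 100
  baseline <- apply(f, 2, function(x) {
    if (win >= length(x)) {
      rep(stats::quantile(x, p, names = FALSE), length(x))
    } else {
      zoo::rollapply(x, width = win, FUN = stats::quantile, probs = p,
                     names = FALSE, fill = "extend", align = "center",
                     partial = TRUE)
    }
  })
  bad <- which(apply(baseline, 2, function(b) any(b <= 0)))
  if (length(bad)) {
    stop("nonpositive dF/F baseline in ROI(s): ",
         paste(colnames(f)[bad] %||% bad, collapse = ", "))
  }
  dff <- (f - baseline) / baseline
  structure(
    list(dff = dff, baseline = baseline,
         mean_dff = rowMeans(dff),
         sd_dff = apply(dff, 1, stats::sd),
         frame_times_s = traces$frame_times_s),
    class = "dff_result"
  )
}

#' @export
print.dff_result <- function(x, ...) {
  cat(sprintf("<dff_result> %d ROIs x %d frames, mean dF/F peak %.3f\n",
              ncol(x$dff), nrow(x$dff),
              if (ncol(x$dff)) max(x$mean_dff) else NA))
  invisible(x)
}

#' Estimate the calcium-to-electrophysiology lag
#'
#' Cross-correlates the ROI-averaged dF/F with the bout-activity indicator
#' resampled onto the imaging frame grid, over a search window of
#' \[-0.5, 1.5\] s; the lag is the argmax of the normalized
#' cross-correlation, refined by a parabolic fit through the peak and its
#' neighbours, which also supplies the uncertainty (half-width of the
#' parabola's concavity step). Before correlating, the binary indicator is
#' convolved with a single-exponential calcium kernel (`kernel_tau_s`):
#' correlating against the raw box indicator instead would displace the
#' peak by roughly the kernel centroid (~0.2 s for a 0.3 s kernel), a bias
#' that matched-template correlation removes. An onset-difference estimate (median delay
#' between each bout onset and the following dF/F upstroke) is provided as
#' the alternative method, since published lag values do not state which
#' definition was used.
#'
#' @param dff a `dff_result`.
#' @param episodes tibble with `start_s`, `end_s` columns (detected
#'   episodes, or ground-truth bout intervals), at least 3 rows.
#' @param method `"xcorr_peak"` (default) or `"onset_diff"`.
#' @param search_window_s numeric length-2 lag search window.
#' @param kernel_tau_s decay constant of the matched calcium template in
#'   seconds (default 0.3, the GCaMP-scale value the generator also uses).
#' @return `lag_estimate`: list with `lag_s`, `uncertainty_s`, `method`.
#' @export
estimate_lag <- function(dff, episodes,
                         method = c("xcorr_peak", "onset_diff"),
                         search_window_s = c(-0.5, 1.5),
                         kernel_tau_s = 0.3) {
  method <- match.arg(method)
  stopifnot(inherits(dff, "dff_result"))
  if (nrow(episodes) < 3L) {
    stop("lag estimation needs at least 3 bouts (got ", nrow(episodes), ")")
  }
  ft <- dff$frame_times_s
  dt <- stats::median(diff(ft))
  ind <- bout_indicator(episodes, ft)
  y <- dff$mean_dff
  if (stats::sd(ind) == 0 || stats::sd(y) == 0) {
    stop("degenerate indicator or dF/F trace; cannot estimate lag")
  }
  if (method == "onset_diff") {
    thr <- stats::quantile(y, 0.2, names = FALSE) +
      0.2 * (max(y) - stats::quantile(y, 0.2, names = FALSE))
    onsets <- episodes$start_s
    lags <- vapply(onsets, function(t0) {
      i <- which(ft >= t0 & ft <= t0 + search_window_s[2] & y >= thr)
      if (!length(i)) return(NA_real_)
      ft[i[1]] - t0
    }, numeric(1))
    lags <- lags[is.finite(lags)]
    if (length(lags) < 3L) stop("too few dF/F upstrokes found after bout onsets")
    return(structure(list(lag_s = stats::median(lags),
                          uncertainty_s = mad_sd(lags) / sqrt(length(lags)),
                          method = method),
                     class = "lag_estimate"))
  }
  # matched template: box indicator convolved with the calcium kernel
  kt <- seq(0, 6 * kernel_tau_s, by = dt)
  kern <- exp(-kt / kernel_tau_s)
  tmpl <- stats::convolve(ind, rev(kern), type = "open")[seq_along(ind)]
  max_shift <- as.integer(ceiling(search_window_s[2] / dt))
  min_shift <- as.integer(floor(search_window_s[1] / dt))
  shifts <- min_shift:max_shift
  cc <- vapply(shifts, function(k) shifted_cor(y, tmpl, k), numeric(1))
  i <- which.max(cc)
  lag <- shifts[i] * dt
  unc <- dt
  if (i > 1L && i < length(shifts) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) {
      delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
      lag <- (shifts[i] + delta) * dt
      unc <- dt * sqrt(max(1e-12, -2 * (cc[i] - max(cc[i - 1], cc[i + 1]))) / -denom)
    }
  }
  structure(list(lag_s = lag, uncertainty_s = unc, method = method),
            class = "lag_estimate")
}

# Pearson correlation of y against x delayed by k samples (y lags x by k).
shifted_cor <- function(y, x, k) {
  n <- length(y)
  if (k >= 0) {
    ys <- y[(1 + k):n]; xs <- x[1:(n - k)]
  } else {
    ys <- y[1:(n + k)]; xs <- x[(1 - k):n]
  }
  if (length(ys) < 8L || stats::sd(ys) == 0 || stats::sd(xs) == 0) return(NA_real_)
  stats::cor(ys, xs)
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf("<lag_estimate> %.0f +- %.0f ms (%s)\n",
              1000 * x$lag_s, 1000 * x$uncertainty_s, x$method))
  invisible(x)
}

#' Align dF/F with swim episodes and score ROI engagement
#'
#' For each ROI and each episode, the peak dF/F inside the lag-shifted
#' episode window; plus one lag-corrected Pearson correlation per ROI
#' between its dF/F trace and the kernel-convolved bout indicator (the
#' same matched template used for lag estimation, so a ROI faithfully
#' driven by every bout scores near 1).
#'
#' @param dff a `dff_result`.
#' @param episodes tibble with `start_s`, `end_s` (may be empty).
#' @param lag a `lag_estimate`.
#' @param kernel_tau_s decay constant of the matched template (default 0.3).
#' @return list of tibbles: `per_episode` (roi, episode_id, peak_dff) and
#'   `per_roi` (roi, correlation).
#' @export
align_and_export <- function(dff, episodes, lag, kernel_tau_s = 0.3) {
  stopifnot(inherits(dff, "dff_result"), inherits(lag, "lag_estimate"))
  ft <- dff$frame_times_s
  rois <- colnames(dff$dff) %||% as.character(seq_len(ncol(dff$dff)))
  if (!nrow(episodes)) {
    warning("no episodes supplied; returning empty alignment table")
    return(list(
      per_episode = tibble::tibble(roi = character(0), episode_id = integer(0),
                                   peak_dff = numeric(0)),
      per_roi = tibble::tibble(roi = rois,
                               correlation = rep(NA_real_, length(rois)))
    ))
  }
  dt <- stats::median(diff(ft))
  k <- as.integer(round(lag$lag_s / dt))
  ind <- bout_indicator(episodes, ft)
  kt <- seq(0, 6 * kernel_tau_s, by = dt)
  ind <- stats::convolve(ind, rev(exp(-kt / kernel_tau_s)),
                         type = "open")[seq_along(ind)]
  per_episode <- list()
  for (r in seq_len(ncol(dff$dff))) {
    for (ei in seq_len(nrow(episodes))) {
      i <- which(ft >= episodes$start_s[ei] + lag$lag_s &
                   ft <= episodes$end_s[ei] + lag$lag_s)
      per_episode[[length(per_episode) + 1L]] <- tibble::tibble(
        roi = rois[r], episode_id = ei,
        peak_dff = if (length(i)) max(dff$dff[i, r]) else NA_real_
      )
    }
  }
  per_roi <- tibble::tibble(
    roi = rois,
    correlation = vapply(seq_len(ncol(dff$dff)), function(r) {
      shifted_cor(dff$dff[, r], ind, k)
    }, numeric(1))
  )
  list(per_episode = dplyr::bind_rows(per_episode), per_roi = per_roi)
}
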