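#' Two-channel fictive-swim recording
#'
#' Container for a dual contralateral ventral-root recording: one voltage
#' trace per hemi-segment side, a common time base and sampling rate, and
#' free-form metadata (preset, segment, age in dpf, ...).
#'
#' @param time_s monotone time vector (seconds from recording start).
#' @param left_v,right_v numeric voltage vectors (arbitrary units), same
#'   length as `time_s`.
#' @param sampling_rate_hz positive sampling rate; `time_s` must advance in
#'   steps of `1/sampling_rate_hz` within tolerance.
#' @param metadata named list.
#' @return object of class `swim_recording`.
#' @export
new_recording <- function(time_s, left_v, right_v, sampling_rate_hz,
                          metadata = list()) {
  stopifnot(
    is.numeric(time_s), is.numeric(left_v), is.numeric(right_v),
    length(left_v) == length(time_s), length(right_v) == length(time_s),
    is.numeric(sampling_rate_hz), sampling_rate_hz > 0
  )
  if (length(time_s) >= 2L) {
    dtv <- diff(time_s)
    if (any(dtv <= 0)) stop("time_s must be strictly increasing")
    if (max(abs(dtv - 1 / sampling_rate_hz)) > 1e-6 / sampling_rate_hz + 1e-12) {
      stop("time step inconsistent with sampling_rate_hz")
    }
  }
  structure(
    list(time_s = time_s, left_v = left_v, right_v = right_v,
         sampling_rate_hz = sampling_rate_hz, metadata = metadata),
    class = "swim_recording"
  )
}

#' @export
print.swim_recording <- function(x, ...) {
  dur <- if (length(x$time_s)) diff(range(x$time_s)) else 0
  cat(sprintf(
    "<swim_recording> %.3f s at %g Hz (%d samples/channel)\n",
    dur, x$sampling_rate_hz, length(x$time_s)
  ))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
      vapply(x$metadata, function(v) paste(format(v), collapse = ","), ""),
      sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

# Channel accessor used throughout: returns the named voltage vector.
channel_of <- function(recording, channel = c("left", "right")) {
  channel <- match.arg(channel)
  if (channel == "left") recording$left_v else recording$right_v
}

# Replace both channels, keeping time base and metadata.
with_channels <- function(recording, left_v, right_v) {
  new_recording(recording$time_s, left_v, right_v,
                recording$sampling_rate_hz, recording$metadata)
}

#' Ground-truth annotation of a synthetic recording
#'
#' Bundles everything the analysis pipeline is expected to recover from a
#' generated recording: bout intervals and their injected frequency
#' trajectories and class labels, per-channel burst and spike times, the
#' injected left-right phase, and (once calcium traces are generated) the
#' calcium-to-ephys lag.
#'
#' @param bouts tibble: bout, start_s, end_s, label, mean_freq_hz,
#'   crosses_30hz. `start_s`/`end_s` span the first to last spike of the bout.
#' @param freq_trajectory tibble: bout, time_s, freq_hz (injected
#'   instantaneous tail-beat frequency of the left channel).
#' @param bursts tibble: bout, channel, start_s, end_s, n_spikes.
#' @param spikes tibble: bout, channel, time_s.
#' @param injected_phase_deg injected right-after-left phase in degrees.
#' @param artefacts tibble: bout, type, time_s (may have zero rows).
#' @param duration_s,sampling_rate_hz the recording geometry.
#' @param calcium_lag_s calcium onset lag in seconds, `NA` until calcium
#'   traces are generated.
#' @return object of class `swim_ground_truth`.
#' @export
new_ground_truth <- function(bouts, freq_trajectory, bursts, spikes,
                             injected_phase_deg, artefacts,
                             duration_s, sampling_rate_hz,
                             calcium_lag_s = NA_real_) {
  gt <- structure(
    list(bouts = bouts, freq_trajectory = freq_trajectory, bursts = bursts,
         spikes = spikes, injected_phase_deg = injected_phase_deg,
         artefacts = artefacts, duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz, calcium_lag_s = calcium_lag_s),
    class = "swim_ground_truth"
  )
  check_ground_truth(gt)
  gt
}

#' Verify annotation soundness of a ground truth
#'
#' Asserts the structural invariants every generated annotation must satisfy:
#' each spike lies inside one of its channel's bursts and each burst lies
#' inside its bout. Called on every generation; exported so tests and users
#' can re-check loaded annotations.
#'
#' @param gt a `swim_ground_truth`.
#' @param tol slack in seconds for the containment checks.
#' @return `gt`, invisibly; stops on violation.
#' @export
check_ground_truth <- function(gt, tol = 1e-9) {
  b <- gt$bursts
  bo <- gt$bouts
  if (nrow(b)) {
    key <- match(b$bout, bo$bout)
    if (anyNA(key)) stop("burst references unknown bout")
    ok <- b$start_s >= bo$start_s[key] - tol & b$end_s <= bo$end_s[key] + tol
    if (!all(ok)) stop("ground-truth burst outside its bout")
  }
  s <- gt$spikes
  if (nrow(s)) {
    for (ch in unique(s$channel)) {
      st <- s$time_s[s$channel == ch]
      bb <- b[b$channel == ch, , drop = FALSE]
      if (!nrow(bb)) stop("spikes on channel ", ch, " but no bursts")
      inside <- vapply(st, function(tt) {
        any(tt >= bb$start_s - tol & tt <= bb$end_s + tol)
      }, logical(1))
      if (!all(inside)) stop("ground-truth spike outside every burst")
    }
  }
  invisible(gt)
}

#' @export
print.swim_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<swim_ground_truth> %d bouts, %d bursts, %d spikes; phase %g deg\n",
    nrow(x$bouts), nrow(x$bursts), nrow(x$spikes), x$injected_phase_deg
  ))
  if (nrow(x$artefacts)) {
    cat("  artefacts:", paste(unique(x$artefacts$type), collapse = ", "), "\n")
  }
  invisible(x)
}
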