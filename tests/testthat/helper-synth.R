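# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so expectations are stable.

# One-bout recording at an exact constant tail-beat frequency.
fixed_freq_recording <- function(freq_hz, noise_sd = 0, seed = 1,
                                 duration_s = 3) {
  generate_recording(synth_config(
    duration_s = duration_s, bout_rate_per_min = 20,
    freq_trajectory = "continuous", freq_fixed_hz = freq_hz,
    noise_sd = noise_sd, seed = seed
  ))
}

# Hand-built swim_episode from explicit per-channel burst intervals.
# Each burst contributes spikes at its endpoints (or a single spike for a
# point burst), then segmentation is re-run, so the episode's bursts match
# the requested intervals exactly.
episode_from_bursts <- function(starts, ends, channels,
                                params = detection_params()) {
  stopifnot(length(starts) == length(ends), length(starts) == length(channels))
  sp <- list()
  for (i in seq_along(starts)) {
    tt <- if (ends[i] > starts[i]) {
      seq(starts[i], ends[i], length.out = max(
        2L, ceiling((ends[i] - starts[i]) / (params$burst_gap_s * 0.9)) + 1L))
    } else {
      starts[i]
    }
    sp[[i]] <- tibble::tibble(time_s = tt, amplitude = 1, channel = channels[i])
  }
  spikes <- dplyr::bind_rows(sp)
  spikes <- spikes[order(spikes$time_s, spikes$channel), ]
  structure(
    list(start_s = min(spikes$time_s), end_s = max(spikes$time_s),
         duration_s = diff(range(spikes$time_s)),
         spikes = spikes, bursts = NULL, params = params),
    class = "swim_episode"
  ) |> segment_bursts(params)
}

# Episode whose bursts follow a given side sequence, non-overlapping.
episode_from_sides <- function(sides, burst_len = 0.01, gap = 0.02) {
  n <- length(sides)
  starts <- (seq_len(n) - 1) * (burst_len + gap)
  episode_from_bursts(starts, starts + burst_len, sides)
}

# Brute-force penalty oracles (naive loops, independent of the package
# implementation path).
brute_alternation <- function(sides) {
  n <- length(sides)
  if (n < 2) return(0)
  cnt <- 0
  for (i in 2:n) if (sides[i] == sides[i - 1]) cnt <- cnt + 1
  cnt / n
}

brute_simultaneous <- function(starts, ends, channels, frac = 0.7) {
  n <- length(starts)
  cnt <- 0
  for (i in seq_len(n)) {
    hit <- FALSE
    for (j in seq_len(n)) {
      if (channels[j] == channels[i]) next
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      di <- ends[i] - starts[i]
      if (di <= 0) {
        if (starts[i] >= starts[j] && starts[i] <= ends[j] &&
            ends[j] > starts[j]) hit <- TRUE
      } else if (ov > frac * di) hit <- TRUE
    }
    if (hit) cnt <- cnt + 1
  }
  cnt / n
}

# Synthetic periodicity-kind trace from an explicit value vector.
trace_from_values <- function(values, fs, channel = "left",
                              kind = "periodicity") {
  fictiveswim:::new_activity_trace((seq_along(values) - 1) / fs, values,
                                   kind, channel, fs)
}
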