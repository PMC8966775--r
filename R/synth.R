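#' Synthetic-recording configuration
#'
#' Parameters of the seeded generator that emulates dual ventral-root
#' recordings of fictive swimming. The four presets are qualitative
#' calibrations to the published character of each elicitation method (see
#' [preset_defaults()] for the constants table): `spontaneous` slow-biased
#' bouts, `nmda` slow (<20 Hz median) bouts, `electrical` short decelerating
#' bouts starting above 30 Hz, and `optomotor` bouts with a bimodal 26/34 Hz
#' tail-beat distribution straddling the 30 Hz speed-module boundary.
#'
#' @param sampling_rate_hz samples per second per channel (default 10000;
#'   real acquisitions run higher, the rate is a free parameter here).
#' @param duration_s recording length in seconds.
#' @param preset one of `"spontaneous"`, `"nmda"`, `"electrical"`,
#'   `"optomotor"`.
#' @param bout_rate_per_min expected bouts per minute; `NULL` takes the
#'   preset default.
#' @param freq_trajectory `"preset-mixed"` (draw per-bout labels from the
#'   preset's mixture) or one of `"increasing"`, `"decreasing"`,
#'   `"continuous"`, `"rise_fall"` to force every bout.
#' @param freq_range_hz length-2 numeric within \[10, 60\]; injected
#'   trajectories are clamped into it. `NULL` takes the preset default.
#' @param phase_deg injected right-after-left phase in degrees, in
#'   \[0, 360); 180 is perfect anti-phase alternation.
#' @param noise_sd SD of additive white Gaussian noise, in units of the
#'   nominal spike amplitude (1).
#' @param pink_noise_sd SD of an optional additive 1/f noise component.
#' @param spike_amplitude nominal spike amplitude (per-burst amplitudes are
#'   drawn lognormally around it).
#' @param burst_duty fraction of the tail-beat period occupied by a burst.
#' @param spike_isi_s nominal within-burst inter-spike interval in seconds.
#'   Must stay below the downstream burst-splitting gap; the default 4 ms
#'   keeps within-burst gaps under 8 ms at every tail-beat frequency in
#'   \[10, 60\] Hz.
#' @param freq_fixed_hz optional exact tail-beat frequency in Hz; when set
#'   (with `freq_trajectory = "continuous"`) every bout is driven at
#'   precisely this frequency instead of a preset draw — the hook used by
#'   parameter-recovery studies.
#' @param artefacts character subset of `c("erratic_burst", "dual_frequency",
#'   "incoherent", "stim_artefact")`; each listed artefact is injected into
#'   every bout (stimulation artefacts at bout onset only).
#' @param seed integer; fully determines the output.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 10000,
                         duration_s = 10,
                         preset = c("spontaneous", "nmda", "electrical",
                                    "optomotor"),
                         bout_rate_per_min = NULL,
                         freq_trajectory = "preset-mixed",
                         freq_range_hz = NULL,
                         phase_deg = 180,
                         noise_sd = 0.15,
                         pink_noise_sd = 0,
                         spike_amplitude = 1,
                         burst_duty = 0.3,
                         spike_isi_s = 0.004,
                         freq_fixed_hz = NULL,
                         artefacts = character(),
                         seed = 1L) {
  preset <- match.arg(preset)
  defs <- preset_defaults(preset)
  if (is.null(bout_rate_per_min)) bout_rate_per_min <- defs$bout_rate_per_min
  if (is.null(freq_range_hz)) freq_range_hz <- defs$freq_range_hz
  stopifnot(
    is.numeric(sampling_rate_hz), sampling_rate_hz > 0,
    is.numeric(duration_s), duration_s > 0,
    is.numeric(bout_rate_per_min), bout_rate_per_min > 0,
    is.numeric(freq_range_hz), length(freq_range_hz) == 2L,
    is.numeric(phase_deg), phase_deg >= 0, phase_deg < 360,
    is.numeric(noise_sd), noise_sd >= 0, pink_noise_sd >= 0,
    spike_amplitude > 0, burst_duty > 0, burst_duty < 1, spike_isi_s > 0
  )
  if (!(freq_trajectory %in% c("preset-mixed", "increasing", "decreasing",
                               "continuous", "rise_fall"))) {
    stop("unknown freq_trajectory: ", freq_trajectory)
  }
  if (freq_range_hz[1] < 10 || freq_range_hz[2] > 60 ||
      freq_range_hz[1] >= freq_range_hz[2]) {
    stop("freq_range_hz must be an increasing pair within [10, 60]")
  }
  # spike waveforms carry energy up to ~1 kHz; keep them resolvable
  if (sampling_rate_hz < 4000) {
    stop("sampling_rate_hz must be at least 4 x the ~1 kHz spike band")
  }
  bad <- setdiff(artefacts, c("erratic_burst", "dual_frequency",
                              "incoherent", "stim_artefact"))
  if (length(bad)) stop("unknown artefacts: ", paste(bad, collapse = ", "))
  if (!is.null(freq_fixed_hz)) {
    stopifnot(is.numeric(freq_fixed_hz), freq_fixed_hz >= 10,
              freq_fixed_hz <= 60)
    if (freq_trajectory != "continuous") {
      stop("freq_fixed_hz requires freq_trajectory = \"continuous\"")
    }
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         preset = preset, bout_rate_per_min = bout_rate_per_min,
         freq_trajectory = freq_trajectory, freq_range_hz = freq_range_hz,
         phase_deg = phase_deg, noise_sd = noise_sd,
         pink_noise_sd = pink_noise_sd, spike_amplitude = spike_amplitude,
         burst_duty = burst_duty, spike_isi_s = spike_isi_s,
         freq_fixed_hz = freq_fixed_hz,
         artefacts = unique(artefacts), seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Preset constants of the synthetic generator
#'
#' One place holding the per-preset calibrations: bout rate, bout-duration
#' distribution, tail-beat frequency distribution, and the mixture over
#' frequency-trajectory classes. These are qualitative calibrations to the
#' published character of each elicitation method (slow NMDA swims, short
#' decelerating electrically evoked swims starting above 30 Hz, bimodal
#' 26/34 Hz optomotor swims); they are not fits to any empirical histogram.
#'
#' @param preset preset name.
#' @return named list of constants.
#' @export
preset_defaults <- function(preset) {
  switch(preset,
    spontaneous = list(
      bout_rate_per_min = 6, freq_range_hz = c(12, 50),
      dur_meanlog = log(0.45), dur_sdlog = 0.45, dur_clamp = c(0.15, 2),
      freq_centres_hz = 24, freq_centre_sd_hz = 5, freq_mix_w = 1,
      mix = c(increasing = 0.20, decreasing = 0.20,
              continuous = 0.35, rise_fall = 0.25)
    ),
    nmda = list(
      bout_rate_per_min = 8, freq_range_hz = c(12, 30),
      dur_meanlog = log(0.45), dur_sdlog = 0.45, dur_clamp = c(0.15, 2),
      freq_centres_hz = 16, freq_centre_sd_hz = 3, freq_mix_w = 1,
      mix = c(increasing = 0.15, decreasing = 0.15,
              continuous = 0.50, rise_fall = 0.20)
    ),
    electrical = list(
      bout_rate_per_min = 4, freq_range_hz = c(12, 55),
      dur_meanlog = log(0.25), dur_sdlog = 0.35, dur_clamp = c(0.15, 0.6),
      freq_centres_hz = 40, freq_centre_sd_hz = 4, freq_mix_w = 1,
      mix = c(increasing = 0, decreasing = 1, continuous = 0, rise_fall = 0)
    ),
    optomotor = list(
      bout_rate_per_min = 10, freq_range_hz = c(12, 55),
      dur_meanlog = log(0.45), dur_sdlog = 0.45, dur_clamp = c(0.15, 2),
      freq_centres_hz = c(26, 34), freq_centre_sd_hz = 2.5,
      freq_mix_w = c(0.5, 0.5),
      mix = c(increasing = 0.20, decreasing = 0.20,
              continuous = 0.30, rise_fall = 0.30)
    ),
    stop("unknown preset: ", preset)
  )
}

# Evaluate expr with a private RNG stream, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Biphasic difference-of-Gaussians spike waveform, ~1 ms total width,
# positive lobe peaking at the nominal spike time. The negative lobe is
# kept clearly smaller so the absolute peak stays on the positive lobe
# even after denoising perturbs the two magnitudes.
spike_waveform <- function(t_rel_s, amplitude) {
  amplitude * (exp(-0.5 * (t_rel_s / 1.2e-4)^2) -
               0.55 * exp(-0.5 * ((t_rel_s - 4e-4) / 1.8e-4)^2))
}

# Injected instantaneous-frequency trajectory of one bout, on a time grid
# relative to bout start. `label` is the trajectory class; f0/f1 span the
# excursion (f1 is the peak for rise_fall).
bout_freq_fun <- function(label, dur, f0, f1) {
  force(dur); force(f0); force(f1)
  switch(label,
    continuous = function(t) rep(f0, length(t)),
    increasing = function(t) f0 + (f1 - f0) * t / dur,
    decreasing = function(t) f1 + (f0 - f1) * t / dur,
    rise_fall = function(t) f0 + (f1 - f0) * (1 - abs(2 * t / dur - 1)),
    stop("unknown trajectory label: ", label)
  )
}

# Draw the per-bout trajectory parameters for a preset. Returns label, f0,
# f1 such that the trajectory stays within freq_range.
draw_bout_params <- function(cfg, defs) {
  if (!is.null(cfg$freq_fixed_hz)) {
    return(list(label = "continuous", f0 = cfg$freq_fixed_hz,
                f1 = cfg$freq_fixed_hz))
  }
  label <- if (cfg$freq_trajectory == "preset-mixed") {
    sample(names(defs$mix), 1L, prob = defs$mix)
  } else {
    cfg$freq_trajectory
  }
  rng <- cfg$freq_range_hz
  if (cfg$preset == "electrical" && cfg$freq_trajectory %in%
        c("preset-mixed", "decreasing")) {
    # decelerating swims starting above 30 Hz
    f_start <- stats::runif(1, 32, min(50, rng[2]))
    f_end <- clamp(f_start - stats::runif(1, 8, 20), rng[1], f_start - 5)
    return(list(label = "decreasing", f0 = f_end, f1 = f_start))
  }
  centre_i <- sample(seq_along(defs$freq_centres_hz), 1L,
                     prob = defs$freq_mix_w)
  fc <- clamp(stats::rnorm(1, defs$freq_centres_hz[centre_i],
                           defs$freq_centre_sd_hz), rng[1] + 1, rng[2] - 1)
  list(label = label, f0 = fc, f1 = fc)
}

# Widen a continuous draw into an excursion for sloped/rise-fall bouts.
# The span grows with duration so the trend slope stays clearly above the
# 5 Hz/s continuous-vs-sloped decision threshold, and the rise-fall
# edge-to-peak contrast stays clearly above the 5 Hz rule.
widen_trajectory <- function(par, dur, rng) {
  if (par$label == "continuous" || par$f1 > par$f0) return(par)
  span_min <- max(12, 6.5 * dur)
  span <- stats::runif(1, span_min, max(span_min + 2, 18))
  f0 <- clamp(par$f0 - span / 2, rng[1], rng[2])
  f1 <- clamp(par$f0 + span / 2, rng[1], rng[2])
  if (f1 - f0 < span_min) {
    if (f0 <= rng[1] + 1e-9) f1 <- min(rng[2], f0 + span_min)
    else f0 <- max(rng[1], f1 - span_min)
  }
  list(label = par$label, f0 = f0, f1 = f1)
}

# Lay the burst/spike skeleton of one rhythmic bout. Returns per-channel
# burst and spike times (absolute seconds) plus the sampled trajectory.
build_bout_skeleton <- function(cfg, t_start, dur, freq_fun) {
  grid <- seq(0, dur, by = 1e-3)
  f <- freq_fun(grid)
  phi <- cumsum(c(0, (head(f, -1) + tail(f, -1)) / 2 * diff(grid)))
  max_phi <- phi[length(phi)]
  bursts <- list(); spikes <- list()
  for (ch in c("left", "right")) {
    off <- if (ch == "left") 0 else cfg$phase_deg / 360
    ks <- seq(0, floor(max_phi), by = 1)
    targets <- ks + off
    targets <- targets[targets < max_phi]
    if (!length(targets)) next
    t_on <- stats::approx(phi, grid, xout = targets)$y
    f_on <- stats::approx(grid, f, xout = t_on)$y
    bdur <- cfg$burst_duty / f_on
    keep <- (t_on + bdur) <= dur
    t_on <- t_on[keep]; bdur <- bdur[keep]
    if (!length(t_on)) next
    ch_spikes <- vector("list", length(t_on))
    for (i in seq_along(t_on)) {
      n_sp <- max(2L, as.integer(floor(bdur[i] / cfg$spike_isi_s)) + 1L)
      ch_spikes[[i]] <- t_start + seq(t_on[i], t_on[i] + bdur[i],
                                      length.out = n_sp)
    }
    bursts[[ch]] <- tibble::tibble(
      channel = ch,
      start_s = t_start + t_on,
      end_s = t_start + t_on + bdur,
      n_spikes = vapply(ch_spikes, length, integer(1))
    )
    spikes[[ch]] <- tibble::tibble(
      channel = ch,
      time_s = unlist(ch_spikes),
      burst = rep(seq_along(ch_spikes), vapply(ch_spikes, length, integer(1)))
    )
  }
  list(
    bursts = dplyr::bind_rows(bursts),
    spikes = dplyr::bind_rows(spikes),
    trajectory = tibble::tibble(time_s = t_start + grid, freq_hz = f)
  )
}

# Concatenate two bout skeletons, renumbering the second skeleton's
# per-channel spike->burst indices past the first skeleton's bursts.
combine_skeletons <- function(sk1, sk2) {
  bursts <- dplyr::bind_rows(sk1$bursts, sk2$bursts)
  sp2 <- sk2$spikes
  for (ch in c("left", "right")) {
    off <- sum(sk1$bursts$channel == ch)
    sp2$burst[sp2$channel == ch] <- sp2$burst[sp2$channel == ch] + off
  }
  list(bursts = bursts, spikes = dplyr::bind_rows(sk1$spikes, sp2))
}

# Poisson spike skeleton (no burst rhythm); each spike is its own
# degenerate burst so annotation-soundness invariants still hold.
build_poisson_skeleton <- function(t_start, dur, rate_hz) {
  out <- list()
  for (ch in c("left", "right")) {
    n <- stats::rpois(1, rate_hz * dur)
    tt <- sort(stats::runif(n, 0, dur)) + t_start
    out[[ch]] <- tibble::tibble(channel = ch, time_s = tt,
                                burst = seq_along(tt))
  }
  spikes <- dplyr::bind_rows(out)
  bursts <- spikes |>
    dplyr::group_by(.data$channel, .data$burst) |>
    dplyr::summarise(start_s = min(.data$time_s), end_s = max(.data$time_s),
                     n_spikes = dplyr::n(), .groups = "drop") |>
    dplyr::select("channel", "start_s", "end_s", "n_spikes")
  list(bursts = bursts, spikes = spikes)
}

#' Generate a synthetic dual-channel fictive-swim recording
#'
#' Produces a seeded two-channel voltage recording with spike bursts riding
#' on noise, anti-phase (or configured-phase) bilateral bursting at injected
#' tail-beat frequencies, preset-specific bout statistics, and the requested
#' artefact classes, together with a full [new_ground_truth()] annotation of
#' what was injected.
#'
#' Bursts are trains of biphasic ~1 ms spike waveforms at the instantaneous
#' tail-beat frequency; the right channel lags the left by
#' `phase_deg / 360` of a cycle. Artefact injectors: `stim_artefact` adds a
#' large-amplitude decaying transient saturating both channels at bout
#' onset; `dual_frequency` drives the right channel at a trajectory
#' displaced by more than 8 Hz from the left; `incoherent` replaces the
#' bout's rhythm with Poisson spiking on both channels; `erratic_burst`
#' switches abruptly mid-bout from low-amplitude irregular spiking to
#' high-frequency erratic bursting.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` ([new_recording()]) and
#'   `ground_truth` ([new_ground_truth()]).
#' @examples
#' out <- generate_recording(synth_config(duration_s = 4, seed = 7))
#' out$recording
#' out$ground_truth
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, generate_recording_impl(config))
}

generate_recording_impl <- function(cfg) {
  fs <- cfg$sampling_rate_hz
  n <- as.integer(round(cfg$duration_s * fs)) + 1L
  time_s <- (seq_len(n) - 1L) / fs
  defs <- preset_defaults(cfg$preset)

  edge <- 0.25           # quiet margin at both record edges (s)
  gap_min <- 0.3         # minimum inter-bout quiescence (s)
  n_bouts <- max(1L, as.integer(round(cfg$bout_rate_per_min *
                                        cfg$duration_s / 60)))
  avail <- cfg$duration_s - 2 * edge
  if (avail < defs$dur_clamp[1] + 0.05) {
    stop("duration_s = ", cfg$duration_s, " too short to place one bout of ",
         "at least ", defs$dur_clamp[1], " s inside ", edge,
         " s edge margins at bout_rate_per_min = ", cfg$bout_rate_per_min)
  }
  slot <- avail / n_bouts
  while (n_bouts > 1L && slot < defs$dur_clamp[1] + gap_min) {
    n_bouts <- n_bouts - 1L
    slot <- avail / n_bouts
  }

  left <- numeric(n); right <- numeric(n)
  bouts <- list(); trajs <- list(); bursts <- list(); spikes <- list()
  artefact_log <- list()

  for (b in seq_len(n_bouts)) {
    slot_start <- edge + (b - 1) * slot
    par0 <- draw_bout_params(cfg, defs)
    # a frequency trajectory needs a few slow cycles per limb to be
    # expressed at all; sloped and rise-fall bouts get a duration floor
    dur_min <- if (par0$label == "continuous") defs$dur_clamp[1] else
      max(defs$dur_clamp[1], 0.5)
    dur <- clamp(stats::rlnorm(1, defs$dur_meanlog, defs$dur_sdlog),
                 dur_min, max(dur_min, min(defs$dur_clamp[2], slot - gap_min)))
    dur <- max(defs$dur_clamp[1], min(dur, slot - 0.15)) # never bleed slots
    t_start <- slot_start + stats::runif(1, 0, max(0, slot - gap_min - dur))
    par <- widen_trajectory(par0, dur, cfg$freq_range_hz)
    freq_fun <- bout_freq_fun(par$label, dur, par$f0, par$f1)

    art_here <- cfg$artefacts
    if ("incoherent" %in% art_here) {
      sk <- build_poisson_skeleton(t_start, dur, rate_hz = 60)
      sk$trajectory <- tibble::tibble(time_s = numeric(0), freq_hz = numeric(0))
      label <- "incoherent"
      amp_scale <- rep(1, nrow(sk$bursts))
      artefact_log[[length(artefact_log) + 1L]] <-
        tibble::tibble(bout = b, type = "incoherent", time_s = t_start)
    } else if ("erratic_burst" %in% art_here) {
      # abrupt regime switch at mid-bout: irregular low-amplitude spiking,
      # then fast high-amplitude erratic bursting
      half <- dur / 2
      sk1 <- build_poisson_skeleton(t_start, half, rate_hz = 35)
      f_err <- function(t) 45 + 10 * sin(2 * pi * t * 1.7) # wandering 35-55 Hz
      sk2 <- build_bout_skeleton(cfg, t_start + half, half, f_err)
      sk <- combine_skeletons(sk1, sk2)
      sk$trajectory <- sk2$trajectory
      label <- par$label
      amp_scale <- ifelse(sk$bursts$start_s < t_start + half, 0.35, 1.6)
      artefact_log[[length(artefact_log) + 1L]] <-
        tibble::tibble(bout = b, type = "erratic_burst",
                       time_s = t_start + half)
    } else if ("dual_frequency" %in% art_here) {
      skL <- build_bout_skeleton(cfg, t_start, dur, freq_fun)
      shift <- if (par$f1 > 30) -12 else 12 # keep within [10, 60]
      freq_fun_r <- function(t) clamp(freq_fun(t) + shift, 10, 60)
      skR <- build_bout_skeleton(cfg, t_start, dur, freq_fun_r)
      sk <- list(
        bursts = dplyr::bind_rows(
          skL$bursts[skL$bursts$channel == "left", , drop = FALSE],
          skR$bursts[skR$bursts$channel == "right", , drop = FALSE]),
        spikes = dplyr::bind_rows(
          skL$spikes[skL$spikes$channel == "left", , drop = FALSE],
          skR$spikes[skR$spikes$channel == "right", , drop = FALSE]),
        trajectory = skL$trajectory
      )
      label <- par$label
      amp_scale <- rep(1, nrow(sk$bursts))
      artefact_log[[length(artefact_log) + 1L]] <-
        tibble::tibble(bout = b, type = "dual_frequency", time_s = t_start)
    } else {
      sk <- build_bout_skeleton(cfg, t_start, dur, freq_fun)
      label <- par$label
      amp_scale <- rep(1, nrow(sk$bursts))
    }
    if (!nrow(sk$spikes)) next

    # per-burst amplitudes (lognormal around the nominal spike amplitude)
    amp_burst <- cfg$spike_amplitude * amp_scale *
      stats::rlnorm(nrow(sk$bursts), 0, 0.15)
    # map each spike to its burst row (per channel) for amplitude lookup
    sp_amp <- numeric(nrow(sk$spikes))
    for (ch in c("left", "right")) {
      bi <- which(sk$bursts$channel == ch)
      si <- which(sk$spikes$channel == ch)
      if (!length(si)) next
      sp_amp[si] <- amp_burst[bi][sk$spikes$burst[si]]
    }

    for (ch in c("left", "right")) {
      si <- which(sk$spikes$channel == ch)
      if (!length(si)) next
      v <- if (ch == "left") left else right
      v <- add_spikes(v, fs, sk$spikes$time_s[si], sp_amp[si])
      if (ch == "left") left <- v else right <- v
    }

    if ("stim_artefact" %in% art_here) {
      # large decaying transient saturating both channels at bout onset
      i0 <- as.integer(round((t_start - 0.005) * fs)) + 1L
      tt <- (0:as.integer(round(0.02 * fs))) / fs
      pulse <- 12 * cfg$spike_amplitude * exp(-tt / 0.004) *
        cos(2 * pi * 150 * tt)
      sat <- 10 * cfg$spike_amplitude
      idx <- i0 + seq_along(pulse) - 1L
      ok <- idx >= 1L & idx <= n
      left[idx[ok]] <- clamp(left[idx[ok]] + pulse[ok], -sat, sat)
      right[idx[ok]] <- clamp(right[idx[ok]] + pulse[ok], -sat, sat)
      artefact_log[[length(artefact_log) + 1L]] <-
        tibble::tibble(bout = b, type = "stim_artefact",
                       time_s = t_start - 0.005)
    }

    traj <- sk$trajectory
    crosses <- nrow(traj) > 0 && min(traj$freq_hz) < 30 && max(traj$freq_hz) > 30
    bouts[[b]] <- tibble::tibble(
      bout = b,
      start_s = min(sk$spikes$time_s), end_s = max(sk$spikes$time_s),
      label = label,
      mean_freq_hz = if (nrow(traj)) mean(traj$freq_hz) else NA_real_,
      crosses_30hz = crosses
    )
    trajs[[b]] <- dplyr::mutate(traj, bout = b, .before = 1)
    bursts[[b]] <- dplyr::mutate(
      dplyr::select(sk$bursts, "channel", "start_s", "end_s", "n_spikes"),
      bout = b, .before = 1)
    spikes[[b]] <- dplyr::mutate(
      dplyr::select(sk$spikes, "channel", "time_s"), bout = b, .before = 1)
  }

  if (cfg$noise_sd > 0) {
    left <- left + stats::rnorm(n, 0, cfg$noise_sd)
    right <- right + stats::rnorm(n, 0, cfg$noise_sd)
  }
  if (cfg$pink_noise_sd > 0) {
    left <- left + pink_noise(n, cfg$pink_noise_sd)
    right <- right + pink_noise(n, cfg$pink_noise_sd)
  }

  rec <- new_recording(time_s, left, right, fs,
                       metadata = list(preset = cfg$preset, seed = cfg$seed,
                                       segment = 10L, age_dpf = 5L))
  gt <- new_ground_truth(
    bouts = dplyr::bind_rows(bouts),
    freq_trajectory = dplyr::bind_rows(trajs),
    bursts = dplyr::bind_rows(bursts),
    spikes = dplyr::bind_rows(spikes),
    injected_phase_deg = cfg$phase_deg,
    artefacts = if (length(artefact_log)) dplyr::bind_rows(artefact_log)
                else tibble::tibble(bout = integer(0), type = character(0),
                                    time_s = numeric(0)),
    duration_s = cfg$duration_s, sampling_rate_hz = fs
  )
  list(recording = rec, ground_truth = gt)
}

# Add biphasic spike waveforms into a voltage vector at the given times.
add_spikes <- function(v, fs, times_s, amplitudes) {
  half <- as.integer(round(0.0012 * fs)) # waveform support ~ +-1.2 ms
  rel <- (-half:half) / fs
  n <- length(v)
  for (i in seq_along(times_s)) {
    c0 <- as.integer(round(times_s[i] * fs)) + 1L
    idx <- c0 + (-half:half)
    ok <- idx >= 1L & idx <= n
    # centre the waveform on the exact (off-grid) spike time
    dt0 <- times_s[i] - (c0 - 1L) / fs
    v[idx[ok]] <- v[idx[ok]] + spike_waveform(rel[ok] - dt0, amplitudes[i])
  }
  v
}

# 1/f-shaped Gaussian noise via spectral shaping, normalized to target SD.
pink_noise <- function(n, sd_target) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x) * sd_target
}
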