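#' Pipeline configuration
#'
#' Bundles every stage's parameters with input/output paths and a master
#' seed. All times are seconds from recording start, all frequencies Hz,
#' all phases degrees in \[0, 360) — the unit policy of the whole package.
#'
#' @param out_dir output directory (created if missing).
#' @param recording path to a recording (`.tsv` or `.rds`), or `NULL` to
#'   simulate one from `synth`.
#' @param calcium path to a calcium CSV, `NULL` to simulate when `synth`
#'   is used, or `NA` to skip the calcium stage.
#' @param synth a [synth_config()] used when `recording` is `NULL`.
#' @param denoise a [denoise_params()].
#' @param detection a [detection_params()].
#' @param rhythm a [rhythm_params()].
#' @param n_rois,calcium_lag_s,frame_rate_hz calcium simulation settings
#'   (used only when simulating).
#' @param seed master seed; stage seeds are derived from it
#'   deterministically.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            recording = NULL,
                            calcium = NULL,
                            synth = synth_config(duration_s = 60,
                                                 preset = "optomotor"),
                            denoise = denoise_params(),
                            detection = detection_params(),
                            rhythm = rhythm_params(),
                            n_rois = 12L,
                            calcium_lag_s = 0.311,
                            frame_rate_hz = 30,
                            seed = 1L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            inherits(synth, "synth_config"),
            inherits(denoise, "denoise_params"),
            inherits(detection, "detection_params"),
            inherits(rhythm, "rhythm_params"))
  if (!is.null(recording) && !file.exists(recording)) {
    stop("recording file not found: ", recording)
  }
  if (is.character(calcium) && !file.exists(calcium)) {
    stop("calcium file not found: ", calcium)
  }
  structure(
    list(out_dir = out_dir, recording = recording, calcium = calcium,
         synth = synth, denoise = denoise, detection = detection,
         rhythm = rhythm, n_rois = as.integer(n_rois),
         calcium_lag_s = calcium_lag_s, frame_rate_hz = frame_rate_hz,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> denoise -> extract episodes -> rhythm analysis ->
#' calcium alignment, writing every stage's table under `out_dir`:
#' `episodes.csv`, `bursts.csv`, `bouts.csv` (classification + phase +
#' penalties per episode), `phase_export.csv` (polar-plot data),
#' `summary.json`, optionally `calcium_alignment.csv` and `lag.json`, and
#' `manifest.json` (config hash, seed, package version, file hashes).
#' Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the result tables and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  gt <- NULL
  if (is.null(config$recording)) {
    say("simulating recording (preset ", config$synth$preset, ")")
    sim <- generate_recording(config$synth)
    rec <- sim$recording
    gt <- sim$ground_truth
    write_ground_truth_json(gt, file.path(config$out_dir, "ground_truth.json"))
  } else {
    say("loading recording from ", config$recording)
    rec <- if (grepl("\\.rds$", config$recording)) {
      read_recording_rds(config$recording)
    } else {
      read_recording_tsv(config$recording)
    }
  }

  say("wavelet denoising")
  den <- wavelet_denoise(rec, config$denoise)
  say("extracting episodes")
  eplist <- extract_episodes(den, config$detection)
  tabs <- episode_tables(eplist)
  readr::write_csv(tabs$episodes, file.path(config$out_dir, "episodes.csv"))
  readr::write_csv(tabs$bursts, file.path(config$out_dir, "bursts.csv"))

  say("rhythm analysis (", length(eplist$episodes), " episodes)")
  rhy <- analyze_rhythm(den, eplist, config$rhythm)
  bouts <- dplyr::left_join(
    rhy,
    tabs$episodes[, c("episode_id", "alternation_penalty",
                      "simultaneous_penalty")],
    by = "episode_id"
  )
  readr::write_csv(bouts, file.path(config$out_dir, "bouts.csv"))
  readr::write_csv(
    bouts[, c("episode_id", "mean_phase_deg", "coherence")],
    file.path(config$out_dir, "phase_export.csv")
  )

  summary_json <- list(
    n_episodes = length(eplist$episodes),
    n_dropped_short = eplist$n_dropped_short,
    n_bouts_analyzed = nrow(bouts)
  )
  if (nrow(bouts)) {
    bouts$group <- rec$metadata$preset %||% "recording"
    summary_json$groups <- summarize_bouts(bouts, "group")
  }

  ca_result <- NULL
  if (!isTRUE(is.na(config$calcium))) {
    ca <- NULL
    if (is.character(config$calcium)) {
      say("loading calcium traces from ", config$calcium)
      ca <- read_calcium_csv(config$calcium)
    } else if (is.null(config$calcium) && !is.null(gt) && config$n_rois > 0) {
      say("simulating calcium traces (", config$n_rois, " ROIs)")
      ca <- generate_calcium(gt, n_rois = config$n_rois,
                             lag_s = config$calcium_lag_s,
                             frame_rate_hz = config$frame_rate_hz,
                             seed = child_seed(config$seed, "calcium"))
    }
    if (!is.null(ca) && ncol(ca$f) > 0 && nrow(tabs$episodes) >= 3) {
      dff <- compute_dff(ca)
      lag <- estimate_lag(dff, tabs$episodes)
      al <- align_and_export(dff, tabs$episodes, lag)
      readr::write_csv(al$per_roi,
                       file.path(config$out_dir, "calcium_alignment.csv"))
      jsonlite::write_json(
        list(lag_s = lag$lag_s, uncertainty_s = lag$uncertainty_s,
             method = lag$method),
        file.path(config$out_dir, "lag.json"), auto_unbox = TRUE, digits = NA)
      ca_result <- list(dff = dff, lag = lag, alignment = al)
      summary_json$calcium_lag_s <- lag$lag_s
    }
  }

  jsonlite::write_json(summary_json, file.path(config$out_dir, "summary.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  # hash the scientific configuration, not the output location
  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fictiveswim")),
    files = file_hashes(config$out_dir, exclude = "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(recording = rec, ground_truth = gt, episodes = eplist,
                 tables = tabs, bouts = bouts, calcium = ca_result,
                 manifest = manifest))
}

file_hashes <- function(dir, exclude = character()) {
  fs <- setdiff(list.files(dir), exclude)
  out <- lapply(fs, function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  })
  stats::setNames(out, fs)
}

#' Write the canonical synthetic fixture set
#'
#' One recording per stimulation preset, one per artefact class, and one
#' calcium trace set, each with its ground-truth annotation — the frozen
#' inputs the test-suite and the analysis scripts share.
#'
#' @param out_dir writable directory.
#' @param seed master seed; each fixture derives its own stream from it.
#' @param duration_s per-recording duration (default 12 s).
#' @return (invisibly) tibble manifest of written files.
#' @export
make_fixtures <- function(out_dir, seed = 1L, duration_s = 12) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  emit <- function(name, cfg) {
    sim <- generate_recording(cfg)
    rp <- file.path(out_dir, paste0(name, ".tsv"))
    gp <- file.path(out_dir, paste0(name, "_truth.json"))
    write_recording_tsv(sim$recording, rp)
    write_ground_truth_json(sim$ground_truth, gp)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, recording = basename(rp), ground_truth = basename(gp),
      n_bouts = nrow(sim$ground_truth$bouts))
    sim
  }
  presets <- c("spontaneous", "nmda", "electrical", "optomotor")
  last <- NULL
  for (p in presets) {
    last <- emit(p, synth_config(duration_s = duration_s, preset = p,
                                 seed = child_seed(seed, p)))
  }
  for (a in c("erratic_burst", "dual_frequency", "incoherent",
              "stim_artefact")) {
    emit(paste0("artefact_", a),
         synth_config(duration_s = duration_s, artefacts = a,
                      seed = child_seed(seed, a)))
  }
  ca <- generate_calcium(last$ground_truth, n_rois = 8, lag_s = 0.311,
                         frame_rate_hz = 30,
                         seed = child_seed(seed, "calcium"))
  write_calcium_csv(ca, file.path(out_dir, "calcium.csv"))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    name = "calcium", recording = "calcium.csv", ground_truth = NA_character_,
    n_bouts = nrow(last$ground_truth$bouts))
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "fixtures.csv"))
  invisible(manifest)
}
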