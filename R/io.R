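#' Read and write recordings, annotations and configs
#'
#' Recordings travel in two formats: a delimited text table with columns
#' `time_s`, `left_v`, `right_v` (values written to 9 significant digits,
#' so TSV round-trips agree to that precision) and R's native serialization
#' (`.rds`), which round-trips bit-exactly and carries the metadata.
#' Ground-truth annotations and generator/pipeline configs travel as JSON.
#'
#' @param recording a [new_recording()].
#' @param path file path.
#' @param sampling_rate_hz sampling rate to attach when reading TSV (if
#'   `NULL`, inferred from the median time step).
#' @name recording_io
NULL

#' @rdname recording_io
#' @export
write_recording_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "swim_recording"))
  df <- tibble::tibble(
    time_s = signif(recording$time_s, 9),
    left_v = signif(recording$left_v, 9),
    right_v = signif(recording$right_v, 9)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording_tsv <- function(path, sampling_rate_hz = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), left_v = readr::col_double(),
    right_v = readr::col_double()
  ))
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- 1 / stats::median(diff(df$time_s))
  }
  # regenerate the time base exactly from the rate to absorb the 9-digit
  # rounding of time stamps
  n <- nrow(df)
  new_recording((seq_len(n) - 1L) / sampling_rate_hz, df$left_v, df$right_v,
                sampling_rate_hz, metadata = list(source = path))
}

#' @rdname recording_io
#' @export
write_recording_rds <- function(recording, path) {
  stopifnot(inherits(recording, "swim_recording"))
  saveRDS(recording, path, version = 3)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording_rds <- function(path) {
  rec <- readRDS(path)
  stopifnot(inherits(rec, "swim_recording"))
  rec
}

#' @rdname recording_io
#' @param ground_truth a [new_ground_truth()].
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "swim_ground_truth"))
  payload <- list(
    bouts = ground_truth$bouts,
    freq_trajectory = ground_truth$freq_trajectory,
    bursts = ground_truth$bursts,
    spikes = ground_truth$spikes,
    injected_phase_deg = ground_truth$injected_phase_deg,
    artefacts = ground_truth$artefacts,
    duration_s = ground_truth$duration_s,
    sampling_rate_hz = ground_truth$sampling_rate_hz,
    calcium_lag_s = ground_truth$calcium_lag_s
  )
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname recording_io
#' @export
read_ground_truth_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(x, proto) {
    if (is.null(x) || length(x) == 0L || all(lengths(x) == 0L)) return(proto)
    tibble::as_tibble(lapply(x, unlist))
  }
  new_ground_truth(
    bouts = as_tbl(p$bouts, tibble::tibble(
      bout = integer(0), start_s = numeric(0), end_s = numeric(0),
      label = character(0), mean_freq_hz = numeric(0),
      crosses_30hz = logical(0))),
    freq_trajectory = as_tbl(p$freq_trajectory, tibble::tibble(
      bout = integer(0), time_s = numeric(0), freq_hz = numeric(0))),
    bursts = as_tbl(p$bursts, tibble::tibble(
      bout = integer(0), channel = character(0), start_s = numeric(0),
      end_s = numeric(0), n_spikes = integer(0))),
    spikes = as_tbl(p$spikes, tibble::tibble(
      bout = integer(0), channel = character(0), time_s = numeric(0))),
    injected_phase_deg = p$injected_phase_deg,
    artefacts = as_tbl(p$artefacts, tibble::tibble(
      bout = integer(0), type = character(0), time_s = numeric(0))),
    duration_s = p$duration_s,
    sampling_rate_hz = p$sampling_rate_hz,
    calcium_lag_s = p$calcium_lag_s %||% NA_real_
  )
}

#' @rdname recording_io
#' @param config a [synth_config()].
#' @export
write_synth_config_json <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_synth_config_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(synth_config))
  extra <- setdiff(names(p), allowed)
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  # JSON nulls and empty arrays come back as empty lists; drop them so the
  # constructor's defaults apply, and restore character types
  p <- p[!vapply(p, function(x) is.null(x) ||
                   (is.list(x) && length(x) == 0L), logical(1))]
  if (!is.null(p$artefacts)) p$artefacts <- as.character(unlist(p$artefacts))
  do.call(synth_config, p[intersect(names(p), allowed)])
}

#' @rdname recording_io
#' @param traces a `calcium_traces` object.
#' @export
write_calcium_csv <- function(traces, path) {
  stopifnot(inherits(traces, "calcium_traces"))
  df <- tibble::as_tibble(as.data.frame(traces$f))
  df <- dplyr::bind_cols(tibble::tibble(frame_time_s = traces$frame_times_s), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_calcium_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  ft <- df$frame_time_s
  f <- as.matrix(df[setdiff(names(df), "frame_time_s")])
  structure(
    list(frame_times_s = ft, f = f,
         frame_rate_hz = 1 / stats::median(diff(ft)),
         lag_s = NA_real_, kernel_tau_s = NA_real_),
    class = "calcium_traces"
  )
}
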