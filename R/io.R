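#' Read a uniformly sampled time series from CSV
#'
#' Expects a comma-separated file with a header, a `time_s` column
#' (monotone, uniform step; relative jitter below `1e-6`), and one numeric
#' column per signal.
#'
#' @param path Path to the CSV file.
#' @param columns Optional character vector of required signal columns.
#' @return A list with `time` (numeric vector), `dt` (validated sampling
#'   interval), and `data` (data.frame of the signal columns).
#' @export
read_timeseries <- function(path, columns = NULL) {
  if (!file.exists(path)) {
    abort_iba(sprintf("file not found: %s", path), "iba_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("time_s" %in% names(df))) {
    abort_iba(sprintf("%s: missing required column 'time_s'", path),
              "iba_format_error")
  }
  for (col in columns) {
    if (!(col %in% names(df))) {
      abort_iba(sprintf("%s: missing required column '%s'", path, col),
                "iba_format_error")
    }
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort_iba(sprintf("%s: non-numeric value in column '%s' at data row %d",
                        path, col, if (is.na(bad)) 1L else bad),
                "iba_format_error")
    }
  }
  t <- df$time_s
  if (length(t) < 2L) {
    abort_iba(sprintf("%s: need at least 2 rows", path), "iba_format_error")
  }
  dts <- diff(t)
  if (any(dts <= 0)) {
    abort_iba(sprintf("%s: time_s is not strictly increasing (first at row %d)",
                      path, which(dts <= 0)[1] + 1L), "iba_format_error")
  }
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt) {
    abort_iba(sprintf("%s: non-uniform sampling (relative jitter %.3g)",
                      path, max(abs(dts - dt)) / dt), "iba_format_error")
  }
  sig <- df[setdiff(names(df), "time_s")]
  list(time = t, dt = dt, data = sig)
}

#' Read an EMG recording from CSV
#'
#' @param path CSV with `time_s` plus one column per EMG channel.
#' @param channel Column to read; defaults to the single non-time column.
#' @param condition Condition label for the recording.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, channel = NULL,
                         condition = c("NoExo", "Exo", "MVC")) {
  condition <- match.arg(condition)
  ts <- read_timeseries(path, columns = channel)
  if (is.null(channel)) {
    if (ncol(ts$data) != 1L) {
      abort_iba(sprintf("%s: specify `channel`; file has columns %s", path,
                        paste(names(ts$data), collapse = ", ")),
                "iba_format_error")
    }
    channel <- names(ts$data)[1]
  }
  emg_recording(ts$data[[channel]], dt = ts$dt, channel = channel,
                condition = condition)
}

#' Read a joint-angle signal from CSV
#'
#' @param path CSV with `time_s` and an angle column in degrees.
#' @param column Angle column; defaults to the single non-time column.
#' @param joint Joint label.
#' @return An [angle_signal()].
#' @export
read_angle_csv <- function(path, column = NULL, joint = "hip") {
  ts <- read_timeseries(path, columns = column)
  if (is.null(column)) {
    if (ncol(ts$data) != 1L) {
      abort_iba(sprintf("%s: specify `column`; file has columns %s", path,
                        paste(names(ts$data), collapse = ", ")),
                "iba_format_error")
    }
    column <- names(ts$data)[1]
  }
  angle_signal(ts$data[[column]], dt = ts$dt, joint = joint)
}

#' Write one or more signals to a time-series CSV
#'
#' @param signals Named list (or data.frame) of equal-length numeric
#'   vectors.
#' @param dt Sampling interval in seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(signals, dt, path) {
  dt <- check_dt(dt)
  signals <- as.data.frame(signals)
  n <- nrow(signals)
  df <- cbind(data.frame(time_s = (seq_len(n) - 1L) * dt), signals)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read timed phase boundaries from CSV
#'
#' @param path CSV with columns `label`, `start_s`, `end_s`.
#' @return A `data.frame` suitable for [timed_phases()].
#' @export
read_phase_boundaries <- function(path) {
  if (!file.exists(path)) {
    abort_iba(sprintf("file not found: %s", path), "iba_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    abort_iba(sprintf("%s: phase file needs columns %s", path,
                      paste(need, collapse = ", ")), "iba_format_error")
  }
  df[need]
}

#' Write a phase map as timed boundaries
#'
#' Segment `[start, end]` (samples) maps to `[(start-1)*dt, end*dt)`
#' seconds, so a round trip through [timed_phases()] restores the map
#' exactly.
#'
#' @param phases A [phase_map()].
#' @param dt Sampling interval of the mapped signal.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_boundaries <- function(phases, dt, path) {
  stopifnot(inherits(phases, "phase_map"))
  dt <- check_dt(dt)
  utils::write.csv(data.frame(label = phases$label,
                              start_s = (phases$start - 1L) * dt,
                              end_s = phases$end * dt),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trial to a bundle directory
#'
#' Serialises a [simulate_trial()] result to the same delimited-text formats
#' the analysis consumes: `emg_noexo.csv`, `emg_exo.csv`, `emg_mvc.csv`
#' (time + channel column), `angle.csv`, `phases.csv` (timed boundaries of
#' the true phase map), and `ground_truth.json` (spec parameters and true
#' indices).
#'
#' @param trial An `iba_trial` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(trial, dir) {
  stopifnot(inherits(trial, "iba_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- 1 / trial$spec$fs
  ch <- trial$spec$channel
  wr <- function(rec, name) {
    sig <- stats::setNames(list(rec$values), ch)
    write_timeseries_csv(sig, rec$dt, file.path(dir, name))
  }
  wr(trial$raw$noexo, "emg_noexo.csv")
  wr(trial$raw$exo, "emg_exo.csv")
  wr(trial$raw$mvc, "emg_mvc.csv")
  write_timeseries_csv(list(angle_deg = trial$angle$values), trial$angle$dt,
                       file.path(dir, "angle.csv"))
  write_phase_boundaries(trial$truth$phases, dt, file.path(dir, "phases.csv"))
  truth <- list(
    channel = ch,
    fs = trial$spec$fs,
    alpha = as.list(trial$spec$alpha),
    alpha_upright = trial$spec$alpha_upright,
    noise_sd = trial$spec$noise_sd,
    seed = trial$spec$seed,
    indices = trial$truth$indices)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Manifest row for a simulated trial bundle
#'
#' Builds the one-row study manifest that points [run_pipeline()] at the
#' files of a [write_trial_bundle()] directory.
#'
#' @param dir Bundle directory.
#' @param subject,device Labels for the manifest row.
#' @param muscle Channel name; defaults to the bundle's `ground_truth.json`
#'   channel.
#' @return A one-row `data.frame` manifest.
#' @export
bundle_manifest <- function(dir, subject = "S01", device = "ExoA",
                            muscle = NULL) {
  if (is.null(muscle)) {
    gt_path <- file.path(dir, "ground_truth.json")
    muscle <- if (file.exists(gt_path)) {
      jsonlite::read_json(gt_path)$channel
    } else {
      "emg"
    }
  }
  data.frame(subject = subject, device = device, muscle = muscle,
             emg_noexo = file.path(dir, "emg_noexo.csv"),
             emg_exo = file.path(dir, "emg_exo.csv"),
             mvc = file.path(dir, "emg_mvc.csv"),
             angle_noexo = file.path(dir, "angle.csv"),
             angle_exo = file.path(dir, "angle.csv"),
             stringsAsFactors = FALSE)
}
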