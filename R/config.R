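#' Default analysis configuration
#'
#' Central registry of the tunable processing parameters. Values follow the
#' standard offline surface-EMG chain: 30-400 Hz fourth-order Butterworth
#' band-pass, 2.5 Hz fourth-order low-pass envelope, 95th-percentile MVC
#' reference, 15 degree bending threshold with 2 degree hysteresis, and 1000
#' samples per phase after time normalization.
#'
#' @param ... Named overrides, e.g. `iba_config(bandpass = list(low_hz = 20))`.
#'   Unnamed groups keep their defaults; within a group only the named keys
#'   are replaced.
#' @return A nested list of configuration groups.
#' @export
#' @examples
#' cfg <- iba_config(segment = list(threshold_deg = 20))
#' cfg$segment$threshold_deg
iba_config <- function(...) {
  cfg <- list(
    bandpass = list(low_hz = 30, high_hz = 400, order = 4L),
    envelope = list(cutoff_hz = 2.5, order = 4L),
    mvc      = list(percentile = 0.95),
    segment  = list(threshold_deg = 15, hysteresis_deg = 2,
                    min_dwell_s = 0.25, plateau_rate_deg_s = 2,
                    rate_smooth_s = 0.05),
    align    = list(samples_per_phase = 1000L)
  )
  merge_config(cfg, list(...))
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the built-in defaults; everything else
#' keeps its default value.
#'
#' @param path Path to a YAML file whose top-level keys match the groups of
#'   [iba_config()].
#' @param base Configuration to merge onto (defaults to [iba_config()]).
#' @return A configuration list.
#' @export
read_config <- function(path, base = iba_config()) {
  if (!file.exists(path)) {
    abort_iba(sprintf("config file not found: %s", path), "iba_format_error")
  }
  merge_config(base, yaml::read_yaml(path))
}

merge_config <- function(base, overrides) {
  if (length(overrides) == 0L) return(base)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    abort_iba("configuration overrides must be named", "iba_validation")
  }
  for (key in names(overrides)) {
    if (is.list(base[[key]]) && is.list(overrides[[key]])) {
      base[[key]] <- merge_config(base[[key]], overrides[[key]])
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

# One "key = value" line per leaf, used by run_pipeline to log every default
# that fired exactly once.
config_lines <- function(cfg, prefix = "") {
  out <- character(0)
  for (key in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (is.list(cfg[[key]])) {
      out <- c(out, config_lines(cfg[[key]], full))
    } else {
      out <- c(out, sprintf("%s = %s", full, format(cfg[[key]])))
    }
  }
  out
}
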