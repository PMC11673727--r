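#' Raw surface-EMG recording
#'
#' Container for a uniformly sampled raw EMG trace in its native amplitude
#' units (e.g. mV), prior to filtering and normalization.
#'
#' @param values Numeric vector of signed amplitudes.
#' @param dt Sampling interval in seconds (single positive number).
#' @param channel Muscle label, e.g. `"erector_spinae"`.
#' @param condition One of `"NoExo"`, `"Exo"`, `"MVC"`.
#' @return An object of class `emg_recording` with fields `values`, `dt`,
#'   `channel`, `condition`.
#' @seealso [process_emg()] for the full processing chain.
#' @export
#' @examples
#' rec <- emg_recording(sin(seq(0, 1, by = 1e-3)), dt = 1e-3, channel = "es")
emg_recording <- function(values, dt,
                          channel = "emg",
                          condition = c("NoExo", "Exo", "MVC")) {
  condition <- match.arg(condition)
  dt <- check_dt(dt)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    abort_iba("a recording needs at least 2 samples", "iba_validation")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort_iba("recording contains non-finite samples", "iba_format_error")
  }
  structure(list(values = values, dt = dt,
                 channel = as.character(channel)[1], condition = condition),
            class = "emg_recording")
}

#' Processed EMG activation envelope
#'
#' A nonnegative, MVC-normalized activation trace in %MVC. This is the object
#' every interaction index consumes.
#'
#' @param values Numeric vector of activations (%MVC), all `>= 0`.
#' @inheritParams emg_recording
#' @param condition One of `"NoExo"`, `"Exo"`.
#' @return An object of class `emg_envelope`.
#' @export
emg_envelope <- function(values, dt, channel = "emg",
                         condition = c("NoExo", "Exo")) {
  condition <- match.arg(condition)
  dt <- check_dt(dt)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    abort_iba("an envelope needs at least 2 samples", "iba_validation")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    abort_iba("envelope contains non-finite samples", "iba_format_error")
  }
  if (any(values < 0)) {
    abort_iba("envelope values must be nonnegative (%MVC)", "iba_validation")
  }
  structure(list(values = values, dt = dt,
                 channel = as.character(channel)[1], condition = condition),
            class = "emg_envelope")
}

#' Joint-rotation signal
#'
#' Uniformly sampled joint angle in degrees (flexion positive), used to
#' segment the task into phases.
#'
#' @param values Numeric vector of angles in degrees. May be empty.
#' @param dt Sampling interval in seconds.
#' @param joint Joint label, e.g. `"hip"` or `"sternum"`.
#' @return An object of class `angle_signal`.
#' @seealso [detect_phases()]
#' @export
angle_signal <- function(values, dt, joint = "hip") {
  dt <- check_dt(dt)
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values))) {
    abort_iba("angle signal contains non-finite samples", "iba_format_error")
  }
  structure(list(values = values, dt = dt, joint = as.character(joint)[1]),
            class = "angle_signal")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s [%s]: %d samples @ %g Hz (%.2f s)\n",
              x$channel, x$condition, length(x$values), 1 / x$dt,
              length(x$values) * x$dt))
  invisible(x)
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf(
    "<emg_envelope> %s [%s]: %d samples @ %g Hz, range %.2f-%.2f %%MVC\n",
    x$channel, x$condition, length(x$values), 1 / x$dt,
    min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.angle_signal <- function(x, ...) {
  cat(sprintf("<angle_signal> %s: %d samples @ %g Hz\n",
              x$joint, length(x$values), 1 / x$dt))
  invisible(x)
}
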