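#' Band-pass filter a raw EMG recording
#'
#' Fourth-order (per pass) Butterworth band-pass, applied forward-backward so
#' the output is zero-phase: index computation requires temporal alignment
#' between conditions, and any group delay would corrupt the interaction
#' trend. The default 30-400 Hz band removes motion artifact and baseline
#' drift below 30 Hz and out-of-band noise above 400 Hz. The filter is
#' designed fresh for the recording's sampling rate and validated against
#' Nyquist.
#'
#' @param rec An [emg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * rec$dt)`.
#' @param order Butterworth design order per pass (default 4).
#' @return An `emg_recording` of the same length, zero-mean in the pass band.
#' @export
#' @examples
#' rec <- emg_recording(rnorm(2000), dt = 1e-3)
#' filtered <- bandpass_filter(rec)
bandpass_filter <- function(rec, low_hz = 30, high_hz = 400, order = 4L) {
  stopifnot(inherits(rec, "emg_recording") || inherits(rec, "emg_envelope"))
  nyq <- nyquist(rec)
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && low_hz < high_hz)) {
    abort_iba("need 0 < low_hz < high_hz", "iba_invalid_cutoff")
  }
  if (high_hz >= nyq) {
    abort_iba(sprintf("high_hz (%g) must be below Nyquist (%g Hz)",
                      high_hz, nyq), "iba_invalid_cutoff")
  }
  if (!(order >= 1)) abort_iba("order must be >= 1", "iba_validation")
  sos <- butter_sos(order, c(low_hz, high_hz) / nyq, type = "pass")
  rec$values <- zero_phase_filter(sos, rec$values)
  rec
}

#' Full-wave rectify a recording
#'
#' @param rec An [emg_recording()].
#' @return The recording with `values` replaced by their absolute values.
#' @export
rectify <- function(rec) {
  stopifnot(inherits(rec, "emg_recording") || inherits(rec, "emg_envelope"))
  rec$values <- abs(rec$values)
  rec
}

#' Low-pass envelope extraction
#'
#' Fourth-order (per pass) zero-phase Butterworth low-pass, by default at
#' 2.5 Hz, applied to the rectified signal to obtain the activation envelope.
#' Zero-phase filtering of a rectified signal can undershoot slightly;
#' residual negative samples are clamped to 0 because the downstream indices
#' interpret the envelope as nonnegative neural energy. The clamping
#' magnitude is recorded in the `"clamp"` attribute
#' (`list(n, max_abs, fraction)`).
#'
#' @param rec A rectified [emg_recording()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 2.5).
#' @param order Butterworth design order per pass (default 4).
#' @return An `emg_recording` holding the smoothed nonnegative envelope.
#' @export
lowpass_envelope <- function(rec, cutoff_hz = 2.5, order = 4L) {
  stopifnot(inherits(rec, "emg_recording") || inherits(rec, "emg_envelope"))
  nyq <- nyquist(rec)
  if (!(is.numeric(cutoff_hz) && cutoff_hz > 0 && cutoff_hz < nyq)) {
    abort_iba(sprintf("cutoff_hz must lie in (0, %g)", nyq),
              "iba_invalid_cutoff")
  }
  if (!(order >= 1)) abort_iba("order must be >= 1", "iba_validation")
  sos <- butter_sos(order, cutoff_hz / nyq, type = "low")
  y <- zero_phase_filter(sos, rec$values)
  neg <- y < 0
  clamp <- list(n = sum(neg),
                max_abs = if (any(neg)) max(-y[neg]) else 0,
                fraction = mean(neg))
  y[neg] <- 0
  rec$values <- y
  attr(rec, "clamp") <- clamp
  rec
}

#' MVC normalization reference
#'
#' Takes the 95th percentile (by default) of a processed maximum-voluntary-
#' contraction envelope as the 100% activation reference. The percentile is
#' computed by linear interpolation between closest order statistics
#' (`stats::quantile` type 7), stated explicitly so results are reproducible.
#'
#' @param mvc_env The processed (band-passed, rectified, low-passed) MVC
#'   trial, as an `emg_recording`.
#' @param percentile Fraction in (0, 1); default 0.95.
#' @return An object of class `mvc_reference` with fields `channel`,
#'   `reference`, `percentile`.
#' @export
mvc_reference <- function(mvc_env, percentile = 0.95) {
  stopifnot(inherits(mvc_env, "emg_recording") ||
              inherits(mvc_env, "emg_envelope"))
  if (!(is.numeric(percentile) && length(percentile) == 1L &&
        percentile > 0 && percentile < 1)) {
    abort_iba("percentile must lie in (0, 1)", "iba_validation")
  }
  ref <- unname(stats::quantile(mvc_env$values, probs = percentile,
                                type = 7, names = FALSE))
  if (!is.finite(ref) || ref <= 0) {
    abort_iba("degenerate MVC reference: processed MVC envelope is all zero",
              "iba_degenerate")
  }
  structure(list(channel = mvc_env$channel, reference = ref,
                 percentile = percentile),
            class = "mvc_reference")
}

#' Normalize a processed envelope to %MVC
#'
#' @param env Fully processed envelope recording (same units as the MVC
#'   reference).
#' @param ref An [mvc_reference()] for the same channel.
#' @return An [emg_envelope()] in %MVC.
#' @export
normalize_to_mvc <- function(env, ref) {
  stopifnot(inherits(ref, "mvc_reference"))
  stopifnot(inherits(env, "emg_recording") || inherits(env, "emg_envelope"))
  if (!identical(env$channel, ref$channel)) {
    abort_iba(sprintf("channel mismatch: envelope '%s' vs MVC reference '%s'",
                      env$channel, ref$channel), "iba_mismatch")
  }
  if (env$condition == "MVC") {
    abort_iba("normalize the task recordings, not the MVC trial itself",
              "iba_validation")
  }
  emg_envelope(100 * pmax(env$values, 0) / ref$reference,
               dt = env$dt, channel = env$channel, condition = env$condition)
}

#' Full EMG processing chain
#'
#' Composes band-pass, rectification, low-pass envelope extraction, and MVC
#' normalization. The MVC trial is processed with the identical chain before
#' its percentile is taken, keeping the units of the reference commensurate
#' with the task envelope.
#'
#' @param raw Task [emg_recording()] (`NoExo` or `Exo`).
#' @param mvc_raw Raw MVC [emg_recording()] for the same channel and
#'   sampling rate.
#' @param config Configuration list, see [iba_config()].
#' @return An [emg_envelope()] in %MVC. The MVC reference is attached as the
#'   `"mvc"` attribute and the low-pass clamping report as `"clamp"`.
#' @export
#' @examples
#' spec <- trial_spec(seed = 7)
#' trial <- simulate_trial(spec)
#' env <- process_emg(trial$raw$noexo, trial$raw$mvc)
process_emg <- function(raw, mvc_raw, config = iba_config()) {
  stopifnot(inherits(raw, "emg_recording"), inherits(mvc_raw, "emg_recording"))
  if (abs(raw$dt - mvc_raw$dt) > 1e-9 * raw$dt) {
    abort_iba("task and MVC recordings must share the sampling interval",
              "iba_mismatch")
  }
  chain <- function(rec) {
    lowpass_envelope(
      rectify(
        bandpass_filter(rec,
                        low_hz = config$bandpass$low_hz,
                        high_hz = config$bandpass$high_hz,
                        order = config$bandpass$order)),
      cutoff_hz = config$envelope$cutoff_hz,
      order = config$envelope$order)
  }
  task_env <- chain(raw)
  ref <- mvc_reference(chain(mvc_raw), percentile = config$mvc$percentile)
  out <- normalize_to_mvc(task_env, ref)
  attr(out, "mvc") <- ref
  attr(out, "clamp") <- attr(task_env, "clamp")
  out
}

#' @export
print.mvc_reference <- function(x, ...) {
  cat(sprintf("<mvc_reference> %s: %.4g (p = %.2f)\n",
              x$channel, x$reference, x$percentile))
  invisible(x)
}
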