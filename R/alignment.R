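#' Time-normalize an envelope phase by phase
#'
#' Resamples each phase onto `samples_per_phase` equally spaced points over
#' its own duration, by linear interpolation, so that trials performed at
#' different speeds become pointwise comparable. Linear interpolation cannot
#' overshoot, so envelope nonnegativity is preserved, and each phase's
#' endpoint values are preserved exactly. The operation is idempotent on its
#' own output.
#'
#' @param env An [emg_envelope()] (or any recording-like object).
#' @param phases A [phase_map()] indexing `env`.
#' @param samples_per_phase Target samples per phase (default 1000, ample for
#'   a 2.5 Hz envelope over phases lasting seconds).
#' @return A list with elements `envelope` (the resampled signal, spanning
#'   only the mapped phases) and `phases` (the new map: phase `k` occupies
#'   samples `[(k-1)*samples_per_phase + 1, k*samples_per_phase]`).
#' @export
#' @examples
#' env <- emg_envelope(abs(sin(seq(0, pi, length.out = 400))), dt = 0.01)
#' ph <- phase_map("task", 1, 400)
#' out <- time_normalize(env, ph, samples_per_phase = 100)
time_normalize <- function(env, phases, samples_per_phase = 1000L) {
  stopifnot(inherits(phases, "phase_map"))
  samples_per_phase <- as.integer(samples_per_phase)
  if (!(samples_per_phase >= 2L)) {
    abort_iba("samples_per_phase must be >= 2", "iba_validation")
  }
  n <- length(env$values)
  if (nrow(phases) == 0L) {
    abort_iba("phase map is empty", "iba_degenerate")
  }
  if (max(phases$end) > n) {
    abort_iba("phase map indexes beyond the end of the signal",
              "iba_validation")
  }
  pieces <- vector("list", nrow(phases))
  for (k in seq_len(nrow(phases))) {
    a <- phases$start[k]; b <- phases$end[k]
    m <- b - a + 1L
    if (m < 2L) {
      abort_iba(sprintf("phase '%s' spans fewer than 2 samples",
                        phases$label[k]), "iba_degenerate")
    }
    xout <- seq(a, b, length.out = samples_per_phase)
    pieces[[k]] <- stats::approx(x = a:b, y = env$values[a:b],
                                 xout = xout)$y
  }
  values <- unlist(pieces, use.names = FALSE)
  total_dur <- sum(phases$end - phases$start + 1L) * env$dt
  out <- env
  out$values <- values
  out$dt <- total_dur / length(values)
  k <- nrow(phases)
  new_map <- phase_map(phases$label,
                       start = (seq_len(k) - 1L) * samples_per_phase + 1L,
                       end = seq_len(k) * samples_per_phase)
  list(envelope = out, phases = new_map)
}

#' Aligned NoExo/Exo envelope pair
#'
#' Constructs the container the interaction indices consume: two envelopes on
#' a common grid with a shared phase map. Use [align_pair()] to build one
#' from raw phase maps that need resampling; use this constructor directly
#' when the envelopes are already pointwise comparable.
#'
#' @param noexo,exo [emg_envelope()] objects of identical length for the same
#'   muscle.
#' @param phases Common [phase_map()]; defaults to one segment labelled
#'   `"task"` spanning the record.
#' @param samples_per_phase Samples per phase, if the pair was resampled.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(noexo, exo, phases = NULL,
                         samples_per_phase = NULL) {
  stopifnot(inherits(noexo, "emg_envelope"), inherits(exo, "emg_envelope"))
  n <- length(noexo$values)
  if (length(exo$values) != n) {
    abort_iba("NoExo and Exo envelopes must have identical length",
              "iba_alignment")
  }
  if (!identical(noexo$channel, exo$channel)) {
    abort_iba("NoExo and Exo envelopes are from different channels",
              "iba_mismatch")
  }
  if (is.null(phases)) {
    phases <- phase_map("task", 1L, n)
  }
  stopifnot(inherits(phases, "phase_map"))
  if (nrow(phases) == 0L || max(phases$end) > n) {
    abort_iba("phase map does not index the pair correctly",
              "iba_validation")
  }
  structure(list(noexo = noexo, exo = exo, phases = phases,
                 samples_per_phase = samples_per_phase),
            class = "aligned_pair")
}

#' Align a NoExo/Exo pair onto a common per-phase grid
#'
#' Both envelopes are time-normalized phase by phase (see
#' [time_normalize()]) so that every phase has `samples_per_phase` samples in
#' both conditions. The two phase maps must contain the same labels in the
#' same order; the phases themselves may differ in duration (the conditions
#' are recorded in separate trials and are never perfectly isochronous).
#'
#' @param noexo_env,exo_env [emg_envelope()] objects for the two conditions.
#' @param noexo_phases,exo_phases [phase_map()]s for the respective
#'   recordings, with identical label sequences.
#' @param samples_per_phase Target samples per phase (default 1000).
#' @return An [aligned_pair()].
#' @export
#' @examples
#' spec <- trial_spec(seed = 3)
#' tr <- simulate_trial(spec)
#' pair <- align_pair(tr$truth$noexo, tr$truth$exo,
#'                    tr$truth$phases, tr$truth$phases)
align_pair <- function(noexo_env, exo_env, noexo_phases, exo_phases,
                       samples_per_phase = 1000L) {
  stopifnot(inherits(noexo_phases, "phase_map"),
            inherits(exo_phases, "phase_map"))
  if (!identical(noexo_phases$label, exo_phases$label)) {
    abort_iba(
      "phase label sequences differ between conditions; cannot align",
      "iba_alignment")
  }
  a <- time_normalize(noexo_env, noexo_phases, samples_per_phase)
  b <- time_normalize(exo_env, exo_phases, samples_per_phase)
  aligned_pair(a$envelope, b$envelope, a$phases,
               samples_per_phase = as.integer(samples_per_phase))
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "<aligned_pair> %s: %d samples, %d phase(s)%s\n",
    x$noexo$channel, length(x$noexo$values), nrow(x$phases),
    if (is.null(x$samples_per_phase)) ""
    else sprintf(" (%d samples/phase)", x$samples_per_phase)))
  invisible(x)
}
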