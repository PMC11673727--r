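#' Specification of a synthetic paired trial
#'
#' Defines a bend-hold-rise trunk task with a known per-phase
#' assistance/resistance profile, from which paired NoExo/Exo raw EMG,
#' a joint-angle trajectory, and an MVC trial can be generated with exact
#' ground truth. Defaults emulate a static fine-positioning task: about 8 s
#' of bent-over holding flanked by a few seconds of bending and rising, a
#' 60 degree bent trunk angle, 1 kHz sampling, a 30-400 Hz Gaussian carrier,
#' and phase activation peaks on the %MVC scale typical of back-muscle
#' recordings (high in bending/rising, low during holding, small tonic
#' baseline while upright).
#'
#' The exoskeleton condition scales the baseline envelope by the per-phase
#' ratio `alpha` (1 = no effect, below 1 = assistance, above 1 =
#' resistance); a ratio alpha over a phase yields a ground-truth per-phase
#' OII of `100 * (1 - alpha)`. Alpha transitions are smoothed with a cosine
#' kernel of width `taper_s` so the 2.5 Hz envelope filter has no
#' discontinuities to ring on. The default alphas (0.71, 0.81, 0.90) mirror
#' per-phase overall indices of roughly 29, 19, and 10 percent.
#'
#' @param phase_durations Named seconds for `bending`, `position_holding`,
#'   `rising_up`.
#' @param rest_s Upright rest before, between, and after cycles (seconds).
#' @param cycles Number of bend-hold-rise repetitions.
#' @param fs Sampling rate in Hz; must exceed twice the carrier band top.
#' @param envelope_peaks Named peak activations (%MVC) per phase.
#' @param baseline_pct Tonic upright activation (%MVC).
#' @param alpha Named per-phase envelope ratios Exo/NoExo.
#' @param alpha_upright Ratio while upright (default 1: device disengaged
#'   below the bending threshold).
#' @param bent_angle_deg Plateau trunk-flexion angle (degrees).
#' @param carrier_band `c(low, high)` Hz band of the Gaussian carrier.
#' @param noise_sd Relative s.d. of the slow multiplicative envelope jitter.
#' @param mvc_level MVC trial activation level (%MVC scale of the
#'   generator).
#' @param mvc_duration_s Duration of the MVC trial (seconds).
#' @param taper_s Width of the alpha smoothing kernel (seconds).
#' @param channel Muscle label stamped on generated signals.
#' @param seed Base RNG seed; every generated signal is a pure function of
#'   the spec and this seed.
#' @return An object of class `trial_spec`.
#' @export
#' @examples
#' spec <- trial_spec(alpha = c(bending = 0.7, position_holding = 0.6,
#'                              rising_up = 0.9), seed = 42)
trial_spec <- function(phase_durations = c(bending = 3, position_holding = 8,
                                           rising_up = 3),
                       rest_s = 2,
                       cycles = 1L,
                       fs = 1000,
                       envelope_peaks = c(bending = 80,
                                          position_holding = 5,
                                          rising_up = 80),
                       baseline_pct = 2,
                       alpha = c(bending = 0.71, position_holding = 0.81,
                                 rising_up = 0.90),
                       alpha_upright = 1,
                       bent_angle_deg = 60,
                       carrier_band = c(30, 400),
                       noise_sd = 0.05,
                       mvc_level = 100,
                       mvc_duration_s = 5,
                       taper_s = 0.1,
                       channel = "erector_spinae",
                       seed = 1L) {
  need <- c("bending", "position_holding", "rising_up")
  if (!all(need %in% names(phase_durations)) ||
      !all(need %in% names(envelope_peaks)) ||
      !all(need %in% names(alpha))) {
    abort_iba(
      "phase_durations, envelope_peaks and alpha need entries for bending, position_holding, rising_up",
      "iba_validation")
  }
  if (any(phase_durations <= 0)) {
    abort_iba("phase durations must be positive", "iba_validation")
  }
  if (any(envelope_peaks < 0) || baseline_pct < 0) {
    abort_iba("envelope levels must be nonnegative", "iba_validation")
  }
  if (any(alpha < 0) || alpha_upright < 0) {
    abort_iba("alpha ratios must be nonnegative", "iba_validation")
  }
  if (!(fs > 2 * carrier_band[2])) {
    abort_iba("fs must exceed twice the carrier band top", "iba_validation")
  }
  if (cycles < 0) abort_iba("cycles must be >= 0", "iba_validation")
  structure(list(
    phase_durations = phase_durations[need], rest_s = rest_s,
    cycles = as.integer(cycles), fs = fs,
    envelope_peaks = envelope_peaks[need], baseline_pct = baseline_pct,
    alpha = alpha[need], alpha_upright = alpha_upright,
    bent_angle_deg = bent_angle_deg, carrier_band = carrier_band,
    noise_sd = noise_sd, mvc_level = mvc_level,
    mvc_duration_s = mvc_duration_s, taper_s = taper_s,
    channel = channel, seed = as.integer(seed)),
    class = "trial_spec")
}

# Segment layout (label + sample count per segment) for one trial.
trial_layout <- function(spec) {
  if (spec$cycles == 0L) {
    return(data.frame(label = character(0), n = integer(0)))
  }
  nseg <- function(d) max(2L, as.integer(round(d * spec$fs)))
  cycle <- data.frame(
    label = c("bending", "position_holding", "rising_up"),
    n = vapply(spec$phase_durations, nseg, integer(1)),
    stringsAsFactors = FALSE)
  rest <- data.frame(label = "upright", n = nseg(spec$rest_s))
  out <- rest
  for (k in seq_len(spec$cycles)) out <- rbind(out, cycle, rest)
  out
}

layout_phase_map <- function(layout) {
  if (nrow(layout) == 0L) return(phase_map())
  ends <- cumsum(layout$n)
  phase_map(layout$label, start = ends - layout$n + 1L, end = ends)
}

#' Simulate the trunk-angle trajectory of a trial
#'
#' Piecewise smooth flexion trajectory: cosine ramp up to the bent angle
#' over the bending phase, constant plateau while holding, cosine ramp back
#' to upright over the rising phase, with upright rest between cycles.
#' Cosine ramps make the trajectory C1 at the corners.
#'
#' @param spec A [trial_spec()].
#' @return An [angle_signal()] (empty for zero cycles).
#' @export
simulate_angle <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  layout <- trial_layout(spec)
  dt <- 1 / spec$fs
  if (nrow(layout) == 0L) return(angle_signal(numeric(0), dt))
  A <- spec$bent_angle_deg
  pieces <- lapply(seq_len(nrow(layout)), function(k) {
    n <- layout$n[k]
    switch(layout$label[k],
           upright = rep(0, n),
           bending = A * (1 - cos(pi * seq_len(n) / n)) / 2,
           position_holding = rep(A, n),
           rising_up = A * (1 + cos(pi * seq_len(n) / n)) / 2)
  })
  angle_signal(unlist(pieces), dt)
}

# Tukey (cosine-tapered) window used for the holding plateau.
tukey_window <- function(n, frac) {
  frac <- min(1, max(0, frac))
  if (frac == 0) return(rep(1, n))
  s <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  h <- frac / 2
  lo <- s < h
  hi <- s > 1 - h
  w[lo] <- (1 - cos(pi * s[lo] / h)) / 2
  w[hi] <- (1 - cos(pi * (1 - s[hi]) / h)) / 2
  w
}

#' Simulate noise-free paired activation envelopes
#'
#' Builds the baseline (NoExo) activation envelope from per-phase shapes —
#' raised-cosine-squared bumps for bending and rising, a cosine-tapered
#' plateau for holding, tonic baseline while upright — and derives the Exo
#' envelope by multiplying with the smoothed per-phase `alpha` profile.
#'
#' @param spec A [trial_spec()].
#' @return A list: `noexo` and `exo` ([emg_envelope()]s, %MVC), `phases`
#'   (the true [phase_map()] including upright segments), and `alpha_trace`
#'   (the smoothed per-sample ratio actually applied).
#' @export
simulate_envelopes <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  layout <- trial_layout(spec)
  if (nrow(layout) == 0L) {
    abort_iba("cannot build envelopes for a zero-cycle trial",
              "iba_degenerate")
  }
  dt <- 1 / spec$fs
  base <- spec$baseline_pct
  shape <- function(label, n) {
    switch(label,
           upright = rep(base, n),
           bending = base + (spec$envelope_peaks[["bending"]] - base) *
             sin(pi * (seq_len(n) - 0.5) / n)^2,
           position_holding = base +
             (spec$envelope_peaks[["position_holding"]] - base) *
             tukey_window(n, 0.25),
           rising_up = base + (spec$envelope_peaks[["rising_up"]] - base) *
             sin(pi * (seq_len(n) - 0.5) / n)^2)
  }
  eno <- unlist(lapply(seq_len(nrow(layout)), function(k) {
    shape(layout$label[k], layout$n[k])
  }))
  alpha_of <- function(label) {
    if (label == "upright") spec$alpha_upright else spec$alpha[[label]]
  }
  alpha_raw <- unlist(lapply(seq_len(nrow(layout)), function(k) {
    rep(alpha_of(layout$label[k]), layout$n[k])
  }))
  alpha_s <- smooth_cosine(alpha_raw, round(spec$taper_s * spec$fs))
  phases <- layout_phase_map(layout)
  list(noexo = emg_envelope(eno, dt, spec$channel, "NoExo"),
       exo = emg_envelope(eno * alpha_s, dt, spec$channel, "Exo"),
       phases = phases,
       alpha_trace = alpha_s)
}

# Raised-cosine kernel smoothing with edge replication; leaves constants
# unchanged.
smooth_cosine <- function(x, width) {
  width <- as.integer(width)
  if (width < 3L || length(x) < 3L) return(x)
  if (all(x == x[1])) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  k <- 0.5 * (1 - cos(2 * pi * seq_len(width) / (width + 1)))
  k <- k / sum(k)
  half <- (width - 1L) %/% 2L
  xe <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xe, k, sides = 2))[(half + 1):(half + length(x))]
}

#' Synthesize raw surface EMG from an activation envelope
#'
#' Models the raw signal as a band-limited Gaussian carrier amplitude-
#' modulated by the activation envelope, with slow multiplicative jitter of
#' relative s.d. `noise_sd` emulating trial-to-trial amplitude variability.
#' The carrier is white Gaussian noise band-passed to `carrier_band` and
#' scaled to unit variance, so the raw amplitude scale is the envelope scale
#' (in envelope units / 100).
#'
#' @param env An [emg_envelope()] (noise-free activation, %MVC scale).
#' @param spec A [trial_spec()] providing `carrier_band`, `noise_sd`, `fs`.
#' @param seed RNG seed (default `spec$seed`); same seed, same samples.
#' @param condition Condition stamped on the output recording.
#' @return An [emg_recording()].
#' @export
synthesize_raw_emg <- function(env, spec, seed = spec$seed,
                               condition = env$condition) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- length(env$values)
  nyq <- spec$fs / 2
  with_seed(seed, {
    bf <- butter_sos(4, spec$carrier_band / nyq, type = "pass")
    carrier <- zero_phase_filter(bf, stats::rnorm(n))
    s <- stats::sd(carrier)
    if (s > 0) carrier <- carrier / s
    gain <- rep(1, n)
    if (spec$noise_sd > 0) {
      lf <- butter_sos(2, 1 / nyq, type = "low")
      j <- zero_phase_filter(lf, stats::rnorm(n))
      sj <- stats::sd(j)
      if (sj > 0) gain <- pmax(0, 1 + j / sj * spec$noise_sd)
    }
    emg_recording(env$values / 100 * carrier * gain, dt = 1 / spec$fs,
                  channel = env$channel, condition = condition)
  })
}

#' Ground-truth interaction indices from noise-free envelopes
#'
#' Reference computation of the interaction indices directly from the
#' generator's noise-free envelopes — the recovery target for pipeline
#' tests. Uses the same normalized-difference definition as [i_trend()] and
#' [interaction_indices()] but is written as an independent code path.
#'
#' @param noexo,exo Noise-free [emg_envelope()]s on a common grid.
#' @param phases The true [phase_map()].
#' @param scope `"full_task"`, `"per_phase"`, or both (default).
#' @return A `data.frame` with columns `scope`, `phase`, `aii`, `rii`,
#'   `oii`.
#' @export
ground_truth_indices <- function(noexo, exo, phases,
                                 scope = c("full_task", "per_phase")) {
  scope <- match.arg(scope, several.ok = TRUE)
  if (length(noexo$values) != length(exo$values)) {
    abort_iba("envelopes are not aligned", "iba_alignment")
  }
  one <- function(scope_label, phase_label, a, b) {
    e0 <- noexo$values[a:b]
    e1 <- exo$values[a:b]
    denom <- sum(e0)
    if (denom <= 0) {
      abort_iba("NoExo envelope integrates to zero over the segment",
                "iba_degenerate")
    }
    d <- 100 * (e0 - e1) / denom
    aii <- sum(d[d >= 0])
    rii <- abs(sum(d[d < 0]))
    data.frame(scope = scope_label, phase = phase_label,
               aii = aii, rii = rii, oii = aii - rii,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if ("full_task" %in% scope) {
    rows[[length(rows) + 1L]] <-
      one("full_task", "full_task", 1L, length(noexo$values))
  }
  if ("per_phase" %in% scope) {
    for (k in seq_len(nrow(phases))) {
      rows[[length(rows) + 1L]] <-
        one("per_phase", phases$label[k], phases$start[k], phases$end[k])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete paired trial
#'
#' Generates everything one experimental cell provides: the joint-angle
#' trajectory, raw NoExo/Exo/MVC EMG recordings, the noise-free envelopes,
#' the true phase map, and the ground-truth interaction indices. Sub-seeds
#' `seed`, `seed + 1`, `seed + 2` drive the NoExo, Exo, and MVC carriers.
#'
#' @param spec A [trial_spec()].
#' @return An object of class `iba_trial`: list with `spec`, `angle`, `raw`
#'   (`noexo`, `exo`, `mvc` recordings), and `truth` (`noexo`, `exo`
#'   envelopes, `phases`, `alpha_trace`, `indices`).
#' @seealso [write_trial_bundle()] to serialise it to CSV/JSON files.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  env <- simulate_envelopes(spec)
  angle <- simulate_angle(spec)
  n_mvc <- max(2L, as.integer(round(spec$mvc_duration_s * spec$fs)))
  mvc_env <- emg_envelope(rep(spec$mvc_level, n_mvc), 1 / spec$fs,
                          spec$channel, "NoExo")
  raw <- list(
    noexo = synthesize_raw_emg(env$noexo, spec, seed = spec$seed),
    exo = synthesize_raw_emg(env$exo, spec, seed = spec$seed + 1L),
    mvc = synthesize_raw_emg(mvc_env, spec, seed = spec$seed + 2L,
                             condition = "MVC"))
  truth <- list(noexo = env$noexo, exo = env$exo, phases = env$phases,
                alpha_trace = env$alpha_trace,
                indices = ground_truth_indices(env$noexo, env$exo,
                                               env$phases))
  structure(list(spec = spec, angle = angle, raw = raw, truth = truth),
            class = "iba_trial")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec> %d cycle(s) of bend/hold/rise = %g/%g/%g s @ %g Hz, alpha = %s, seed %d\n",
    x$cycles, x$phase_durations[["bending"]],
    x$phase_durations[["position_holding"]],
    x$phase_durations[["rising_up"]], x$fs,
    paste(sprintf("%.2f", x$alpha), collapse = "/"), x$seed))
  invisible(x)
}

#' @export
print.iba_trial <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d samples per condition, %d phases (ground-truth full-task OII %.2f%%)\n",
              length(x$truth$noexo$values), nrow(x$truth$phases),
              x$truth$indices$oii[x$truth$indices$scope == "full_task"]))
  invisible(x)
}
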