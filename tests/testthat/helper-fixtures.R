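# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except in the io tests, which write their own files first.

make_env <- function(values, dt = 1e-3, channel = "es",
                     condition = "NoExo") {
  emg_envelope(values, dt = dt, channel = channel, condition = condition)
}

make_rec <- function(values, dt = 1e-3, channel = "es",
                     condition = "NoExo") {
  emg_recording(values, dt = dt, channel = channel, condition = condition)
}

make_pair <- function(noexo_values, exo_values, dt = 1e-3, phases = NULL) {
  aligned_pair(make_env(noexo_values, dt = dt),
               make_env(exo_values, dt = dt, condition = "Exo"),
               phases = phases)
}

# Random nonnegative envelope pair of a given length; strictly positive
# NoExo so the normalizing integral is defined.
random_pair <- function(n) {
  make_pair(stats::runif(n, 0.01, 2) * stats::runif(1, 0.5, 50),
            stats::runif(n, 0, 2) * stats::runif(1, 0.5, 50))
}

# Complex-exponential magnitude response of a designed filter at frequency
# f_hz; the zero-phase (forward-backward) power gain is its square.
butter_gain <- function(flt, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  z <- exp(-1i * w * (seq_along(flt$b) - 1))
  num <- sum(flt$b * z)
  den <- sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  Mod(num / den)
}
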