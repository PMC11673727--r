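fs <- 1000
t5 <- seq(0, 5 - 1 / fs, by = 1 / fs)

test_that("band-pass keeps the EMG band and rejects out-of-band tones", {
  # zero in, zero out (linearity sanity)
  z <- bandpass_filter(make_rec(rep(0, 1000), dt = 1 / fs))
  expect_equal(z$values, rep(0, 1000))

  flt <- signal::butter(4, c(30, 400) / (fs / 2), type = "pass")
  tone <- function(f) sin(2 * pi * f * t5)
  ratio <- function(f) {
    out <- bandpass_filter(make_rec(tone(f), dt = 1 / fs))$values
    stats::sd(out) / stats::sd(tone(f))
  }
  # oracle: designed magnitude response, squared for forward-backward
  expect_lt(butter_gain(flt, 1, fs)^2, 0.05)
  expect_lt(ratio(1), 0.05)
  expect_equal(ratio(100), butter_gain(flt, 100, fs)^2, tolerance = 1e-3)
  expect_lt(abs(ratio(100) - 1), 0.05)
})

test_that("band-pass rejects invalid cutoffs and preserves length", {
  rec <- make_rec(rnorm(500), dt = 1 / fs)
  expect_error(bandpass_filter(rec, 30, 600), class = "iba_invalid_cutoff")
  expect_error(bandpass_filter(rec, 30, 500), class = "iba_invalid_cutoff")
  expect_error(bandpass_filter(rec, 400, 30), class = "iba_invalid_cutoff")
  expect_error(bandpass_filter(rec, -5, 400), class = "iba_invalid_cutoff")
  expect_length(bandpass_filter(rec)$values, 500)
})

test_that("filtering is linear and zero-phase", {
  set.seed(42)
  x <- rnorm(4000)
  rec1 <- bandpass_filter(make_rec(x, dt = 1 / fs))
  rec3 <- bandpass_filter(make_rec(3.7 * x, dt = 1 / fs))
  expect_equal(rec3$values, 3.7 * rec1$values, tolerance = 1e-9)

  # a symmetric pulse keeps its peak sample (+/- 1) through both filters
  pulse <- exp(-((1:4000) - 2000)^2 / (2 * 120^2))
  peak_bp <- which.max(bandpass_filter(make_rec(pulse, dt = 1 / fs))$values)
  peak_lp <- which.max(lowpass_envelope(make_rec(pulse, dt = 1 / fs))$values)
  expect_lte(abs(peak_bp - 2000), 1)
  expect_lte(abs(peak_lp - 2000), 1)
})

test_that("rectification is the absolute value and is idempotent", {
  rec <- make_rec(c(-1, 2, -3))
  expect_equal(rectify(rec)$values, c(1, 2, 3))
  nonneg <- make_rec(c(0, 1, 2))
  expect_equal(rectify(nonneg)$values, nonneg$values)
  expect_equal(rectify(rectify(rec))$values, rectify(rec)$values)
})

test_that("low-pass envelope has unit DC gain and recovers the mean of a rectified tone", {
  const <- lowpass_envelope(make_rec(rep(4.2, 3000), dt = 1 / fs))
  expect_equal(const$values, rep(4.2, 3000), tolerance = 1e-9)

  z <- lowpass_envelope(make_rec(rep(0, 1000), dt = 1 / fs))
  expect_equal(z$values, rep(0, 1000))

  # mean of |A sin| is 2A/pi
  A <- 2.5
  env <- lowpass_envelope(make_rec(A * abs(sin(2 * pi * 100 * t5)),
                                   dt = 1 / fs))
  expect_equal(mean(env$values), 2 * A / pi, tolerance = 0.05)
  expect_gte(min(env$values), 0)
  expect_type(attr(env, "clamp"), "list")
  expect_error(lowpass_envelope(make_rec(rnorm(100), dt = 1 / fs),
                                cutoff_hz = 600),
               class = "iba_invalid_cutoff")
})

test_that("MVC reference is the linear-interpolation percentile", {
  expect_equal(mvc_reference(make_rec(rep(7, 100)))$reference, 7)
  expect_equal(mvc_reference(make_rec(0:100), percentile = 0.95)$reference,
               95)
  expect_equal(mvc_reference(make_rec(c(10, 20)), percentile = 0.95)$reference,
               19.5)
  expect_error(mvc_reference(make_rec(rep(0, 50))), class = "iba_degenerate")
  expect_error(mvc_reference(make_rec(1:10), percentile = 1.2),
               class = "iba_validation")
})

test_that("MVC normalization scales to %MVC", {
  ref <- mvc_reference(make_rec(rep(8, 100)))
  expect_equal(normalize_to_mvc(make_rec(rep(8, 50)), ref)$values,
               rep(100, 50))
  expect_equal(normalize_to_mvc(make_rec(rep(0, 50)), ref)$values,
               rep(0, 50))
  expect_equal(normalize_to_mvc(make_rec(rep(4, 50)), ref)$values,
               rep(50, 50))
  other <- mvc_reference(make_rec(rep(8, 100), channel = "rf"))
  expect_error(normalize_to_mvc(make_rec(rep(4, 50)), other),
               class = "iba_mismatch")
})

test_that("process_emg composes the chain and is invariant to common gain", {
  set.seed(7)
  raw <- make_rec(rnorm(6000), dt = 1 / fs)
  mvc <- make_rec(3 * rnorm(6000), dt = 1 / fs, condition = "MVC")
  cfg <- iba_config()

  env <- process_emg(raw, mvc, cfg)
  manual <- normalize_to_mvc(
    lowpass_envelope(rectify(bandpass_filter(raw))),
    mvc_reference(lowpass_envelope(rectify(bandpass_filter(mvc)))))
  expect_equal(env$values, manual$values, tolerance = 1e-12)

  # common positive rescaling of raw and MVC cancels in %MVC
  scaled <- process_emg(make_rec(250 * raw$values, dt = 1 / fs),
                        make_rec(250 * mvc$values, dt = 1 / fs,
                                 condition = "MVC"), cfg)
  expect_equal(scaled$values, env$values, tolerance = 1e-9)

  zero <- process_emg(make_rec(rep(0, 6000), dt = 1 / fs), mvc, cfg)
  expect_equal(zero$values, rep(0, 6000))
  expect_gte(min(env$values), 0)
})

test_that("the processed envelope tracks a known amplitude modulation", {
  spec <- trial_spec(noise_sd = 0.02, seed = 31)
  env_true <- simulate_envelopes(spec)$noexo
  raw <- synthesize_raw_emg(env_true, spec)
  chain <- lowpass_envelope(rectify(bandpass_filter(raw)))
  expect_gt(stats::cor(chain$values, env_true$values), 0.95)
})
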