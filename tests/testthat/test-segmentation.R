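seg_time <- function(phases, k, dt) {
  c(start = (phases$start[k] - 1) * dt, end = phases$end[k] * dt)
}

test_that("an angle that never crosses threshold yields a single upright segment", {
  ph <- detect_phases(angle_signal(rep(0, 500), dt = 0.01))
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$label, "upright")
  expect_equal(c(ph$start, ph$end), c(1L, 500L))
})

test_that("hysteresis crossings of a triangular trajectory match the analytic times", {
  # 0 -> 30 -> 0 deg at 1 deg/s, dt = 0.1 s: enters bent when the angle
  # exceeds 17 deg (t = 17 s), leaves when it drops below 13 deg (t = 47 s)
  dt <- 0.1
  tt <- seq(0, 60, by = dt)
  tri <- angle_signal(pmin(tt, 60 - tt), dt = dt)
  ph <- detect_phases(tri, threshold_deg = 15, hysteresis_deg = 2)
  bent <- which(ph$label != "upright")
  t_enter <- (ph$start[bent[1]] - 1) * dt
  t_exit <- ph$end[bent[length(bent)]] * dt
  expect_lt(abs(t_enter - 17), 0.15)
  expect_lt(abs(t_exit - 47), 0.15)
})

test_that("a trapezoidal trajectory splits into bending / holding / rising at the plateau edges", {
  dt <- 0.01
  up <- seq(0, 30, by = 10 * dt)          # 10 deg/s ramp, 3 s
  hold <- rep(30, 800)                    # 8 s plateau
  down <- seq(30, 0, by = -10 * dt)
  ang <- angle_signal(c(rep(0, 100), up, hold, down, rep(0, 100)), dt = dt)
  ph <- detect_phases(ang)
  labs <- ph$label[ph$label != "upright"]
  expect_equal(labs, c("bending", "position_holding", "rising_up"))
  hold_row <- which(ph$label == "position_holding")
  # true plateau spans samples 402..1201 (t = 4.01 .. 12.01 s)
  expect_lt(abs(ph$start[hold_row] - 402), 5)
  expect_lt(abs(ph$end[hold_row] - 1201), 5)
})

test_that("states shorter than the dwell are merged and detection is deterministic", {
  dt <- 0.01
  base <- c(rep(0, 300), seq(0, 30, by = 30 * dt), rep(30, 500),
            seq(30, 0, by = -30 * dt), rep(0, 300))
  # inject brief chatter around the threshold during the ramp
  chatter <- base
  chatter[340:345] <- 18
  ph <- detect_phases(angle_signal(chatter, dt = dt), min_dwell_s = 0.25)
  bent_runs <- rle(ph$label != "upright")
  expect_equal(sum(bent_runs$values), 1L)  # one bent interval, no fragment

  a <- detect_phases(angle_signal(base, dt = dt))
  b <- detect_phases(angle_signal(base, dt = dt))
  expect_identical(a, b)
})

test_that("timed boundaries convert to sample indices with exclusive ends", {
  ph <- timed_phases(data.frame(label = "hold", start_s = 0, end_s = 1),
                     dt = 0.1)
  expect_equal(c(ph$start, ph$end), c(1L, 10L))

  expect_equal(nrow(timed_phases(data.frame(label = character(0),
                                            start_s = numeric(0),
                                            end_s = numeric(0)), dt = 0.1)),
               0L)

  two <- timed_phases(data.frame(label = c("a", "b"), start_s = c(0, 1),
                                 end_s = c(1, 2)), dt = 0.5)
  expect_equal(two$start, c(1L, 3L))
  expect_equal(two$end, c(2L, 4L))

  expect_error(timed_phases(data.frame(label = c("a", "b"),
                                       start_s = c(0, 0.5),
                                       end_s = c(1, 2)), dt = 0.5),
               class = "iba_validation")
  expect_error(timed_phases(data.frame(label = "a", start_s = 2, end_s = 1),
                            dt = 0.5),
               class = "iba_validation")
})

test_that("phase maps validate their segment structure", {
  expect_error(phase_map("a", 5, 3), class = "iba_degenerate")
  expect_error(phase_map(c("a", "b"), c(1, 5), c(6, 9)),
               class = "iba_validation")
  ok <- phase_map(c("a", "b"), c(1, 7), c(6, 12))
  expect_equal(phase_durations(ok, dt = 0.5), c(3, 3))
})

test_that("time normalization preserves affine signals and endpoints", {
  env <- make_env(seq(2, 10, length.out = 41), dt = 0.1)
  ph <- phase_map("task", 1, 41)

  # identity when the target equals the current length
  same <- time_normalize(env, ph, samples_per_phase = 41)
  expect_equal(same$envelope$values, env$values)

  # a linear ramp stays linear with the same endpoints at any density
  out <- time_normalize(env, ph, samples_per_phase = 17)
  expect_equal(out$envelope$values,
               seq(2, 10, length.out = 17), tolerance = 1e-12)

  # idempotence on its own output
  again <- time_normalize(out$envelope, out$phases, samples_per_phase = 17)
  expect_equal(again$envelope$values, out$envelope$values)

  expect_error(time_normalize(env, ph, samples_per_phase = 1),
               class = "iba_validation")
})

test_that("resampling a band-limited envelope preserves its mean", {
  x <- 5 + 4 * sin(2 * pi * seq(0, 1, length.out = 1000))
  env <- make_env(x, dt = 1e-3)
  ph <- phase_map("task", 1, 1000)
  out <- time_normalize(env, ph, samples_per_phase = 250)
  expect_equal(mean(out$envelope$values), mean(x), tolerance = 0.005)
})

test_that("align_pair produces a common grid and preserves shapes across speeds", {
  # identical inputs align to identical envelopes
  e <- make_env(abs(sin(seq(0, pi, length.out = 300))) + 0.1, dt = 0.01)
  ph <- phase_map(c("a", "b"), c(1, 151), c(150, 300))
  pair <- align_pair(e, make_env(e$values, dt = 0.01, condition = "Exo"),
                     ph, ph, samples_per_phase = 100)
  expect_equal(pair$noexo$values, pair$exo$values)
  expect_equal(nrow(pair$phases), 2L)
  expect_equal(pair$phases$end - pair$phases$start + 1L, c(100L, 100L))

  # constants are resampling-invariant whatever the phase durations
  c1 <- make_env(rep(3, 400), dt = 0.01)
  c2 <- make_env(rep(3, 200), dt = 0.01, condition = "Exo")
  pc <- align_pair(c1, c2, phase_map("a", 1, 400), phase_map("a", 1, 200),
                   samples_per_phase = 50)
  expect_equal(pc$noexo$values, rep(3, 50))
  expect_equal(pc$exo$values, rep(3, 50))

  # the same task at two speeds: per-phase shapes correlate after alignment
  s1 <- simulate_envelopes(trial_spec(seed = 1))
  s2 <- simulate_envelopes(trial_spec(
    phase_durations = c(bending = 4.5, position_holding = 12,
                        rising_up = 4.5),
    rest_s = 3, seed = 1))
  sp <- align_pair(s1$noexo,
                   emg_envelope(s2$noexo$values, s2$noexo$dt,
                                s2$noexo$channel, "Exo"),
                   s1$phases, s2$phases, samples_per_phase = 500)
  for (k in which(sp$phases$label != "upright")) {
    idx <- sp$phases$start[k]:sp$phases$end[k]
    expect_gt(stats::cor(sp$noexo$values[idx], sp$exo$values[idx]), 0.99)
  }

  # mismatched label sequences cannot be aligned
  expect_error(align_pair(c1, c2, phase_map("a", 1, 400),
                          phase_map("b", 1, 200)),
               class = "iba_alignment")
})

test_that("per-phase interaction indices survive time normalization", {
  spec <- trial_spec(alpha = c(bending = 0.7, position_holding = 0.6,
                               rising_up = 0.9), seed = 2)
  env <- simulate_envelopes(spec)
  dense <- analyze_pair(aligned_pair(env$noexo, env$exo, env$phases),
                        scope = "per_phase")$indices
  ali <- align_pair(env$noexo, env$exo, env$phases, env$phases,
                    samples_per_phase = 250)
  coarse <- analyze_pair(ali, scope = "per_phase")$indices
  expect_lt(max(abs(coarse$oii - dense$oii)), 0.5)  # percentage points
})
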