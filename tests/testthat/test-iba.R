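test_that("integrated EMG is the rectangle-rule integral", {
  expect_equal(integrated_emg(make_env(c(1, 2, 3), dt = 0.5)), 3)
  expect_equal(integrated_emg(make_env(rep(0, 10), dt = 0.1)), 0)
  expect_equal(integrated_emg(make_env(rep(4, 25), dt = 0.2)), 4 * 25 * 0.2)
  env <- make_env(1:10, dt = 0.1)
  expect_equal(integrated_emg(env, segment = c(3, 5)), (3 + 4 + 5) * 0.1)
  expect_error(integrated_emg(env, segment = c(5, 3)),
               class = "iba_validation")
})

test_that("the interaction trend is the sum-normalized envelope difference", {
  expect_equal(i_trend(make_pair(c(2, 2), c(1, 1)))$values, c(25, 25))
  same <- make_pair(c(3, 1, 4), c(3, 1, 4))
  expect_equal(i_trend(same)$values, rep(0, 3))
  expect_equal(i_trend(make_pair(c(1, 3), c(3, 1)))$values, c(-50, 50))
  expect_error(i_trend(make_pair(c(0, 0), c(1, 1))),
               class = "iba_degenerate")
})

test_that("AII, RII, OII partition the trend by sign", {
  ix <- interaction_indices(c(-50, 50))
  expect_equal(ix$aii, 50)
  expect_equal(ix$rii, 50)
  expect_equal(ix$oii, 0)

  z <- interaction_indices(rep(0, 5))
  expect_equal(c(z$aii, z$rii, z$oii), c(0, 0, 0))

  # zero samples belong to the assistive partition deterministically;
  # a trend that is nonnegative everywhere has RII exactly 0
  pos <- interaction_indices(c(0, 1, 0, 2))
  expect_identical(pos$rii, 0)
  expect_identical(pos$oii, pos$aii - pos$rii)
})

test_that("uniform envelope scaling gives OII = 100 * (1 - alpha) at every scope", {
  set.seed(9)
  eno <- runif(900, 0.5, 60)
  ph <- phase_map(c("bending", "position_holding", "rising_up"),
                  c(1, 301, 601), c(300, 600, 900))
  pair <- make_pair(eno, 0.8 * eno, phases = ph)
  an <- analyze_pair(pair)$indices
  expect_equal(an$oii, rep(20, 4), tolerance = 1e-12)
  expect_equal(an$rii, rep(0, 4))

  ident <- analyze_pair(make_pair(eno, eno, phases = ph))$indices
  expect_equal(ident$aii, rep(0, 4))
  expect_equal(ident$oii, rep(0, 4))
})

test_that("phase OIIs, weighted by each phase's share of baseline energy, sum to the full-task OII", {
  set.seed(21)
  ph <- phase_map(c("a", "b", "c"), c(1, 201, 501), c(200, 500, 800))
  pair <- random_pair(800)
  pair$phases <- ph
  an <- analyze_pair(pair)$indices
  full <- an[an$scope == "full_task", ]
  per <- an[an$scope == "per_phase", ]
  w <- vapply(seq_len(nrow(ph)), function(k) {
    sum(pair$noexo$values[ph$start[k]:ph$end[k]])
  }, numeric(1))
  w <- w / sum(pair$noexo$values)
  expect_equal(sum(w * per$oii), full$oii, tolerance = 1e-9)
})

test_that("per-phase normalization uses the phase-local baseline integral", {
  # two phases with very different energies but the same relative reduction
  eno <- c(rep(50, 100), rep(2, 100))
  ph <- phase_map(c("hi", "lo"), c(1, 101), c(100, 200))
  pair <- make_pair(eno, 0.75 * eno, phases = ph)
  per <- analyze_pair(pair, scope = "per_phase")$indices
  expect_equal(per$oii, c(25, 25), tolerance = 1e-12)
})

test_that("group aggregation averages per-subject indices", {
  rows <- data.frame(
    subject = c("S1", "S1", "S2", "S2"),
    device = "A", muscle = "es",
    phase = rep(c("bending", "holding"), 2),
    aii = c(12, 30, 22, 40), rii = c(2, 0, 2, 0),
    oii = c(10, 30, 20, 40))
  g <- aggregate_indices(rows)
  g <- g[order(g$phase), ]
  expect_equal(g$n, c(2L, 2L))
  expect_equal(g$oii_mean, c(15, 35))
  expect_equal(g$oii_sd, c(sd(c(10, 20)), sd(c(30, 40))))
  expect_equal(g$oii_mean, g$aii_mean - g$rii_mean)

  one <- aggregate_indices(rows[rows$subject == "S1", ])
  expect_equal(one$oii_sd, c(0, 0))
  expect_equal(sort(one$oii_mean), c(10, 30))

  expect_error(aggregate_indices(rows, by = c("device", "muscle")),
               class = "iba_grouping")
})

test_that("mean trend averages pointwise on a common grid", {
  expect_equal(mean_trend(list(c(1, 2, 3), c(3, 2, 1))), c(2, 2, 2))
  expect_error(mean_trend(list(c(1, 2), c(1, 2, 3))),
               class = "iba_alignment")
})

test_that("trend traces flatten to a plottable long table", {
  ph <- phase_map(c("a", "b"), c(1, 51), c(50, 100))
  pair <- make_pair(runif(100, 1, 5), runif(100, 1, 5), phases = ph)
  tr <- trend_traces(analyze_pair(pair))
  expect_equal(names(tr), c("phase", "normalized_time", "i_trend"))
  expect_setequal(unique(tr$phase), c("full_task", "a", "b"))
  expect_true(all(tr$normalized_time >= 0 & tr$normalized_time <= 1))
})
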