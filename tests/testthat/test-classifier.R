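test_that("a clean parabola carries no breakpoints and classifies Normal", {
  for (peak in c(42, 50, 57)) {
    crv <- as_norm_curve(oracle_parabola(seq(90, 10), peak))
    expect_identical(nrow(detect_breakpoints(crv)), 0L)
    expect_identical(classify_repetition(crv), "Normal")
  }
})

test_that("a recovering pre-peak notch is reported and read as Valley", {
  torque <- oracle_parabola(seq(90, 10)) *
    oracle_notch(seq(90, 10), centre = 60, depth = 0.10)
  crv <- as_norm_curve(torque)
  bp <- detect_breakpoints(crv)
  expect_identical(nrow(bp), 1L)
  expect_true(bp$recovers)
  expect_identical(bp$position, "near_peak")
  expect_lt(abs(bp$angle - 60), 4)
  # the notch is measured as a slight (valley-range) deviation
  expect_gt(bp$depth, classifier_config()$min_depth)
  expect_lt(bp$depth, classifier_config()$valley_max_depth)
  expect_identical(classify_repetition(crv), "Valley")
})

test_that("a sharp non-recovering post-peak step is reported and read as Drop", {
  torque <- oracle_parabola(seq(90, 10)) *
    oracle_step(seq(90, 10), centre = 45, depth = 0.25)
  crv <- as_norm_curve(torque)
  bp <- detect_breakpoints(crv)
  expect_identical(nrow(bp), 1L)
  expect_false(bp$recovers)
  expect_identical(bp$position, "after_peak")
  expect_equal(bp$depth, 0.25, tolerance = 0.2)
  expect_gt(bp$sharpness, classifier_config()$drop_min_sharpness)
  expect_identical(classify_repetition(crv), "Drop")
})

test_that("mid-curve flutter spanning the peak is read as Shaking", {
  torque <- oracle_parabola(seq(90, 10)) *
    oracle_flutter(seq(90, 10), cycles = 5, amplitude = 0.10)
  crv <- as_norm_curve(torque)
  bp <- detect_breakpoints(crv)
  expect_gte(nrow(bp), 3L)
  expect_true(min(bp$angle) < 50 && max(bp$angle) > 50)
  expect_identical(classify_repetition(crv), "Shaking")
})

test_that("classification is deterministic and scale invariant", {
  trial <- generate_trial(curve_spec("Valley", noise_sd = 0.02, seed = 21L))
  reps <- preprocess_trial(trial)
  expect_identical(classify_trial(reps), classify_trial(reps))

  scaled <- lapply(trial, function(rep) {
    rep$torque_nm <- rep$torque_nm * 3.7
    rep
  })
  expect_identical(classify_trial(preprocess_trial(scaled)),
                   classify_trial(reps))
})

test_that("the label moves monotonically with notch depth", {
  # Normal at negligible depth, Valley in the slight range; deeper recovering
  # notches stop being Valley but never regress to it
  labels <- vapply(c(0.01, 0.08, 0.12), function(d) {
    classify_repetition(as_norm_curve(
      oracle_parabola(seq(90, 10)) * oracle_notch(seq(90, 10), 60, d)
    ))
  }, character(1))
  expect_identical(labels, c("Normal", "Valley", "Valley"))

  # a deepening non-recovering step goes Normal -> Drop and stays Drop
  labels <- vapply(c(0.02, 0.25, 0.45), function(d) {
    classify_repetition(as_norm_curve(
      oracle_parabola(seq(90, 10)) * oracle_step(seq(90, 10), 45, d)
    ))
  }, character(1))
  expect_identical(labels, c("Normal", "Drop", "Drop"))
})

test_that("the trial consistency rule needs the same irregularity three times", {
  mk <- function(pattern) {
    torque <- switch(
      pattern,
      Normal = oracle_parabola(seq(90, 10)),
      Valley = oracle_parabola(seq(90, 10)) * oracle_notch(seq(90, 10), 60, 0.10),
      Drop = oracle_parabola(seq(90, 10)) * oracle_step(seq(90, 10), 45, 0.30),
      Shaking = oracle_parabola(seq(90, 10)) * oracle_flutter(seq(90, 10), 5, 0.10)
    )
    as_norm_curve(torque)
  }
  expect_identical(classify_trial(lapply(c("Valley", "Valley", "Valley"), mk)),
                   "Valley")
  expect_identical(classify_trial(lapply(c("Valley", "Valley", "Normal"), mk)),
                   "Normal")
  expect_identical(classify_trial(lapply(c("Drop", "Shaking", "Drop"), mk)),
                   "Normal")
  expect_identical(classify_trial(lapply(rep("Normal", 3), mk)), "Normal")
  expect_error(classify_trial(lapply(c("Valley", "Valley"), mk)), "three")
})

test_that("generator round trip recovers every injected pattern without noise", {
  for (p in imc_patterns()) {
    trial <- generate_trial(curve_spec(p, noise_sd = 0, seed = 31L))
    reps <- preprocess_trial(trial)
    per_rep <- vapply(reps, classify_repetition, character(1))
    expect_identical(unique(per_rep), p)
    expect_identical(classify_trial(reps), p)
  }
})

test_that("classifier_config rejects inconsistent thresholds", {
  expect_error(classifier_config(min_depth = 0.2, valley_max_depth = 0.1),
               "min_depth")
  expect_error(classifier_config(smoothing_window = 4), "odd")
  expect_error(classifier_config(mid_region = c(0.8, 0.2)), "mid_region")
})
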