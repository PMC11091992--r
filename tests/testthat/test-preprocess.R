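test_that("resampling to the 1-degree grid is exact linear interpolation", {
  # input already on integer degrees is returned unchanged on those degrees
  raw <- data.frame(angle_deg = 90:10,
                    velocity_deg_s = 60,
                    torque_nm = oracle_parabola(90:10) * 100)
  grid <- resample_to_grid(raw)
  expect_equal(grid$torque_nm, raw$torque_nm, tolerance = 1e-12)
  expect_equal(grid$angle_deg, seq(90, 10))

  # linear midpoint
  two <- data.frame(angle_deg = c(12, 10), torque_nm = c(0.70, 0.50))
  expect_error(resample_to_grid(two), class = "imc_rejection") # span too short
  many <- data.frame(angle_deg = c(90, 12, 10), torque_nm = c(0, 0.70, 0.50))
  expect_equal(resample_to_grid(many)$torque_nm[seq(90, 10) == 11], 0.60)

  # dense random piecewise-linear trace against direct evaluation
  set.seed(1)
  knots_x <- sort(runif(40, 10, 90), decreasing = TRUE)
  knots_x[1] <- 90; knots_x[40] <- 10
  knots_y <- runif(40, 0, 120)
  dense <- resample_to_grid(data.frame(angle_deg = knots_x, torque_nm = knots_y))
  direct <- approx(knots_x, knots_y, xout = seq(90, 10))$y
  expect_equal(dense$torque_nm, direct, tolerance = 1e-9)
})

test_that("sub-threshold and missing samples are filled by interpolation averaging", {
  grid <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                     torque_nm = oracle_parabola(seq(90, 10)))
  # no invalid samples: unchanged
  expect_equal(fill_missing(grid)$torque_nm, grid$torque_nm)

  # single interior gap with one valid neighbour each side: plain average
  g <- data.frame(angle_deg = seq(80, 76),
                  velocity_deg_s = c(60, 20, 20, 20, 60),
                  torque_nm = c(1.0, 0.95, 0.9, 0.85, 0.8))
  filled <- fill_missing(g)
  expect_equal(filled$torque_nm[g$angle_deg == 78], 0.9)
  expect_true(all(filled$filled[2:4]))

  # interior gap with two valid neighbours each side on a linear trend:
  # both one-sided fits agree with the truth
  lin <- data.frame(angle_deg = seq(60, 50),
                    velocity_deg_s = c(60, 60, rep(10, 7), 60, 60),
                    torque_nm = seq(100, 90))
  expect_equal(fill_missing(lin)$torque_nm, seq(100, 90))

  # leading gap: nearest-valid constant extrapolation
  lead <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                     torque_nm = seq(90, 10))
  lead$velocity_deg_s[1:5] <- 30
  filled <- fill_missing(lead)
  expect_equal(filled$torque_nm[1:5], rep(85, 5))
  expect_equal(filled$torque_nm[6:81], seq(85, 10))

  # nothing valid at all is a rejection
  dead <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 10,
                     torque_nm = seq(90, 10))
  expect_error(fill_missing(dead), class = "imc_rejection")
})

test_that("peak normalization scales, locates and tie-breaks correctly", {
  grid <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                     torque_nm = oracle_parabola(seq(90, 10), 50) * 120)
  crv <- normalize_to_peak(grid)
  expect_s3_class(crv, "imc_curve")
  expect_equal(max(crv$value), 1)
  expect_equal(crv$peak_angle, 50)
  expect_equal(crv$peak_torque, 120)
  expect_equal(crv$value[crv$angle == 50], 1)

  # constant curve: everything is the peak; tie-break lands mid-range
  const <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                      torque_nm = rep(5, 81))
  ncrv <- normalize_to_peak(const)
  expect_true(all(ncrv$value == 1))
  expect_equal(ncrv$peak_angle, 50)

  # symmetric two-point tie: larger flexion angle wins
  two_peaks <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                          torque_nm = rep(1, 81))
  two_peaks$torque_nm[seq(90, 10) %in% c(55, 45)] <- 2
  expect_equal(normalize_to_peak(two_peaks)$peak_angle, 55)

  zero <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                     torque_nm = rep(0, 81))
  expect_error(normalize_to_peak(zero), class = "imc_rejection")
})

test_that("repetitions 2-4 are the analyzed ones", {
  trial <- as.list(1:5)
  expect_identical(select_repetitions(trial), as.list(2:4))
  expect_identical(select_repetitions(as.list(1:4)), as.list(2:4))
  expect_error(select_repetitions(as.list(1:3)), class = "imc_rejection")
})

test_that("preprocessing is idempotent on an already clean gridded curve", {
  grid <- data.frame(angle_deg = seq(90, 10), velocity_deg_s = 60,
                     torque_nm = oracle_parabola(seq(90, 10)))
  once <- fill_missing(resample_to_grid(grid))
  twice <- fill_missing(resample_to_grid(once))
  expect_equal(twice$torque_nm, once$torque_nm, tolerance = 1e-12)
  n1 <- normalize_to_peak(once)
  grid2 <- data.frame(angle_deg = n1$angle, velocity_deg_s = 60,
                      torque_nm = n1$value)
  n2 <- normalize_to_peak(fill_missing(resample_to_grid(grid2)))
  expect_equal(n2$value, n1$value, tolerance = 1e-12)
})

test_that("monotone raw segments stay monotone after resampling", {
  set.seed(7)
  for (i in 1:20) {
    x <- sort(runif(30, 10, 90), decreasing = TRUE)
    x[1] <- 90; x[30] <- 10
    y <- cumsum(runif(30, 0, 5))   # monotone in acquisition order
    out <- resample_to_grid(data.frame(angle_deg = x, torque_nm = y))
    expect_true(all(diff(out$torque_nm) >= -1e-12))
  }
})
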