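# Phase-window detection, cloud points, calibration and mass balance.

test_that("phase-window detection matches a brute-force grid scan on a rectangular bump", {
  grid <- 0:40
  od <- ifelse(grid >= 10 & grid <= 20, 1, 0)
  cv <- turbidity_curve(grid, od)
  pw <- detect_phase_windows(cv, threshold_fraction = 0.5)
  expect_equal(nrow(pw), 1L)
  expect_false(attr(pw, "reentrant"))
  # brute-force scan: all grid points with od >= 0.5 lie inside the window
  inside <- grid[od >= 0.5]
  expect_true(all(inside >= pw$lo & inside <= pw$hi))
  expect_true(all(grid[od < 0.5 & (grid < 9 | grid > 21)] < pw$lo |
                  grid[od < 0.5 & (grid < 9 | grid > 21)] > pw$hi))
  # interpolated boundaries sit between the last sub- and first supra-threshold points
  expect_gte(pw$lo, 9); expect_lte(pw$lo, 10)
  expect_gte(pw$hi, 20); expect_lte(pw$hi, 21)
})

test_that("flat-zero curves give zero windows and no error", {
  pw <- detect_phase_windows(turbidity_curve(0:10, rep(0, 11)))
  expect_equal(nrow(pw), 0L)
  expect_false(attr(pw, "reentrant"))
})

test_that("window detection is invariant under positive od rescaling", {
  cv <- gen_turbidity_profile(list(c(5, 30), c(60, 90)), sharpness = 2,
                              grid = seq(0, 100, 0.5), noise_sd = 0.01,
                              seed = 5)
  a <- detect_phase_windows(cv, 0.2)
  cv2 <- turbidity_curve(cv$control, cv$od600 * 37.5)
  b <- detect_phase_windows(cv2, 0.2)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("window count is non-increasing in the threshold", {
  # property of the detector on smooth profiles; measurement noise near the
  # curve maximum can transiently split a window (see the methods vignette)
  cv <- gen_turbidity_profile(list(c(5, 30), c(60, 90)), sharpness = 3,
                              grid = seq(0, 100, 0.5))
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(th) nrow(detect_phase_windows(cv, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("salt-sweep shapes: reentrant arginine-rich vs single-window lysine-rich", {
  grid <- c(seq(0, 200, 5), seq(250, 4500, 25))
  protamine_like <- gen_turbidity_profile(list(c(0, 80), c(3000, 4000)),
                                          sharpness = 5, grid = grid)
  pw <- detect_phase_windows(protamine_like)
  expect_equal(nrow(pw), 2L)
  expect_true(attr(pw, "reentrant"))
  expect_lt(pw$lo[2], 3100)  # reappearance above ~3 M
  epl_like <- gen_turbidity_profile(list(c(0, 80)), sharpness = 5, grid = grid)
  pw2 <- detect_phase_windows(epl_like)
  expect_equal(nrow(pw2), 1L)
  expect_false(attr(pw2, "reentrant"))
})

test_that("replicate averaging happens before detection by default", {
  grid <- seq(0, 100, 1)
  reps <- lapply(1:3, function(s)
    gen_turbidity_profile(list(c(20, 60)), sharpness = 2, grid = grid,
                          noise_sd = 0.05, seed = s))
  pw <- detect_phase_windows(reps, 0.3)
  expect_equal(nrow(pw), 1L)
  per <- detect_phase_windows(reps, 0.3, per_replicate = TRUE)
  expect_length(per, 3L)
})

test_that("cloud points: UCST, UCST+LCST, and zero hysteresis for identical ramps", {
  temps <- seq(4, 70, 0.5)
  # monotone decreasing turbidity: one dissolve on heating
  ucst_h <- turbidity_curve(temps, pmax(0, 1 - temps / 40), ramp = "heating")
  ucst_c <- turbidity_curve(temps, pmax(0, 1 - temps / 40), ramp = "cooling")
  cp <- detect_cloud_points(ucst_h, ucst_c, 0.5)
  th <- subset(cp$transitions, ramp == "heating")
  expect_equal(nrow(th), 1L)
  expect_equal(th$direction, "dissolve")
  expect_equal(cp$hysteresis, 0)
  expect_true(all(cp$transitions$temperature >= 4 &
                  cp$transitions$temperature <= 70))

  # turbid at low and at high T (UCST + LCST window in between)
  h <- gen_turbidity_profile(list(c(-10, 20), c(50, 80)), sharpness = 1.5,
                             grid = temps, ramp = "heating",
                             hysteresis_shift = 4)
  cl <- gen_turbidity_profile(list(c(-10, 20), c(50, 80)), sharpness = 1.5,
                              grid = temps, ramp = "cooling",
                              hysteresis_shift = 4)
  cp2 <- detect_cloud_points(h, cl, 0.5)
  expect_equal(nrow(subset(cp2$transitions, ramp == "heating")), 2L)
  expect_equal(nrow(subset(cp2$transitions, ramp == "cooling")), 2L)
  expect_equal(length(cp2$hysteresis), 2L)
  expect_equal(cp2$hysteresis, c(4, 4), tolerance = 0.2)

  expect_error(detect_cloud_points(ucst_h, ucst_h, 0.5), "cooling")
})

test_that("calibration: exact line, blank handling, noisy OLS recovery", {
  std <- data.frame(concentration = c(1, 2, 3, 4),
                    peak_area = 5 * c(1, 2, 3, 4) + 2)
  cal <- fit_calibration(std, blank_mean = 2)
  expect_equal(cal$slope, 5, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r2, 1)
  # blank 0 equals plain regression
  cal0 <- fit_calibration(std, blank_mean = 0)
  expect_equal(cal0$slope, 5, tolerance = 1e-12)
  expect_equal(cal0$intercept, 2, tolerance = 1e-10)

  # noisy four-point set: slope within its analytic OLS standard error band
  set.seed(42)
  reps <- replicate(200, {
    noisy <- std
    noisy$peak_area <- noisy$peak_area + rnorm(4, sd = 0.3)
    fit_calibration(noisy, blank_mean = 2)$slope
  })
  se_analytic <- 0.3 / sqrt(sum((std$concentration - mean(std$concentration))^2))
  expect_lt(abs(mean(reps) - 5), 3 * se_analytic / sqrt(200))
  expect_equal(sd(reps), se_analytic, tolerance = 0.25)

  expect_error(fit_calibration(data.frame(concentration = c(2, 2),
                                          peak_area = c(1, 2))), "singular")
})

test_that("concentration quantification round-trips and clips negatives", {
  std <- data.frame(concentration = c(0.5, 1, 2, 4),
                    peak_area = 12 * c(0.5, 1, 2, 4) + 7)
  cal <- fit_calibration(std, blank_mean = 7)
  expect_equal(quantify_concentration(std$peak_area, cal),
               std$concentration, tolerance = 1e-9)
  # randomized noiseless round-trips
  set.seed(1)
  conc <- runif(100, 0, 10)
  areas <- 12 * conc + 7
  expect_equal(quantify_concentration(areas, cal), conc, tolerance = 1e-9)
  # area at the blank-adjusted intercept maps to zero
  expect_equal(quantify_concentration(7 + cal$intercept, cal), 0, tolerance = 1e-9)
  expect_warning(out <- quantify_concentration(0, cal), "clipped")
  expect_equal(out, 0)
  bad <- cal; bad$slope <- -1
  expect_error(quantify_concentration(10, bad), "slope")
})

test_that("mass balance: closures and inconsistency detection", {
  # c_dilute = 0 and volumes partitioned fully
  expect_equal(dense_from_mass_balance(10, 0, 1, 0.8, 0.2), 10 * 1 / 0.2)
  # no partitioning
  expect_equal(dense_from_mass_balance(10, 10, 1, 0.8, 0.2), 10)
  # generator closure: random synthetic partition experiments invert exactly
  set.seed(3)
  for (i in 1:50) {
    Vt <- runif(1, 0.5, 2); Vd <- runif(1, 0.05, 0.3); Vdil <- Vt - Vd
    cd <- runif(1, 100, 2000); cdil <- runif(1, 0, 50)
    ct <- (cd * Vd + cdil * Vdil) / Vt
    expect_equal(dense_from_mass_balance(ct, cdil, Vt, Vdil, Vd), cd,
                 tolerance = 1e-9)
  }
  expect_error(dense_from_mass_balance(1, 50, 1, 0.9, 0.1), "inconsistency")
  expect_error(dense_from_mass_balance(1, 1, 1, 0.9, 0.2), "volumes")
})

test_that("composition ratios reproduce the reported packing ratios", {
  expect_equal(composition_ratio(1227.8, 680.9), 1.80, tolerance = 0.005)
  expect_equal(composition_ratio(158.3, 165.2), 0.96, tolerance = 0.005)
  expect_equal(composition_ratio(7.3, 7.3), 1)
  expect_error(composition_ratio(1, 0), "division")
})
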