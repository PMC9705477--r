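# Synthetic-data generators: determinism, analytic moments, parameter errors.

test_that("generators are deterministic given (params, seed) and record ground truth", {
  a <- gen_brownian_tracks(0.3, n_frames = 50, n_particles = 3, seed = 7)
  b <- gen_brownian_tracks(0.3, n_frames = 50, n_particles = 3, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(a),
    as.data.frame(gen_brownian_tracks(0.3, n_frames = 50, n_particles = 3, seed = 8))
  ))
  expect_equal(get_ground_truth(a)$seed, 7L)

  e1 <- gen_echo_decay(1e-9, c(0, 10, 20), noise_sd = 0.02, seed = 3)
  e2 <- gen_echo_decay(1e-9, c(0, 10, 20), noise_sd = 0.02, seed = 3)
  expect_identical(e1$psi, e2$psi)

  c1 <- gen_chain_ensemble("freely_jointed", 5, 0.38, 10, seed = 5)
  c2 <- gen_chain_ensemble("freely_jointed", 5, 0.38, 10, seed = 5)
  expect_identical(c1$frames, c2$frames)

  w1 <- gen_umbrella_windows(double_well_landscape(), 1, c(0, 10), 100, seed = 2)
  w2 <- gen_umbrella_windows(double_well_landscape(), 1, c(0, 10), 100, seed = 2)
  expect_identical(w1[[1]]$samples, w2[[1]]$samples)

  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_brownian_tracks(0.3, n_frames = 10, n_particles = 1, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Brownian generator: Stokes-Einstein D and single-step variance", {
  tr <- gen_brownian_tracks(0.3052, probe_radius = 1e-6, temperature = 295.15,
                            n_frames = 2, n_particles = 4000,
                            frame_interval = 0.02, seed = 11)
  D <- get_ground_truth(tr)$D_m2_s
  expect_equal(D, 1.380649e-23 * 295.15 / (6 * pi * 0.3052 * 1e-6),
               tolerance = 1e-12)
  expect_equal(D, 7.08e-16, tolerance = 5e-3)

  # per-axis single-step variance = 2 D dt (um^2) within 3 SE over particles
  dx <- tapply(tr$x_um, tr$particle_id, diff)
  v <- mean(unlist(dx)^2)
  truth <- 2 * D * 0.02 * 1e12
  se <- sd(unlist(dx)^2) / sqrt(length(dx))
  expect_lt(abs(v - truth), 3 * se)

  expect_error(gen_brownian_tracks(-1), "viscosity")
  expect_error(gen_brownian_tracks(1, temperature = 0), "temperature")
  expect_error(gen_brownian_tracks(1, n_frames = 1), "n_frames")
})

test_that("localization noise adds 4*noise_sd^2 to the expected MSD", {
  noise <- 5e-8  # 50 nm
  tr <- gen_brownian_tracks(0.3052, n_frames = 2000, n_particles = 40,
                            noise_sd = noise, seed = 4)
  D <- get_ground_truth(tr)$D_m2_s
  msd <- compute_msd(tr, max_lag_fraction = 0.01)
  truth <- (4 * D * msd$lag_s) * 1e12 + 4 * (noise * 1e6)^2
  expect_lt(max(abs(msd$msd_um2 / truth - 1)), 0.1)
})

test_that("echo-decay generator matches the closed form", {
  g <- seq(0, 80, length.out = 16)
  expect_equal(gen_echo_decay(0, g)$psi, rep(1, 16))
  d <- gen_echo_decay(2.40e-9, g, delta = 1e-3, Delta = 20e-3)
  expect_equal(d$psi[g == 0], 1)
  # -ln(psi) exactly quadratic in g: residual of lm on g^2 is zero
  y <- -log(d$psi[-1])
  fit <- lm(y ~ 0 + I(g[-1]^2))
  expect_lt(max(abs(residuals(fit))), 1e-12)
  # term-by-term closed form
  b <- (2.6752e4 * g * 100 * 1e-3)^2 * (20e-3 - 1e-3 / 3)
  expect_equal(d$psi, exp(-b * 2.40e-9), tolerance = 1e-12)
  expect_error(gen_echo_decay(1e-9, c(10, 10)), "distinct")
  expect_error(gen_echo_decay(1e-9, c(0, 10), delta = 3e-3, Delta = 1e-3), "Delta")
})

test_that("coalescence generator: tau = (19/20) eta R / sigma and scaling", {
  cs <- gen_coalescence_series(28.47, 4.20e-3, 10e-6, A0 = 0.5)
  tau <- get_ground_truth(cs)$tau_s
  expect_equal(tau, 0.95 * 28.47 * 1e-5 / 4.20e-3, tolerance = 1e-12)
  expect_equal(tau, 0.0644, tolerance = 1e-3)
  expect_equal(cs$A[1], 0.5)  # A(0) = A0 exactly, noiseless
  cs2 <- gen_coalescence_series(28.47, 2 * 4.20e-3, 10e-6, A0 = 0.5)
  expect_equal(get_ground_truth(cs2)$tau_s, tau / 2)
  expect_error(gen_coalescence_series(1, 1, 1, A0 = 1.2), "A0")
})

test_that("turbidity generator: flat zero without windows, errors on overlap", {
  flat <- gen_turbidity_profile(list(), grid = 0:100)
  expect_true(all(flat$od600 == 0))
  expect_error(
    gen_turbidity_profile(list(c(0, 50), c(40, 80)), grid = 0:100),
    "disjoint")
  expect_error(
    gen_turbidity_profile(list(c(50, 40)), grid = 0:100), "lo < hi")
})

test_that("umbrella sampler: stiff-spring limit, analytic biased distribution, schedule", {
  Fm <- double_well_landscape()
  stiff <- gen_umbrella_windows(Fm, kappa = 1e3, 20, 500, seed = 1)
  expect_true(all(stiff[[1]]$samples == 20))
  expect_equal(stiff[[1]]$n_equilibration_discarded, 0L)

  # flat landscape, kappa = 10: histogram matches the discretized Gaussian
  # at N* (chi-square GOF, alpha = 0.01, classes <=19 / 20 / >=21)
  flat <- tibble::tibble(N = 0:40, betaF = rep(0, 41))
  w <- gen_umbrella_windows(flat, kappa = 10, 20, 5000, seed = 9)[[1]]
  p_raw <- exp(-5 * (0:40 - 20)^2)
  p <- p_raw / sum(p_raw)
  classes <- c(sum(p[0:40 <= 19]), p[0:40 == 20], sum(p[0:40 >= 21]))
  obs <- c(sum(w$samples <= 19), sum(w$samples == 20), sum(w$samples >= 21))
  chi2 <- sum((obs - 5000 * classes)^2 / (5000 * classes))
  expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.01)

  sched <- parse_nstar_schedule("{-9..3..54}")
  expect_length(sched, 22)
  expect_equal(sched[1:3], c(-9, -6, -3))
  expect_equal(sched[22], 54)
  expect_error(parse_nstar_schedule("9..3..54"), "schedule")
  expect_error(gen_umbrella_windows(Fm, 1, numeric(0), 10), "schedule|non-empty")
})

test_that("solvated frames: Poisson counts and box validation", {
  expect_equal(nrow(gen_solvated_frame(matrix(1, 1, 3), 0, c(2, 2, 2),
                                       seed = 1)$water_oxygen_positions), 0)
  counts <- vapply(1:30, function(s)
    nrow(gen_solvated_frame(matrix(1, 1, 3), 20, c(2, 2, 2),
                            seed = s)$water_oxygen_positions), numeric(1))
  truth <- 20 * 8
  expect_lt(abs(mean(counts) - truth), 3 * sd(counts) / sqrt(30))
  expect_error(gen_solvated_frame(matrix(5, 1, 3), 10, c(2, 2, 2)), "inside")
})

test_that("chain generator: exact bonds, dimer dee, ideal-chain law", {
  ce <- gen_chain_ensemble("freely_jointed", 2, bond_length = 0.7,
                           n_frames = 20, seed = 3)
  dee <- vapply(ce$frames, end_to_end, numeric(1))
  expect_equal(dee, rep(0.7, 20), tolerance = 1e-12)

  ce2 <- gen_chain_ensemble("freely_jointed", 20, bond_length = 0.38,
                            n_frames = 1500, seed = 6)
  bl <- vapply(ce2$frames, function(fr) sqrt(sum((fr[2, ] - fr[1, ])^2)),
               numeric(1))
  expect_equal(bl, rep(0.38, 1500), tolerance = 1e-12)
  d2 <- vapply(ce2$frames, function(fr) end_to_end(fr)^2, numeric(1))
  truth <- 19 * 0.38^2
  expect_lt(abs(mean(d2) - truth), 3 * sd(d2) / sqrt(length(d2)))

  sa <- gen_chain_ensemble("self_avoiding", 12, 0.38, 25, seed = 2)
  dmin <- min(vapply(sa$frames, function(fr) min(dist(fr)), numeric(1)))
  expect_gte(dmin, 0.9 * 0.38 - 1e-9)
})
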