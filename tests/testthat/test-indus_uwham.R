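# Hydration-volume water counting and UWHAM unbiasing.

toy_frame <- function(seed, density = 20, box = c(2.5, 2.5, 2.5),
                      centers = rbind(c(1.0, 1.25, 1.25), c(1.6, 1.25, 1.25))) {
  gen_solvated_frame(centers, density, box, seed = seed)
}

test_that("hydration volume: sphere arithmetic and Monte-Carlo union volumes", {
  fr <- gen_solvated_frame(rbind(c(1, 1, 1), c(1, 1, 1), c(2.3, 1, 1)),
                           0, c(3.5, 3.5, 3.5), seed = 1)
  v1 <- hydration_volume(fr, 1L, Rv = 0.55)
  expect_equal(nrow(v1$centers), 1L)
  mc1 <- union_volume(v1, n_samples = 2e5, seed = 2)
  expect_equal(as.numeric(mc1), (4 / 3) * pi * 0.55^3, tolerance = 0.01)
  expect_equal((4 / 3) * pi * 0.55^3, 0.697, tolerance = 1e-3)

  # coincident spheres add nothing
  v2 <- hydration_volume(fr, c(1L, 2L), Rv = 0.55)
  mc2 <- union_volume(v2, n_samples = 2e5, seed = 2)
  expect_equal(as.numeric(mc2), as.numeric(mc1), tolerance = 0.01)

  # spheres >= 2 Rv apart: exactly two sphere volumes, within 1% of MC
  v3 <- hydration_volume(fr, c(1L, 3L), Rv = 0.55)
  mc3 <- union_volume(v3, n_samples = 5e5, seed = 3)
  expect_equal(as.numeric(mc3), 2 * (4 / 3) * pi * 0.55^3, tolerance = 0.01)

  expect_error(hydration_volume(fr, integer(0)), "non-empty")
  expect_error(hydration_volume(fr, 99L), "out of range")
})

test_that("sharp count: basic cases and the Poisson mean", {
  empty <- gen_solvated_frame(matrix(1.25, 1, 3), 0, c(2.5, 2.5, 2.5), seed = 1)
  vol <- hydration_volume(empty, 1L)
  expect_equal(sharp_count(empty, vol), 0L)

  # a water exactly at a center is counted
  fr <- empty
  fr$water_oxygen_positions <- matrix(1.25, 1, 3)
  expect_equal(sharp_count(fr, vol), 1L)

  # mean in-shell count over seeds ~ density x union volume (3 SE)
  counts <- vapply(1:60, function(s) {
    f <- toy_frame(s)
    as.numeric(sharp_count(f, hydration_volume(f, c(1L, 2L))))
  }, numeric(1))
  uv <- union_volume(hydration_volume(toy_frame(1), c(1L, 2L)),
                     n_samples = 5e5, seed = 4)
  truth <- 20 * as.numeric(uv)
  expect_lt(abs(mean(counts) - truth), 3 * sd(counts) / sqrt(60))
})

test_that("single-atom shell at bulk-like density holds about 23 waters", {
  counts <- vapply(1:60, function(s) {
    f <- gen_solvated_frame(matrix(1.5, 1, 3), 33, c(3, 3, 3), seed = s)
    as.numeric(sharp_count(f, hydration_volume(f, 1L, Rv = 0.55)))
  }, numeric(1))
  truth <- 33 * (4 / 3) * pi * 0.55^3   # ~23.0
  expect_lt(abs(mean(counts) - truth), 3 * sd(counts) / sqrt(60))
})

test_that("coarse count: exact limits, sharp-count bound, sigma->0 convergence", {
  fr <- toy_frame(5)
  vol <- hydration_volume(fr, c(1L, 2L))

  # water at a center contributes exactly 1; far water exactly 0
  probe <- fr
  probe$water_oxygen_positions <- rbind(vol$centers[1, ],
                                        c(2.49, 2.49, 2.49))
  expect_equal(coarse_count(probe, vol), 1)

  expect_error(coarse_count(fr, vol, sigma = 0.02, rc = 0.01), "rc > sigma")

  # |coarse - sharp| bounded by the number of waters within rc of a surface,
  # over 100 seeded frames; equality when no water is near a surface
  mismatch <- function(f, sigma, rc) {
    v <- hydration_volume(f, c(1L, 2L))
    d <- sapply(seq_len(nrow(v$centers)), function(k)
      sqrt(rowSums(sweep(f$water_oxygen_positions, 2, v$centers[k, ])^2)))
    near_surface <- sum(apply(abs(d - v$Rv) <= rc, 1, any))
    c(diff = abs(coarse_count(f, v, sigma, rc) - sharp_count(f, v)),
      near = near_surface)
  }
  res <- vapply(1:100, function(s) mismatch(toy_frame(s), 0.01, 0.02),
                numeric(2))
  expect_true(all(res["diff", ] <= res["near", ] + 1e-9))
  expect_true(all(res["diff", res["near", ] == 0] < 1e-12))

  # shrinking sigma, rc tightens the agreement toward the sharp oracle
  res_small <- vapply(1:100, function(s) mismatch(toy_frame(s), 1e-4, 2e-4),
                      numeric(2))
  expect_lt(mean(res_small["diff", ]), mean(res["diff", ]))
  expect_lt(mean(res_small["diff", ]), 0.02)
})

test_that("coarse count respects periodic minimum-image distances", {
  fr <- gen_solvated_frame(matrix(0.1, 1, 3), 0, c(3, 3, 3), seed = 1,
                           periodic = TRUE)
  fr$water_oxygen_positions <- matrix(c(2.95, 0.1, 0.1), 1, 3)
  vol <- hydration_volume(fr, 1L, Rv = 0.55)
  expect_equal(sharp_count(fr, vol), 1L)   # 0.15 nm across the boundary
  expect_equal(coarse_count(fr, vol), 1)
})

test_that("UWHAM: unbiased single window reduces to the histogram", {
  Fm <- double_well_landscape(wells = c(5, 15), barrier = 2, N_range = 0:25)
  w <- gen_umbrella_windows(Fm, kappa = 1e-12, 10, 4000, seed = 7)
  w[[1]]$kappa <- 0
  prof <- uwham_unbias(w)
  h <- tabulate(w[[1]]$samples + 1L, nbins = 26)
  keep <- h > 0
  manual <- -log(h[keep] / sum(h))
  manual <- manual - min(manual)
  expect_equal(prof$betaF[match(which(keep) - 1L, prof$N)], manual,
               tolerance = 1e-9)
})

test_that("UWHAM: two identical windows equal one window with pooled samples", {
  Fm <- double_well_landscape(wells = c(5, 15), barrier = 2, N_range = 0:25)
  w <- gen_umbrella_windows(Fm, kappa = 0.5, 10, 3000, seed = 8)[[1]]
  dup <- structure(list(w, w), class = "umbrella_window_set")
  pooled <- structure(list(nstar = w$nstar, kappa = w$kappa,
                           samples = c(w$samples, w$samples),
                           n_equilibration_discarded = 0L),
                      class = "umbrella_window")
  p1 <- uwham_unbias(dup)
  p2 <- uwham_unbias(list(pooled))
  expect_equal(p1$betaF, p2$betaF, tolerance = 1e-6)
})

test_that("UWHAM is invariant under window permutation and redundant windows", {
  Fm <- double_well_landscape(wells = c(8, 20), barrier = 3, N_range = 0:30)
  w <- gen_umbrella_windows(Fm, kappa = 0.5, seq(0, 28, 4), 3000, seed = 9)
  p <- uwham_unbias(w)
  set.seed(5)
  wp <- w[sample(seq_along(w))]
  class(wp) <- "umbrella_window_set"
  pp <- uwham_unbias(wp)
  expect_equal(p$betaF, pp$betaF, tolerance = 1e-6)
  expect_equal(p$N, pp$N)

  # a window split into two half-windows (same bias, same pooled samples) is
  # redundant: merging or splitting leaves the profile unchanged
  w4 <- w[[4]]
  half <- length(w4$samples) %/% 2
  wa <- w4; wa$samples <- w4$samples[seq_len(half)]
  wb <- w4; wb$samples <- w4$samples[-seq_len(half)]
  ws <- c(w[-4], list(wa, wb))
  pd <- uwham_unbias(ws)
  expect_equal(p$betaF, pd$betaF[match(p$N, pd$N)], tolerance = 1e-6)
})

test_that("UWHAM recovers a double-well landscape under overlapping windows", {
  Fm <- double_well_landscape()
  errs <- vapply(1:3, function(s) {
    w <- gen_umbrella_windows(Fm, kappa = 0.5, "{-9..3..54}", 20000, seed = s)
    prof <- uwham_unbias(w)
    reg <- Fm$N[Fm$betaF <= 8]
    truth <- Fm$betaF[match(reg, Fm$N)]
    est <- prof$betaF[match(reg, prof$N)]
    max(abs((est - min(est)) - (truth - min(truth))))
  }, numeric(1))
  expect_true(all(errs <= 0.1))
})

test_that("UWHAM agrees with the independent binned-WHAM oracle", {
  Fm <- double_well_landscape()
  w <- gen_umbrella_windows(Fm, kappa = 0.5, "{-9..3..54}", 5000, seed = 17)
  prof <- uwham_unbias(w)
  oracle <- binned_wham(w)
  common <- intersect(prof$N, oracle$N)
  a <- prof$betaF[match(common, prof$N)]
  b <- oracle$betaF[match(common, oracle$N)]
  fin <- is.finite(a) & is.finite(b)
  expect_lt(max(abs((a - b)[fin])), 0.05)
})

test_that("disconnected window chains raise an error; low overlap warns", {
  Fm <- tibble::tibble(N = 0:200, betaF = rep(0, 201))
  w <- gen_umbrella_windows(Fm, kappa = 50, c(5, 195), 200, seed = 1)
  expect_error(uwham_unbias(w), "disconnected")

  w2 <- gen_umbrella_windows(double_well_landscape(), kappa = 10,
                             c(10, 16), 500, seed = 2)
  expect_warning(uwham_unbias(w2), "overlap")
})

test_that("equilibration discard removes leading samples", {
  Fm <- double_well_landscape(wells = c(5, 15), barrier = 2, N_range = 0:25)
  w <- gen_umbrella_windows(Fm, kappa = 0.5, 10, 2000, seed = 3)[[1]]
  w_disc <- w
  w_disc$samples <- c(rep(25, 5), w$samples)  # 5 junk leading values
  w_disc$n_equilibration_discarded <- 5L
  p1 <- uwham_unbias(list(w))
  p2 <- uwham_unbias(list(w_disc))
  expect_equal(p1$betaF, p2$betaF, tolerance = 1e-9)
})

test_that("per-water profile: quadratic closed form, flat profile, comparator", {
  # quadratic betaF = (N - N0)^2 / (2 s): per-water value at N is (N0 - N)/(2 s)
  N <- 0:40; N0 <- 25; s <- 5
  prof <- structure(list(N = N, betaF = (N - N0)^2 / (2 * s), N0 = N0,
                         window_f = NULL, nstar = NULL, iterations = 0L,
                         residual = 0, overlap = numeric(0)),
                    class = "free_energy_profile")
  pw <- per_water_profile(prof)
  expect_equal(pw$per_water_kBT, (N0 - pw$N) / (2 * s), tolerance = 1e-12)
  expect_equal(pw$occupancy, pw$N / N0)

  flatish <- prof
  flatish$betaF <- c(rep(0, 40), 1)  # minimum interior-ish: force via N0
  flatish$betaF <- rep(0, 41); flatish$betaF[41] <- 1e-9; flatish$N0 <- 20
  pwf <- per_water_profile(flatish)
  expect_true(all(abs(pwf$per_water_kBT) < 1e-9))

  # a shallower well costs less per water: classified more hydrophobic
  shallow <- prof; shallow$betaF <- (N - N0)^2 / (2 * 10)
  cmp <- compare_hydrophobicity(shallow, prof)
  expect_equal(cmp$more_hydrophobic, "a")
  expect_lt(cmp$mean_a, cmp$mean_b)

  edge <- prof; edge$N <- 5:45; edge$N0 <- 5
  edge$betaF <- seq(0, 4, length.out = 41)
  expect_error(per_water_profile(edge), "interior")
})

test_that("indus_params validates the parameter relationships", {
  p <- indus_params()
  expect_equal(p$Rv, 0.55); expect_equal(p$kappa, 10)
  expect_error(indus_params(sigma = 0.03, rc = 0.02), "rc > sigma")
  expect_error(indus_params(Rv = 0.01), "Rv > rc")
  w <- sample_model_biased(double_well_landscape(), p, nstar = -9,
                           n_samples = 50, seed = 1)
  expect_true(all(w$samples >= 0))
  expect_equal(w$nstar, -9)
})
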