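#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume,
# with ground-truth sidecars, under a single base seed. All conditions mirror
# the study protocols: probe radius 1 um, T = 295.15 K, 20 ms / 1 s frame
# intervals, 16-echo gradient sweeps at delta = 1 ms / Delta = 20 ms,
# droplet radius 10 um after coalescence, and the salt-sweep turbidity shapes
# (dissolution near 80 mM; reappearance above 3 M for the arginine-rich pair).

suppressMessages(library(coacervate))
seed <- 20260922L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

pars <- protocol_defaults()
dp <- dense_phase_reference()
eta <- setNames(dp$viscosity_Pa_s, dp$system)
sig <- setNames(dp$interfacial_tension_N_m, dp$system)

## probe tracks at the two reported dense-phase viscosities
tr_lo <- gen_brownian_tracks(eta[["low_salt_HA_protamine"]],
                             frame_interval = pars$frame_interval_low_salt_s,
                             n_frames = 2000, n_particles = 50, seed = seed)
write_probe_tracks(tr_lo, "results/data/tracks_low_salt.csv")
write_ground_truth(tr_lo, "results/data/tracks_low_salt.truth.json")

tr_hi <- gen_brownian_tracks(eta[["high_salt_HA_protamine"]],
                             frame_interval = pars$frame_interval_high_salt_s,
                             n_frames = 2000, n_particles = 50, seed = seed + 1L)
write_probe_tracks(tr_hi, "results/data/tracks_high_salt.csv")
write_ground_truth(tr_hi, "results/data/tracks_high_salt.truth.json")

## echo decay at the literature water diffusivity
dec <- gen_echo_decay(water_diffusivity_reference()$water_literature,
                      seq(5, 85, length.out = pars$pfg_n_echoes),
                      delta = pars$pfg_delta_s, Delta = pars$pfg_Delta_s,
                      noise_sd = 0.02, seed = seed)
write_echo_decay(dec, "results/data/echo_water.csv")
write_ground_truth(dec, "results/data/echo_water.truth.json")

## coalescence relaxations for the three reported (eta, sigma) pairs
for (sys in dp$system) {
  cs <- gen_coalescence_series(eta[[sys]], sig[[sys]], droplet_radius = 10e-6,
                               A0 = 0.5, n_frames = 50, noise_sd = 0.02,
                               seed = seed + match(sys, dp$system))
  write_coalescence_series(cs, sprintf("results/data/coalescence_%s.csv", sys))
  write_ground_truth(cs, sprintf("results/data/coalescence_%s.truth.json", sys))
}

## salt-sweep turbidity profiles (triplicates, as acquired)
grid <- c(seq(0, 200, 5), seq(250, 4500, 25))
for (r in 1:3) {
  arg_rich <- gen_turbidity_profile(list(c(0, 80), c(3000, 4000)),
                                    sharpness = 5, grid = grid,
                                    noise_sd = 0.02, seed = seed + 10L + r)
  write_turbidity_curve(arg_rich,
                        sprintf("results/data/turbidity_HA_protamine_r%d.csv", r))
  lys_rich <- gen_turbidity_profile(list(c(0, 80)), sharpness = 5, grid = grid,
                                    noise_sd = 0.02, seed = seed + 20L + r)
  write_turbidity_curve(lys_rich,
                        sprintf("results/data/turbidity_HA_ePL_r%d.csv", r))
}

## temperature ramps with 4 C hysteresis (UCST + LCST window pair)
temps <- seq(4, 70, 0.5)
for (ramp in c("heating", "cooling")) {
  cv <- gen_turbidity_profile(list(c(-10, 20), c(50, 80)), sharpness = 1.5,
                              grid = temps, ramp = ramp, hysteresis_shift = 4,
                              noise_sd = 0.01, seed = seed + 30L)
  write_turbidity_curve(cv, sprintf("results/data/ramp_%s.csv", ramp))
}

## umbrella windows over the double-well model landscape, at the study
## schedule (kappa = 10 kBT, N* in {-9..3..54}, 5000 samples/window) and at
## an overlapping-window reference (kappa = 0.5)
Fm <- double_well_landscape(wells = c(10, 35), barrier = 4)
utils::write.csv(Fm, "results/data/landscape_double_well.csv", row.names = FALSE)
w_study <- gen_umbrella_windows(Fm, kappa = 10, "{-9..3..54}", 5000,
                                seed = seed)
write_umbrella_windows(w_study, "results/data/umbrella_study")
w_ref <- gen_umbrella_windows(Fm, kappa = 0.5, "{-9..3..54}", 20000,
                              seed = seed)
write_umbrella_windows(w_ref, "results/data/umbrella_overlap")

cat("simulated inputs written to results/data/ (base seed", seed, ")\n")
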