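#!/usr/bin/env Rscript
# Stage 5: Stejskal-Tanner fit of the simulated water echo decay, plus a
# small Monte-Carlo bias check of the fitter at the acquisition noise level.

suppressMessages(library(coacervate))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

dec <- read_echo_decay("results/data/echo_water.csv")
truth <- jsonlite::read_json("results/data/echo_water.truth.json")
fit <- fit_diffusion(dec)
cat(sprintf("fitted D = %.4g m^2/s (truth %.4g, %+.2f%%)\n",
            fit$D_m2_s, truth$D_m2_s, 100 * (fit$D_m2_s / truth$D_m2_s - 1)))

## bias check: 100 independent 2%-noise acquisitions
g <- seq(5, 85, length.out = 16)
Ds <- vapply(1:100, function(s)
  fit_diffusion(gen_echo_decay(truth$D_m2_s, g, noise_sd = 0.02,
                               seed = s))$D_m2_s, numeric(1))
cat(sprintf("mean recovered D over 100 noisy repeats: %.4g m^2/s (bias %+.2f%%)\n",
            mean(Ds), 100 * (mean(Ds) / truth$D_m2_s - 1)))

utils::write.csv(
  data.frame(quantity = c("fitted_D_m2_s", "true_D_m2_s",
                          "mc_mean_D_m2_s", "mc_sd_D_m2_s"),
             value = c(fit$D_m2_s, truth$D_m2_s, mean(Ds), sd(Ds))),
  "results/tables/pfg_nmr.csv", row.names = FALSE)
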