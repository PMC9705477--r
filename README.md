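# coacervate

Quantitative analysis of complex-coacervate liquid-liquid phase separation
(LLPS): phase behavior, dense-phase mechanics, water dynamics, dewetting
thermodynamics and chain conformation, with seeded synthetic-data generators
so every estimator can be validated against known ground truth.

## The problem

Oppositely charged polyelectrolytes — here hyaluronic acid (HA) paired with
arginine-rich protamine or lysine-rich ε-poly-L-lysine (εPL) — demix into a
dense coacervate phase and a dilute phase. Electrostatics drive the
low-salt regime; the arginine-rich pair, uniquely, re-enters phase
separation above ~3 M NaCl because the guanidinium side chain is
effectively hydrophobic. Characterizing the two regimes takes a battery of
measurements, each with its own estimator:

- **Phase windows / cloud points** — turbidity (OD600) versus salt or
  temperature, thresholded at a fraction of the curve maximum; reentrance =
  two or more windows; heating/cooling crossings give UCST/LCST cloud
  points and hysteresis.
- **Composition** — amino-acid-analysis calibration (OLS on blank-corrected
  peak areas), concentration by inversion, and dense-phase concentration by
  mass balance, c_dense = (c_tot·V_tot − c_dil·V_dil)/V_dense.
- **Microrheology** — probe tracks → time/ensemble-averaged MSD → power-law
  fit MSD(τ) = 4Dτ^α → Stokes–Einstein viscosity η = k_B·T/(6πDr).
- **Interfacial tension** — droplet-coalescence aspect ratio
  A = (L−W)/(L+W) relaxing as A₀e^{−t/τ} with τ ≅ (19/20)·ηR/σ.
- **Water diffusion** — Stejskal–Tanner echo attenuation
  ψ = exp(−(γgδ)²D(Δ−δ/3)) fit for the self-diffusion coefficient.
- **Dewetting free energy** — INDUS-style coarse water counts over
  union-of-spheres hydration volumes (Rv = 0.55 nm, σ = 0.01 nm,
  rc = 0.02 nm), harmonically biased windows (κ in kBT), binless UWHAM
  unbiasing to βF(N) = −ln P_v(N), and a per-water normalization
  (βF(N) − βF(N₀))/(N₀ − N): lower per-water cost = more hydrophobic.
- **Chain conformation** — Rg, end-to-end distance, their distributions,
  contact maps, geometric hydrogen bonds.

Every input has a generator (`gen_*()`) that records its exact parameters
and seed, so the whole pipeline runs and is tested without any external
data.

## Worked example

Generate Brownian probe tracks at the reported low-salt dense-phase
viscosity and recover it through the full microrheology chain:

```r
library(coacervate)

tracks <- gen_brownian_tracks(
  viscosity = 0.3052,       # Pa s, low-salt HA-protamine dense phase
  probe_radius = 1e-6,      # 1 um probe
  temperature = 295.15,     # K
  frame_interval = 0.02,    # 20 ms frames (low-salt acquisition)
  n_frames = 2000, n_particles = 50, seed = 20260922
)
get_ground_truth(tracks)$D_m2_s
#> [1] 7.083905e-16            # Stokes-Einstein D used by the generator

microrheology(tracks)
#> <microrheology: D = 6.92e-16 m^2/s, alpha = 0.973, eta = 0.3124 Pa s>
```

The recovered viscosity (0.3124 Pa s) is within 2.4% of the generating
0.3052 Pa s, with a diffusive exponent near 1 as expected for a Newtonian
medium. The same pattern — generate at known truth, estimate, compare —
runs for every stage in the numbered drivers:

```sh
Rscript analysis/01_simulate_inputs.R     # all synthetic inputs + ground truth
Rscript analysis/02_phase_behavior.R      # windows, cloud points, ratios
Rscript analysis/03_microrheology.R       # MSD -> D -> eta
Rscript analysis/04_interfacial_tension.R # tau -> sigma
Rscript analysis/05_pfg_nmr.R             # Stejskal-Tanner fits
Rscript analysis/06_dewetting_uwham.R     # umbrella windows -> betaF(N)
Rscript analysis/07_chain_conformation.R  # Rg, dee, contacts, H-bonds
```

Stage 2, for instance, prints the dense-phase ratios computed from the
reported composition measurements:

```
                                         quantity value
              protamine:HA, high-salt dense phase 1.803
               protamine:HA, low-salt dense phase 0.958
        total conc, high vs low salt HA-protamine 5.900
      total conc, low-salt HA-protamine vs HA-ePL 1.720
   interfacial tension, low-salt protamine vs ePL 1.363
 hydration-water retardation, dilute/dense (ODNP) 1.327
```

i.e. the arginine-rich dense phase packs protamine and HA ~1:1 at low salt
but ~1.8:1 at high salt, is ~6× more concentrated at high salt, and its
hydration water is ~1.3× retarded relative to the dilute phase. Tables land
under `results/tables/`. The methods vignette
(`vignettes/coacervate-methods.Rmd`) documents the models, parameter
defaults, numerical choices and limitations.

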