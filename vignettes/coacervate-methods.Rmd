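---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacervate)
```

This vignette is the package's own account of the science it implements: the
models behind each analysis stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and the numerical choices made where a published protocol leaves the
design open. Everything quantitative stated here is computed by the test
suite or the `analysis/` drivers; nothing is asserted that the code does not
itself verify.

## The systems and the questions

Complex coacervation is liquid-liquid phase separation (LLPS) driven by the
association of oppositely charged polyelectrolytes. The package is built
around two model pairs: hyaluronic acid (HA) with arginine-rich protamine,
and HA with lysine-rich ε-poly-L-lysine (εPL). Both pairs demix at low ionic
strength, where electrostatics dominate; only the arginine-rich pair
re-enters phase separation above ~3 M NaCl, where charges are screened and
the hydrophobic character of the guanidinium side chain takes over. The
pipeline quantifies the observables that tell these regimes apart: phase
windows and cloud points, dense-phase composition, viscosity, interfacial
tension, interstitial water diffusivity, residue-level dewetting free
energies, and chain compactness.

## Phase behavior

**Window detection.** A turbidity curve (OD600 versus salt concentration or
temperature) is thresholded at a fraction of its own maximum (default
`threshold_fraction = 0.1`; protocols report "relative turbidity" without a
stated cutoff, so the threshold is exposed as a parameter). Window
boundaries are linearly interpolated between grid points; two or more
windows set the reentrant flag. Because the threshold is relative, the
detector is invariant under positive rescaling of the turbidity axis, and
the window count is non-increasing in the threshold *for smooth profiles*.
With measurement noise comparable to the distance between the threshold and
the curve maximum, a window can transiently split at high thresholds; this
is a property of any threshold detector and the reason the monotonicity
property is stated (and tested) on noise-free shapes. Replicates are
averaged on their common grid before detection by default; a per-replicate
mode is available. Two "relative turbidity" normalizations are provided
(per-curve maximum, the default, and global maximum) since the published
figures do not say which was used.

**Cloud points.** Heating and cooling scans (protocol: 4–70 °C at
2 °C/min) are traversed in temporal order; each crossing of the threshold is
reported as `appear` (rising turbidity) or `dissolve` (falling). A UCST
transition is `dissolve`-on-heating / `appear`-on-cooling; an LCST the
reverse; the low-salt arginine-rich system shows both pairs. Crossing
temperatures are interpolated linearly because the 2 °C/min ramp is sampled
on a coarse grid. When both ramps report the same number of crossings they
are paired in temperature order and hysteresis is the heating-minus-cooling
temperature per pair; with unequal counts no pairing is attempted and the
hysteresis vector is empty rather than guessed.

**Composition.** Quantitative amino acid analysis is calibrated by ordinary
least squares of blank-corrected peak area on standard concentration
(four standards in the protocol; at least two distinct concentrations are
required). The intercept is free by default — the protocol says only
"linear regression" — with a forced-zero option. Unknowns are inverted
through the line; negative concentrations are clipped to zero with a
warning. Dense phases too viscous or too small to assay directly are
recovered by mass balance,
$c_{dense} = (c_{tot} V_{tot} - c_{dil} V_{dil}) / V_{dense}$, with volume
consistency checked and negative results beyond a relative tolerance of
1e-8 treated as inconsistent data rather than clipped.

## Microrheology

Probe particles (radius 1 μm, default temperature 295.15 K) embedded in the
dense phase perform thermal motion. The estimator chain is:

1. **MSD** — per track, the time-averaged squared displacement over all
   overlapping origins; tracks are then combined by an unweighted ensemble
   average. The protocol says only "averaged MSD"; a pair-count-weighted
   mode is provided. Lags run to 25% of the longest track by default
   because time-averaged MSDs lose statistical reliability at long lags.
2. **Power-law fit** — least squares of log MSD on log lag,
   $\mathrm{MSD}(\tau) = 4 D \tau^{\alpha}$. The diffusive exponent
   $\alpha$ should be 1 in a Newtonian medium; values outside [0.9, 1.1]
   trigger a "non-diffusive" warning, but $\eta$ is still computed (the
   protocol applies Stokes–Einstein without an $\alpha$ gate).
3. **Stokes–Einstein** — $\eta = k_B T / (6 \pi D r)$.

Static localization error is not subtracted by default (the protocol does
not mention it); the generator can inject it, the expected MSD then being
$4 D \tau + 4\sigma_{loc}^2$, and the fitter offers an optional constant
offset term. The two acquisition conditions (20 ms frames at low salt, 1 s
at high salt) are carried as protocol defaults.

## Interfacial tension by droplet coalescence

After two droplets merge, the aspect ratio $A = (L - W)/(L + W)$ relaxes as
$A(t) = A_0 e^{-t/\tau}$ with $\tau \cong (19/20)\,\eta R/\sigma$. The
fitter initializes from the log-linear solution (already exact on noiseless
data) and refines by nonlinear least squares; a series whose total
log-decay over the observation window is unresolvable is a fit error, not a
huge-τ answer. Inverting with the microrheology viscosity and the
post-coalescence radius gives $\sigma$.

## PFG-NMR diffusion

Echo attenuation follows the Stejskal–Tanner relation
$\psi = \exp(-(\gamma g \delta)^2 D (\Delta - \delta/3))$ with
$\delta$ = 1 ms, $\Delta$ = 20 ms and 16 gradient amplitudes as acquisition
defaults. Gradients are accepted in G/cm as acquired and converted to G/m
internally; the proton gyromagnetic ratio defaults to
2.6752×10⁴ s⁻¹G⁻¹ and is overridable. The fit is performed on the
transformed axis $b = (\gamma g \delta)^2(\Delta - \delta/3)$: the
log-linear solution through the origin initializes a bounded
one-dimensional refinement minimizing the residual sum of squares in
$\psi$ (uniform weights; log-space weighting by option, in which case the
initializer *is* the answer). A decay that trends upward is an error; one
that is flat returns $D = 0$.

## INDUS water counting and UWHAM

**Hydration volume.** The dynamic hydration volume of a tagged residue is
the union of spheres of radius $R_v$ (default 0.55 nm, roughly the first
hydration shell) pinned to its heavy atoms. `sharp_count()` is the binary
occupancy; `coarse_count()` is the differentiable observable used for
biasing: each water–sphere indicator is smoothed with a truncated,
normalized Gaussian (width $\sigma$ = 0.01 nm, truncation $r_c$ = 0.02 nm),
and sphere contributions combine by the complement-product rule
$\tilde h = 1 - \prod_j (1 - \tilde h_j)$. The published construction does
not state how sub-volume indicators combine; complement-product is chosen
because it is smooth, bounded in [0, 1], and reduces exactly to the
single-sphere indicator for one or coincident spheres. By construction the
coarse count equals the sharp count whenever no water lies within $r_c$ of
a sphere surface, and converges to it as $\sigma, r_c \to 0$; both facts
are tested against brute-force counting.

**Biased sampling.** Model landscapes are tabulated $\beta F(N)$ on an
integer grid (a quartic double well with wells at N = 10 and 35 and a
4 kBT barrier is the standard test landscape). Umbrella windows draw i.i.d.
samples from the exactly normalized biased distribution
$P_{bias}(N) \propto \exp(-\beta F(N) - \beta\kappa (N - N^*)^2/2)$ —
direct categorical sampling, chosen deliberately so that UWHAM tests are
not confounded by Markov-chain convergence. Negative bias centers are legal
and simply push toward an empty volume; samples remain non-negative. The
equilibration-discard field exists for Markov-chain inputs (the simulation
protocol discards the first 1 ns of 5 ns, i.e. 20%) and is zero for exact
sampling.

**UWHAM.** The binless self-consistent equations are solved for the
per-window free energies with the first window pinned to zero,
convergence criterion max |Δf| < 1e-8 kBT, iteration cap 1e5. Numerically,
duplicated sample values are collapsed with multiplicities first (lossless
for the discrete sampler), and the iteration is warm-started at the
minimizer of the equivalent convex objective (quasi-Newton descent followed
by an exact Newton refinement computed from row-scaled, bounded weights);
the damped self-consistent iteration then verifies and polishes the fixed
point. This matters because plain self-consistent iteration contracts
arbitrarily slowly when window overlap is poor. The unbiased weights are
assembled into $P_v(N)$ on the integer grid (continuous samples are
binned to the nearest integer, half-integer ties rounding toward the
window's own bias center) and $\beta F(N) = -\ln P_v(N)$ is reported
min-shifted to zero, with $N_0$ the profile argmin.

**Window overlap.** Adjacent windows are checked for overlap of their
sampled distributions (histogram overlap coefficient; warning below 0.01).
This is not pedantry: at the study parameters $\kappa$ = 10 kBT and spacing
3, the biased distributions have standard deviation $1/\sqrt{10} \approx
0.32$ in N, so neighboring windows share essentially no sampled support and
the relative free energies *between* windows are statistically
unconstrained — the likelihood is nearly flat along inter-block directions,
and two fully converged solvers can land kBT apart along that ridge. The
`analysis/06` driver demonstrates both regimes on the same landscape: the
stiff study schedule (large reconstruction error, with the warning) and an
overlapping reference at $\kappa$ = 0.5 kBT with 20 000 samples/window
(reconstruction within ~0.1 kBT, verified in the test suite over three
seeds against an independently coded unit-bin WHAM oracle). In real
biased MD this stiffness is workable because continuous coarse counts
fluctuate and correlate differently than exact integer-lattice samples; on
the integer lattice it is not, and the package reports it honestly rather
than smoothing over it.

**Per-water dewetting cost.** The published analysis plots an "average
dehydration free energy per water molecule" against fractional occupancy
without giving the normalization formula. The package's documented choice is
$y(N) = (\beta F(N) - \beta F(N_0)) / (N_0 - N)$ against $x = N/N_0$ for
$N < N_0$: the total cost of expelling $N_0 - N$ waters divided by their
number. For a quadratic well this is linear in depletion (a closed form the
tests assert), and a flat profile costs zero. A lower per-water cost is
classified as the more hydrophobic surface. Whether profiles from several
probed residues are averaged before or after this normalization is also
unstated; both reducers are provided (`average_profiles()` then
`per_water_profile()`, or the reverse).

The atomistic result this machinery supports — the ~0.6 kBT per-water gap
between arginine and lysine — requires explicit-solvent MD and is outside
this package's scope; what is validated here is the estimator itself on
landscapes with known truth.

## Chain conformation

Radius of gyration (mass-weighted RMS distance from the center of mass),
end-to-end distance (first to last site by default, minimum-image when a
box is given; which atoms define the termini is configurable since the
published choice is unstated), normalized Rg/dee histograms
(Freedman–Diaconis bins by default), bootstrap confidence intervals for
between-ensemble mean differences, contact maps (fraction of frames with
site–site distance ≤ 0.6 nm, pairs closer than 3 in sequence zeroed — the
published "nonadjacent residues" criterion made concrete), and geometric
hydrogen bonds (D–A ≤ 0.35 nm and D–H–A within 30° of linear; standard
criterion, unstated in the protocol). Freely-jointed ensembles reproduce
$\langle d_{ee}^2 \rangle = (n-1)b^2$ and the exact discrete
$\langle R_g^2 \rangle = b^2 (n^2-1)/(6n)$ within three standard errors at
n = 50 over 2000 frames; contact maps and H-bond counts match brute-force
enumeration.

## What the synthetic data do and do not emulate

The generators reproduce the *statistical models* the estimators assume:
free 2-D Brownian motion with optional static localization noise,
single-exponential echo and aspect-ratio decays with multiplicative or
additive Gaussian noise, sigmoid-edged phase windows with ramp hysteresis,
exactly sampled umbrella windows, Poisson solvation, and ideal or
self-avoiding chains. They deliberately do not emulate confined or
viscoelastic (subdiffusive) probe motion, particle detection and linking
errors, baseline drifts and bubbles in turbidity, multi-component
diffusion, restricted-diffusion NMR signatures, Markov-chain correlation in
umbrella samples, or atomistic water structure. A passing recovery test
therefore shows the estimator is correct *under its stated model*; it does
not show the model covers every artifact of real acquisitions. Every
generated dataset records its full parameter set and seed
(`get_ground_truth()`, JSON sidecars), and identical parameters and seed
give byte-identical output without disturbing the caller's RNG stream.

## Problem sizes

The recovery studies run at the scale the protocols describe where that is
desk-feasible: 50 tracks × 2000 frames per tracking condition (five seeds,
median, for the viscosity studies), 16-echo gradient sweeps, 50-frame
coalescence series, 22 umbrella windows × 5000 samples at the study
schedule (20 000 at the overlapping reference), 100 seeded solvated frames
for the counting checks, and 2000-frame chain ensembles. These sizes were
chosen so the statistical tolerances in the tests (three standard errors,
15% viscosity, 10% tension, 2% diffusivity) are meaningful.

## Known limitations

- No molecular dynamics engine, biased or otherwise: force evaluation,
  thermostats and water models are out of scope, as are rheometer moduli,
  EPR lineshape fitting, ODNP coupling-factor theory (reported diffusivity
  values are consumed as inputs only) and FRAP modelling.
- Molecular input is limited to programmatic frames and PDB files (via the
  suggested bio3d package); compressed trajectory formats are not read.
- UWHAM uncertainty is not estimated beyond the overlap diagnostics; a
  bootstrap over windows would be the natural extension.
- The threshold detector classifies windows; it does not fit a
  thermodynamic model (no Flory–Huggins fitting, no salt-type/Hofmeister
  prediction — curves for different salts are just additional inputs).
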