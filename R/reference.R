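#' Published dense-phase properties of the model coacervate systems
#'
#' Reported physical properties of the dense (coacervate) phase for the three
#' model systems: hyaluronic acid with epsilon-poly-L-lysine at low salt, and
#' hyaluronic acid with protamine at low salt (no added NaCl) and at high salt
#' (4 M NaCl). These fixed reference measurements serve two roles in the
#' package: as inputs to ratio analyses (relative concentration, viscosity and
#' interfacial tension between conditions) and as ground-truth parameters for
#' the synthetic-data recovery studies (e.g. Brownian tracks generated at a
#' known viscosity).
#'
#' @return A tibble with columns `system`, `concentration_mg_ml` (total
#'   polyelectrolyte concentration of the dense phase), `viscosity_Pa_s`
#'   (from particle-tracking microrheology) and `interfacial_tension_N_m`
#'   (from droplet coalescence).
#' @export
#' @examples
#' dense_phase_reference()
dense_phase_reference <- function() {
  tibble::tibble(
    system = c("low_salt_HA_ePL", "low_salt_HA_protamine", "high_salt_HA_protamine"),
    concentration_mg_ml = c(188, 323.4, 1909),
    viscosity_Pa_s = c(0.0244, 0.3052, 28.47),
    interfacial_tension_N_m = c(2.34e-5, 3.19e-5, 4.20e-3)
  )
}

#' Reported dense-phase component concentrations from amino acid analysis
#'
#' Protamine and hyaluronic-acid concentrations measured by quantitative amino
#' acid analysis in the dense phase of HA-protamine coacervates formed at low
#' salt and at high salt (4 M NaCl), with their standard deviations.
#'
#' @return A tibble with one row per salt condition.
#' @export
phase_composition_reference <- function() {
  tibble::tibble(
    condition = c("low_salt", "high_salt"),
    protamine_mg_ml = c(158.3, 1227.8),
    protamine_sd = c(20.7, 76.9),
    ha_mg_ml = c(165.2, 680.9),
    ha_sd = c(22.8, 42.3)
  )
}

#' Reported water diffusivities (PFG-NMR and ODNP)
#'
#' Interstitial water self-diffusion coefficients from pulsed-field-gradient
#' NMR and hydration-water diffusivities from Overhauser dynamic nuclear
#' polarization (ODNP) for the dilute and dense phases of the model systems,
#' in m^2/s. `water_literature` is the accepted pure-water self-diffusivity
#' at room temperature, used as the generating value in the synthetic
#' echo-decay recovery study. The ODNP values are consumed only as fixed
#' inputs to ratio computations (e.g. the dilute/dense hydration-water
#' retardation factor); no ODNP theory is implemented here.
#'
#' @return A named list with elements `water_literature` (numeric),
#'   `pfg` (tibble: system, phase, D_m2_s) and `odnp_coupling` (tibble:
#'   system, phase, D_m2_s).
#' @export
water_diffusivity_reference <- function() {
  list(
    water_literature = 2.40e-9,
    pfg = tibble::tibble(
      system = c("DW", "low_salt_HA_ePL", "low_salt_HA_ePL",
                 "low_salt_HA_protamine", "low_salt_HA_protamine"),
      phase = c("pure", "dilute", "dense", "dilute", "dense"),
      D_m2_s = c(2.52e-9, 2.35e-9, 1.51e-9, 2.52e-9, 1.34e-9)
    ),
    odnp_coupling = tibble::tibble(
      system = c("low_salt_HA_ePL", "low_salt_HA_ePL",
                 "low_salt_HA_protamine", "low_salt_HA_protamine",
                 "high_salt_HA_protamine"),
      phase = c("dilute", "dense", "dilute", "dense", "dense"),
      D_m2_s = c(8.27e-10, 8.69e-10, 9.41e-10, 7.09e-10, 0.52e-10)
    )
  )
}

#' Default acquisition parameters of the microrheology and PFG-NMR protocols
#'
#' Probe radius (1 um), temperature (295.15 K), the two frame intervals used
#' for particle tracking (20 ms at low salt, 1 s at high salt), and the
#' gradient-pulse timings of the diffusion measurements (delta = 1 ms,
#' Delta = 20 ms, 16 echoes).
#'
#' @return A named list.
#' @export
protocol_defaults <- function() {
  list(
    probe_radius_m = 1e-6,
    temperature_K = 295.15,
    frame_interval_low_salt_s = 0.02,
    frame_interval_high_salt_s = 1,
    pfg_delta_s = 1e-3,
    pfg_Delta_s = 20e-3,
    pfg_n_echoes = 16L
  )
}
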