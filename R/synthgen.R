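# Seeded synthetic-data generators. Each returns the same container the
# corresponding analysis stage consumes, with the generating parameters
# recorded in a `ground_truth` attribute. Identical (params, seed) give
# byte-identical output.

#' Generate 2-D Brownian probe-particle tracks at known viscosity
#'
#' Simulates free (unconfined) two-dimensional Brownian motion of probe
#' particles embedded in a Newtonian fluid, the forward model of passive
#' particle-tracking microrheology. The generating diffusion coefficient is
#' the Stokes-Einstein value \eqn{D = k_B T / (6 \pi \eta r)}; per-frame
#' increments are Gaussian with variance \eqn{2 D \Delta t} per axis, and an
#' optional static localization error of standard deviation `noise_sd` is
#' added to each measured position. The population mean-squared displacement
#' at lag \eqn{\tau} is then \eqn{4 D \tau + 4\,\mathrm{noise\_sd}^2} in
#' expectation.
#'
#' @param viscosity Dynamic viscosity of the medium, Pa s.
#' @param probe_radius Probe particle radius, m (default 1 um).
#' @param temperature Absolute temperature, K (default 295.15).
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames per track (>= 2).
#' @param n_particles Number of independent tracks.
#' @param noise_sd Localization error per axis, m (default 0).
#' @param seed Integer seed.
#' @return A `probe_tracks` tibble with columns `particle_id`, `frame`,
#'   `x_um`, `y_um`; attributes `frame_interval_s`, `probe_radius_m`,
#'   `temperature_K` and a `ground_truth` record (including the generating
#'   `D_m2_s`).
#' @seealso [compute_msd()], [fit_msd_powerlaw()], [viscosity_stokes_einstein()]
#' @export
#' @examples
#' tr <- gen_brownian_tracks(0.3052, n_frames = 100, n_particles = 5, seed = 1)
#' get_ground_truth(tr)$D_m2_s  # ~7.08e-16 m^2/s
gen_brownian_tracks <- function(viscosity, probe_radius = 1e-6,
                                temperature = 295.15, frame_interval = 0.02,
                                n_frames = 2000L, n_particles = 50L,
                                noise_sd = 0, seed = 1L) {
  assert_positive(viscosity, "viscosity")
  assert_positive(probe_radius, "probe_radius")
  assert_positive(temperature, "temperature")
  assert_positive(frame_interval, "frame_interval")
  n_frames <- assert_count(n_frames, "n_frames", min = 2L)
  n_particles <- assert_count(n_particles, "n_particles")
  assert_nonneg(noise_sd, "noise_sd")

  D <- kB_J_per_K * temperature / (6 * pi * viscosity * probe_radius) # m^2/s
  step_sd_um <- sqrt(2 * D * frame_interval) * 1e6
  noise_um <- noise_sd * 1e6

  xy <- with_seed(seed, {
    dx <- matrix(rnorm((n_frames - 1L) * n_particles, sd = step_sd_um),
                 n_frames - 1L, n_particles)
    dy <- matrix(rnorm((n_frames - 1L) * n_particles, sd = step_sd_um),
                 n_frames - 1L, n_particles)
    x <- rbind(0, apply(dx, 2L, cumsum))
    y <- rbind(0, apply(dy, 2L, cumsum))
    if (noise_um > 0) {
      x <- x + matrix(rnorm(n_frames * n_particles, sd = noise_um), n_frames)
      y <- y + matrix(rnorm(n_frames * n_particles, sd = noise_um), n_frames)
    }
    list(x = x, y = y)
  })

  out <- tibble::tibble(
    particle_id = rep(seq_len(n_particles), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n_particles),
    x_um = as.vector(xy$x),
    y_um = as.vector(xy$y)
  )
  structure(out,
    class = c("probe_tracks", class(out)),
    frame_interval_s = frame_interval,
    probe_radius_m = probe_radius,
    temperature_K = temperature,
    ground_truth = ground_truth(
      viscosity_Pa_s = viscosity, probe_radius_m = probe_radius,
      temperature_K = temperature, D_m2_s = D,
      frame_interval_s = frame_interval, n_frames = n_frames,
      n_particles = n_particles, noise_sd_m = noise_sd, seed = seed
    )
  )
}

#' Generate a Stejskal-Tanner echo-attenuation decay
#'
#' Evaluates \eqn{\psi(g) = \exp(-(\gamma g \delta)^2 D (\Delta - \delta/3))}
#' at the requested gradient amplitudes and applies multiplicative Gaussian
#' noise of fractional standard deviation `noise_sd`.
#'
#' @param D Self-diffusion coefficient, m^2/s (>= 0).
#' @param gradients Gradient amplitudes, G/cm; at least 2 distinct
#'   non-negative values (the standard acquisition uses 16).
#' @param delta Effective gradient-pulse duration, s.
#' @param Delta Total diffusion time, s; must exceed `delta/3`.
#' @param gamma Gyromagnetic ratio, s^-1 G^-1 (default: proton).
#' @param noise_sd Fractional (multiplicative) noise level (default 0).
#' @param seed Integer seed.
#' @return An `echo_decay` tibble with columns `g_Gcm`, `psi` and attributes
#'   `delta_s`, `Delta_s`, `gamma_sG`, plus a `ground_truth` record.
#' @seealso [fit_diffusion()], [stejskal_tanner()]
#' @export
gen_echo_decay <- function(D, gradients, delta = 1e-3, Delta = 20e-3,
                           gamma = proton_gamma_sG, noise_sd = 0, seed = 1L) {
  assert_nonneg(D, "D")
  if (!is.numeric(gradients) || length(unique(gradients)) < 2L)
    stop_param("`gradients` must contain at least 2 distinct values")
  if (any(!is.finite(gradients)) || any(gradients < 0))
    stop_param("`gradients` must be finite and non-negative")
  assert_positive(delta, "delta")
  assert_positive(gamma, "gamma")
  assert_scalar_number(Delta, "Delta")
  if (Delta <= delta / 3)
    stop_param("`Delta` must exceed `delta`/3 (non-positive effective diffusion time)")
  assert_nonneg(noise_sd, "noise_sd")

  psi <- stejskal_tanner(gradients, D, delta, Delta, gamma)
  if (noise_sd > 0)
    psi <- with_seed(seed, psi * (1 + rnorm(length(psi), sd = noise_sd)))

  out <- tibble::tibble(g_Gcm = as.numeric(gradients), psi = psi)
  structure(out,
    class = c("echo_decay", class(out)),
    delta_s = delta, Delta_s = Delta, gamma_sG = gamma,
    ground_truth = ground_truth(D_m2_s = D, delta_s = delta, Delta_s = Delta,
                                gamma_sG = gamma, noise_sd = noise_sd,
                                seed = seed)
  )
}

#' Generate a droplet-coalescence aspect-ratio relaxation
#'
#' After two droplets merge, the elongated composite relaxes to a sphere with
#' aspect ratio \eqn{A(t) = A_0 e^{-t/\tau}} where
#' \eqn{\tau \cong (19/20)\,\eta R / \sigma} for a droplet of viscosity
#' \eqn{\eta}, post-coalescence radius \eqn{R} and interfacial tension
#' \eqn{\sigma}. Additive Gaussian noise of standard deviation `noise_sd`
#' (in A units) emulates shape-measurement error. Length/width columns
#' consistent with the final radius are included for the tabular writers.
#'
#' @param eta Dense-phase viscosity, Pa s.
#' @param sigma_int Interfacial tension, N/m.
#' @param droplet_radius Droplet radius after coalescence, m.
#' @param A0 Initial aspect ratio, in (0, 1).
#' @param frame_interval Time between frames, s.
#' @param n_frames Number of frames.
#' @param noise_sd Additive noise on A (default 0).
#' @param seed Integer seed.
#' @return A `coalescence_series` tibble with columns `t_s`, `A`, `L_um`,
#'   `W_um`; attribute `droplet_radius_m` and a `ground_truth` record
#'   (including the generating `tau_s`).
#' @seealso [fit_relaxation_time()], [interfacial_tension()]
#' @export
gen_coalescence_series <- function(eta, sigma_int, droplet_radius, A0 = 0.5,
                                   frame_interval = NULL, n_frames = 50L,
                                   noise_sd = 0, seed = 1L) {
  assert_positive(eta, "eta")
  assert_positive(sigma_int, "sigma_int")
  assert_positive(droplet_radius, "droplet_radius")
  assert_scalar_number(A0, "A0")
  if (A0 <= 0 || A0 >= 1) stop_param("`A0` must lie strictly between 0 and 1")
  n_frames <- assert_count(n_frames, "n_frames", min = 4L)
  assert_nonneg(noise_sd, "noise_sd")

  tau <- (19 / 20) * eta * droplet_radius / sigma_int
  if (is.null(frame_interval)) frame_interval <- 5 * tau / n_frames
  assert_positive(frame_interval, "frame_interval")

  t <- (seq_len(n_frames) - 1L) * frame_interval
  A <- A0 * exp(-t / tau)
  if (noise_sd > 0) A <- with_seed(seed, A + rnorm(n_frames, sd = noise_sd))
  Ac <- pmin(pmax(A, 0), 1 - 1e-9)
  R_um <- droplet_radius * 1e6

  out <- tibble::tibble(
    t_s = t, A = A,
    L_um = 2 * R_um * (1 + Ac),
    W_um = 2 * R_um * (1 - Ac)
  )
  structure(out,
    class = c("coalescence_series", class(out)),
    droplet_radius_m = droplet_radius,
    ground_truth = ground_truth(eta_Pa_s = eta, sigma_N_m = sigma_int,
                                droplet_radius_m = droplet_radius,
                                tau_s = tau, A0 = A0, noise_sd = noise_sd,
                                seed = seed)
  )
}

#' Construct a turbidity curve
#'
#' Low-level constructor validating the turbidity-curve contract: a strictly
#' increasing control axis (salt concentration in mM or temperature in
#' degrees C), non-negative optical density at 600 nm, and a ramp label.
#'
#' @param control Strictly increasing control values.
#' @param od600 Optical densities, same length, >= 0.
#' @param ramp One of `"none"`, `"heating"`, `"cooling"`.
#' @param replicate_id Optional replicate label.
#' @return A `turbidity_curve` tibble.
#' @export
turbidity_curve <- function(control, od600, ramp = "none", replicate_id = NA) {
  if (length(control) != length(od600))
    stop_param("`control` and `od600` must have the same length")
  if (any(!is.finite(control)) || any(diff(control) <= 0))
    stop_param("`control` must be finite and strictly increasing")
  if (any(!is.finite(od600)) || any(od600 < 0))
    stop_param("`od600` must be finite and non-negative")
  ramp <- match.arg(ramp, c("none", "heating", "cooling"))
  out <- tibble::tibble(control = as.numeric(control), od600 = as.numeric(od600))
  structure(out, class = c("turbidity_curve", class(out)),
            ramp = ramp, replicate_id = replicate_id)
}

#' Generate a synthetic turbidity profile with one or more phase windows
#'
#' Produces a smooth turbidity curve on a control grid (salt or temperature)
#' as a sum of bumps, one per phase window, with sigmoidal edges of width
#' `sharpness`. Heating/cooling ramps shift the window edges by
#' +/- `hysteresis_shift`/2 (dissolution on heating occurs at higher control
#' values than condensation on cooling), emulating thermal hysteresis.
#'
#' @param windows List of `c(lo, hi)` intervals in control units; must be
#'   sorted and disjoint. An empty list gives a flat zero curve.
#' @param amplitude Peak turbidity per window, OD600 units.
#' @param sharpness Edge width in control units.
#' @param grid Sorted control grid on which to evaluate.
#' @param ramp `"none"`, `"heating"` or `"cooling"`.
#' @param hysteresis_shift Total heating-minus-cooling edge shift, control units.
#' @param noise_sd Additive noise, OD600 units (default 0; output clipped at 0).
#' @param seed Integer seed.
#' @return A `turbidity_curve` with `ground_truth` attached.
#' @seealso [detect_phase_windows()], [detect_cloud_points()]
#' @export
gen_turbidity_profile <- function(windows, amplitude = 1, sharpness = 1, grid,
                                  ramp = "none", hysteresis_shift = 0,
                                  noise_sd = 0, seed = 1L) {
  ramp <- match.arg(ramp, c("none", "heating", "cooling"))
  assert_positive(amplitude, "amplitude")
  assert_positive(sharpness, "sharpness")
  assert_nonneg(noise_sd, "noise_sd")
  if (any(!is.finite(grid)) || is.unsorted(grid, strictly = TRUE))
    stop_param("`grid` must be finite and strictly increasing")
  windows <- validate_windows(windows)

  shift <- switch(ramp, none = 0, heating = hysteresis_shift / 2,
                  cooling = -hysteresis_shift / 2)
  od <- rep(0, length(grid))
  for (w in windows) {
    lo <- w[1] + shift
    hi <- w[2] + shift
    od <- od + amplitude *
      stats::plogis((grid - lo) / sharpness) *
      stats::plogis((hi - grid) / sharpness)
  }
  if (noise_sd > 0)
    od <- with_seed(seed, od + rnorm(length(grid), sd = noise_sd))
  od <- pmax(od, 0)

  out <- turbidity_curve(grid, od, ramp = ramp)
  attr(out, "ground_truth") <- ground_truth(
    windows = windows, amplitude = amplitude, sharpness = sharpness,
    ramp = ramp, hysteresis_shift = hysteresis_shift, noise_sd = noise_sd,
    seed = seed
  )
  out
}

validate_windows <- function(windows) {
  if (is.matrix(windows)) windows <- asplit(windows, 1L)
  if (length(windows) == 0L) return(list())
  windows <- lapply(windows, function(w) {
    if (length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2])
      stop_param("each window must be c(lo, hi) with lo < hi")
    as.numeric(w)
  })
  lo <- vapply(windows, `[`, numeric(1L), 1L)
  hi <- vapply(windows, `[`, numeric(1L), 2L)
  if (is.unsorted(lo) || any(lo[-1L] <= hi[-length(hi)]))
    stop_param("windows must be sorted and disjoint")
  windows
}

#' Parse an umbrella-window schedule string
#'
#' Parses the compact `"{start..step..stop}"` notation for the harmonic-bias
#' centers of an umbrella-sampling run, e.g. `"{-9..3..54}"` for 22 windows
#' at -9, -6, ..., 54. The stop value is inclusive when reachable.
#'
#' @param text Schedule string.
#' @return Numeric vector of N* values.
#' @export
#' @examples
#' parse_nstar_schedule("{-9..3..54}")
parse_nstar_schedule <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop_param("`text` must be a single string")
  pat <- "^\\{(-?[0-9]+\\.?[0-9]*)\\.\\.(-?[0-9]+\\.?[0-9]*)\\.\\.(-?[0-9]+\\.?[0-9]*)\\}$"
  m <- regmatches(text, regexec(pat, text))[[1L]]
  if (length(m) != 4L)
    stop_param("schedule must look like \"{start..step..stop}\", e.g. \"{-9..3..54}\"")
  start <- as.numeric(m[2L]); step <- as.numeric(m[3L]); stop_ <- as.numeric(m[4L])
  if (step <= 0 || stop_ < start) stop_param("need step > 0 and stop >= start")
  seq(start, stop_, by = step)
}

#' Draw exact samples from a biased umbrella window over a model landscape
#'
#' For each bias center N* in `nstar_schedule`, draws `n_samples` i.i.d.
#' water-number samples from the exactly normalized biased distribution
#' \eqn{P_{bias}(N) \propto \exp(-\beta F(N) - \beta\kappa (N - N^*)^2 / 2)}
#' over the tabulated integer range of the model free-energy landscape.
#' Direct categorical sampling means there is no Markov-chain burn-in, so the
#' equilibration discard of every window is zero; this isolates the UWHAM
#' unbiasing step from sampler-convergence questions.
#'
#' @param F_model Data frame (or tibble) with columns `N` (contiguous
#'   integers) and `betaF` (finite, kBT units).
#' @param kappa Harmonic bias strength, kBT per N^2 (> 0).
#' @param nstar_schedule Numeric vector of bias centers, or a schedule string
#'   accepted by [parse_nstar_schedule()]. Centers may be negative.
#' @param n_samples Samples per window (>= 1).
#' @param seed Integer seed.
#' @return A list of `umbrella_window` objects (fields `nstar`, `kappa`,
#'   `samples`, `n_equilibration_discarded`), classed
#'   `umbrella_window_set`, with a `ground_truth` record.
#' @seealso [uwham_unbias()], [sample_model_biased()]
#' @export
gen_umbrella_windows <- function(F_model, kappa, nstar_schedule, n_samples,
                                 seed = 1L) {
  F_model <- validate_F_model(F_model)
  assert_positive(kappa, "kappa")
  if (is.character(nstar_schedule))
    nstar_schedule <- parse_nstar_schedule(nstar_schedule)
  if (length(nstar_schedule) == 0L || any(!is.finite(nstar_schedule)))
    stop_param("`nstar_schedule` must be a non-empty vector of finite bias centers")
  n_samples <- assert_count(n_samples, "n_samples")

  N <- F_model$N
  bF <- F_model$betaF
  windows <- with_seed(seed, {
    lapply(nstar_schedule, function(ns) {
      logw <- -bF - 0.5 * kappa * (N - ns)^2
      w <- exp(logw - max(logw))
      samples <- sample(N, n_samples, replace = TRUE, prob = w)
      structure(
        list(nstar = ns, kappa = kappa, samples = as.numeric(samples),
             n_equilibration_discarded = 0L),
        class = "umbrella_window"
      )
    })
  })
  structure(windows, class = "umbrella_window_set",
            ground_truth = ground_truth(F_model = F_model, kappa = kappa,
                                        nstar_schedule = nstar_schedule,
                                        n_samples = n_samples, seed = seed))
}

validate_F_model <- function(F_model) {
  if (!is.data.frame(F_model) || !all(c("N", "betaF") %in% names(F_model)))
    stop_param("`F_model` must be a data frame with columns `N` and `betaF`")
  N <- F_model$N
  if (any(N != floor(N)) || !identical(as.numeric(N), as.numeric(seq(min(N), max(N)))))
    stop_param("`F_model$N` must be a contiguous integer range")
  if (any(!is.finite(F_model$betaF)))
    stop_param("`F_model$betaF` must be finite everywhere on the range")
  tibble::tibble(N = as.numeric(N), betaF = as.numeric(F_model$betaF))
}

#' Generate a Poisson-solvated molecular frame
#'
#' Places water-oxygen positions as a uniform Poisson point process of the
#' requested number density in a rectangular box, around fixed solute heavy
#' atoms. A toy stand-in for an explicit-solvent snapshot, used to exercise
#' the hydration-volume water-counting observables with analytically known
#' expectations (mean count = density x volume).
#'
#' @param solute_atom_positions Numeric matrix (n x 3) of heavy-atom
#'   coordinates, nm; must lie inside the box.
#' @param water_number_density Water number density, nm^-3 (>= 0;
#'   bulk water is about 33 nm^-3).
#' @param box Box edge lengths, nm (length-3, positive).
#' @param seed Integer seed.
#' @param periodic Treat the box as periodic for distance computations.
#' @return A `molecular_frame` (list with `heavy_atom_positions`,
#'   `water_oxygen_positions`, `box`, `periodic`), with `ground_truth`.
#' @seealso [sharp_count()], [coarse_count()], [hydration_volume()]
#' @export
gen_solvated_frame <- function(solute_atom_positions, water_number_density,
                               box, seed = 1L, periodic = FALSE) {
  sol <- as.matrix(solute_atom_positions)
  if (ncol(sol) != 3L || any(!is.finite(sol)))
    stop_param("`solute_atom_positions` must be a finite n x 3 matrix (nm)")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_param("`box` must be three positive edge lengths (nm)")
  assert_nonneg(water_number_density, "water_number_density")
  if (any(sol < 0) || any(sweep(sol, 2L, box, `>`)))
    stop_param("solute atoms must lie inside the box")

  waters <- with_seed(seed, {
    n_w <- rpois(1L, water_number_density * prod(box))
    matrix(runif(3L * n_w) * rep(box, each = n_w), ncol = 3L)
  })
  structure(
    list(heavy_atom_positions = sol, water_oxygen_positions = waters,
         box = as.numeric(box), periodic = isTRUE(periodic)),
    class = "molecular_frame",
    ground_truth = ground_truth(water_number_density_nm3 = water_number_density,
                                box_nm = as.numeric(box), seed = seed)
  )
}

#' Generate an ideal or self-avoiding bead-chain ensemble
#'
#' Freely-jointed chains take each bond as an independent uniformly random
#' direction of exact length `bond_length`, so the ensemble obeys the
#' ideal-chain laws \eqn{\langle d_{ee}^2 \rangle = (n-1) b^2} and
#' \eqn{\langle R_g^2 \rangle \approx (n-1) b^2 / 6}. Self-avoiding chains are
#' grown bead-by-bead, rejecting placements closer than `0.9 * bond_length`
#' to any non-bonded bead, with up to `max_retries` restarts per frame before
#' a generation error is raised.
#'
#' @param model `"freely_jointed"` or `"self_avoiding"`.
#' @param n_beads Number of beads (>= 2).
#' @param bond_length Bond length, nm.
#' @param n_frames Number of independent frames (>= 1).
#' @param seed Integer seed.
#' @param max_retries Restart budget per frame for the self-avoiding walk.
#' @return A `chain_ensemble` (list with `frames`, a list of n x 3 matrices;
#'   `masses`; `termini`; `bond_length_nm`; `model`), with `ground_truth`.
#' @seealso [radius_of_gyration()], [end_to_end()], [ensemble_distributions()]
#' @export
gen_chain_ensemble <- function(model = c("freely_jointed", "self_avoiding"),
                               n_beads, bond_length = 0.38, n_frames = 100L,
                               seed = 1L, max_retries = 1000L) {
  model <- match.arg(model)
  n_beads <- assert_count(n_beads, "n_beads", min = 2L)
  assert_positive(bond_length, "bond_length")
  n_frames <- assert_count(n_frames, "n_frames")
  max_retries <- assert_count(max_retries, "max_retries")

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      if (model == "freely_jointed") {
        v <- matrix(rnorm(3L * (n_beads - 1L)), ncol = 3L)
        v <- v / sqrt(rowSums(v^2))
        rbind(0, apply(v * bond_length, 2L, cumsum))
      } else {
        grow_self_avoiding(n_beads, bond_length, max_retries)
      }
    })
  })
  structure(
    list(frames = frames, masses = rep(1, n_beads),
         termini = c(1L, n_beads), bond_length_nm = bond_length,
         model = model),
    class = "chain_ensemble",
    ground_truth = ground_truth(model = model, n_beads = n_beads,
                                bond_length_nm = bond_length,
                                n_frames = n_frames, seed = seed)
  )
}

grow_self_avoiding <- function(n_beads, b, max_retries) {
  min_sep2 <- (0.9 * b)^2
  for (attempt in seq_len(max_retries)) {
    coords <- matrix(0, n_beads, 3L)
    ok <- TRUE
    for (i in 2:n_beads) {
      placed <- FALSE
      for (try in 1:50) {
        v <- rnorm(3L)
        v <- v / sqrt(sum(v^2)) * b
        cand <- coords[i - 1L, ] + v
        if (i <= 2L) { placed <- TRUE } else {
          prev <- coords[seq_len(i - 2L), , drop = FALSE]
          d2 <- rowSums(sweep(prev, 2L, cand)^2)
          placed <- all(d2 >= min_sep2)
        }
        if (placed) { coords[i, ] <- cand; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(coords)
  }
  stop("self-avoiding chain generation failed after ", max_retries,
       " restarts", call. = FALSE)
}
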