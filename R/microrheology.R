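# Passive particle-tracking microrheology: MSD, power-law fit,
# Stokes-Einstein viscosity.

#' Time- and ensemble-averaged mean-squared displacement
#'
#' For each track the MSD at lag \eqn{\ell} frames is the time average of the
#' squared displacement over all overlapping start points; tracks are then
#' combined by an unweighted ensemble average (the default), or weighted by
#' the number of displacement pairs (`weighting = "pairs"`). Lags run from one
#' frame up to `max_lag_fraction` of the longest track; the default 0.25
#' reflects the degrading statistical reliability of time-averaged MSDs at
#' long lags. Tracks with gaps contribute only the frame pairs actually
#' observed.
#'
#' @param tracks A `probe_tracks` tibble (columns `particle_id`, `frame`,
#'   `x_um`, `y_um`, attribute `frame_interval_s`), or a plain data frame
#'   plus `frame_interval`.
#' @param max_lag_fraction Longest lag as a fraction of the longest track.
#' @param weighting `"track"` (unweighted across tracks) or `"pairs"`.
#' @param frame_interval Frame interval in s, if not carried by `tracks`.
#' @return An `msd_curve` tibble: `lag_s`, `msd_um2`, `n_pairs`, `n_tracks`.
#' @export
compute_msd <- function(tracks, max_lag_fraction = 0.25,
                        weighting = c("track", "pairs"),
                        frame_interval = NULL) {
  weighting <- match.arg(weighting)
  assert_scalar_number(max_lag_fraction, "max_lag_fraction")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop_param("`max_lag_fraction` must lie in (0, 1]")
  if (is.null(frame_interval))
    frame_interval <- attr(tracks, "frame_interval_s", exact = TRUE)
  if (is.null(frame_interval))
    stop_param("`frame_interval` missing: supply it or use probe_tracks input")
  assert_positive(frame_interval, "frame_interval")
  req <- c("particle_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(tracks)))
    stop_param("tracks need columns ", paste(req, collapse = ", "))

  by_id <- split(tracks[, c("frame", "x_um", "y_um")], tracks$particle_id)
  by_id <- Filter(function(tr) nrow(tr) >= 2L, by_id)
  if (length(by_id) == 0L)
    stop_param("no track with >= 2 frames")
  for (tr in by_id)
    if (any(diff(tr$frame) <= 0))
      stop_param("frames within a track must be strictly increasing")

  span <- max(vapply(by_id, function(tr) diff(range(tr$frame)), numeric(1L)))
  max_lag <- max(1L, floor(max_lag_fraction * span))
  lags <- seq_len(max_lag)

  sum_msd <- n_tracks <- n_pairs <- wsum <- numeric(max_lag)
  for (tr in by_id) {
    f <- tr$frame
    contiguous <- all(diff(f) == 1L)
    for (ell in lags) {
      if (contiguous) {
        n <- length(f)
        if (ell >= n) break
        dx <- tr$x_um[(1L + ell):n] - tr$x_um[1L:(n - ell)]
        dy <- tr$y_um[(1L + ell):n] - tr$y_um[1L:(n - ell)]
      } else {
        j <- match(f + ell, f)
        ok <- !is.na(j)
        if (!any(ok)) next
        dx <- tr$x_um[j[ok]] - tr$x_um[ok]
        dy <- tr$y_um[j[ok]] - tr$y_um[ok]
      }
      m <- length(dx)
      msd_tr <- mean(dx * dx + dy * dy)
      w <- if (weighting == "track") 1 else m
      sum_msd[ell] <- sum_msd[ell] + w * msd_tr
      wsum[ell] <- wsum[ell] + w
      n_pairs[ell] <- n_pairs[ell] + m
      n_tracks[ell] <- n_tracks[ell] + 1L
    }
  }
  keep <- wsum > 0
  out <- tibble::tibble(
    lag_s = lags[keep] * frame_interval,
    msd_um2 = sum_msd[keep] / wsum[keep],
    n_pairs = n_pairs[keep],
    n_tracks = n_tracks[keep]
  )
  structure(out, class = c("msd_curve", class(out)),
            frame_interval_s = frame_interval, weighting = weighting)
}

#' Power-law fit of an MSD curve
#'
#' Fits \eqn{\mathrm{MSD}(\tau) = 4 D \tau^{\alpha}} by least squares on
#' log MSD versus log lag: the slope is the diffusive exponent \eqn{\alpha}
#' and the intercept gives \eqn{\log 4D}. Purely viscous media give
#' \eqn{\alpha = 1}; an exponent outside [0.9, 1.1] triggers a
#' "non-diffusive" warning since the Stokes-Einstein conversion downstream
#' assumes simple diffusion. Non-positive MSD values are excluded with a
#' warning. With `include_offset = TRUE` a constant term `4 * offset2`
#' (static localization error) is added and the fit is refined by nonlinear
#' least squares.
#'
#' @param msd An `msd_curve` (lags s, MSD um^2).
#' @param fit_range Optional `c(min_lag, max_lag)` in seconds.
#' @param include_offset Add a constant localization-error term.
#' @return An `msd_fit` list: `D_m2_s`, `alpha`, `r2`, `n_points`,
#'   `fit_range`, and `offset_um2` when requested.
#' @export
fit_msd_powerlaw <- function(msd, fit_range = NULL, include_offset = FALSE) {
  lag <- msd$lag_s
  y <- msd$msd_um2
  if (!is.null(fit_range)) {
    keep <- lag >= fit_range[1L] & lag <= fit_range[2L]
    lag <- lag[keep]; y <- y[keep]
  }
  pos <- y > 0
  if (any(!pos)) {
    warning("excluding ", sum(!pos), " non-positive MSD point(s)", call. = FALSE)
    lag <- lag[pos]; y <- y[pos]
  }
  if (length(y) < 3L)
    stop_param("fit error: need >= 3 positive MSD points in range")

  fit <- lm(log(y) ~ log(lag))
  alpha <- unname(coef(fit)[2L])
  D_um2 <- exp(unname(coef(fit)[1L])) / 4      # um^2 / s^alpha
  offset_um2 <- NULL
  if (include_offset) {
    nl <- try(minpack.lm::nlsLM(
      y ~ 4 * d * lag^a + c0,
      start = list(d = D_um2, a = alpha, c0 = 0),
      lower = c(0, 0, 0), upper = c(Inf, 2, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      co <- coef(nl)
      D_um2 <- unname(co[["d"]]); alpha <- unname(co[["a"]])
      offset_um2 <- unname(co[["c0"]])
    }
  }
  if (alpha < 0.9 || alpha > 1.1)
    warning(sprintf("non-diffusive exponent alpha = %.3f", alpha), call. = FALSE)
  structure(list(
    D_m2_s = D_um2 * 1e-12, alpha = alpha,
    r2 = suppressWarnings(summary(fit)$r.squared), n_points = length(y),
    fit_range = range(lag), offset_um2 = offset_um2
  ), class = "msd_fit")
}

#' Stokes-Einstein viscosity from a probe diffusion coefficient
#'
#' \eqn{\eta = k_B T / (6 \pi D r)} for a spherical probe of radius `r` in a
#' Newtonian medium at temperature `T`.
#'
#' @param D Probe diffusion coefficient, m^2/s (> 0).
#' @param probe_radius Probe radius, m (default 1 um).
#' @param temperature Absolute temperature, K (default 295.15).
#' @return Viscosity, Pa s.
#' @export
#' @examples
#' viscosity_stokes_einstein(7.084e-16)  # ~0.305 Pa s
viscosity_stokes_einstein <- function(D, probe_radius = 1e-6,
                                      temperature = 295.15) {
  assert_scalar_number(D, "D")
  if (D == 0) stop_param("division error: D must be > 0")
  if (D < 0) stop_param("`D` must be > 0")
  assert_positive(probe_radius, "probe_radius")
  assert_positive(temperature, "temperature")
  kB_J_per_K * temperature / (6 * pi * D * probe_radius)
}

#' Full microrheology pipeline: tracks to viscosity
#'
#' Convenience wrapper chaining [compute_msd()], [fit_msd_powerlaw()] and
#' [viscosity_stokes_einstein()] with the protocol defaults.
#'
#' @inheritParams compute_msd
#' @inheritParams fit_msd_powerlaw
#' @param probe_radius,temperature Passed to the Stokes-Einstein step;
#'   defaults are taken from the track attributes when present.
#' @return A `rheology_result` list: `D_probe_m2_s`, `alpha`, `eta_Pa_s`,
#'   `msd`, `fit`.
#' @export
microrheology <- function(tracks, max_lag_fraction = 0.25, fit_range = NULL,
                          include_offset = FALSE, probe_radius = NULL,
                          temperature = NULL) {
  if (is.null(probe_radius))
    probe_radius <- attr(tracks, "probe_radius_m", exact = TRUE) %||% 1e-6
  if (is.null(temperature))
    temperature <- attr(tracks, "temperature_K", exact = TRUE) %||% 295.15
  msd <- compute_msd(tracks, max_lag_fraction = max_lag_fraction)
  fit <- fit_msd_powerlaw(msd, fit_range = fit_range,
                          include_offset = include_offset)
  eta <- viscosity_stokes_einstein(fit$D_m2_s, probe_radius, temperature)
  structure(list(D_probe_m2_s = fit$D_m2_s, alpha = fit$alpha,
                 eta_Pa_s = eta, msd = msd, fit = fit,
                 probe_radius_m = probe_radius, temperature_K = temperature),
            class = "rheology_result")
}

#' @export
print.rheology_result <- function(x, ...) {
  cat(sprintf("<microrheology: D = %.4g m^2/s, alpha = %.3f, eta = %.4g Pa s>\n",
              x$D_probe_m2_s, x$alpha, x$eta_Pa_s))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
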