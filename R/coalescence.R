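# Droplet-coalescence shape relaxation and interfacial tension.

#' Aspect ratio of a relaxing droplet
#'
#' \eqn{A = (L - W)/(L + W)} from the length and width of a coalescing
#' droplet; 0 for a relaxed sphere, approaching 1 for extreme elongation.
#'
#' @param L,W Droplet length and width (same units); requires `L >= W > 0`.
#' @return Aspect ratio in \[0, 1). Vectorized.
#' @export
#' @examples
#' aspect_ratio(2, 1)  # 1/3
aspect_ratio <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)))
    stop_param("`L` and `W` must be finite")
  if (any(W <= 0)) stop_param("`W` must be > 0")
  if (any(L < W)) stop_param("need L >= W")
  (L - W) / (L + W)
}

#' Fit the exponential relaxation time of a coalescence event
#'
#' Nonlinear least squares of \eqn{A(t) = A_0 e^{-t/\tau}} to an
#' aspect-ratio time series, initialized from the log-linear fit (which is
#' already exact for noiseless data). A series that does not decay is a fit
#' error.
#'
#' @param series A `coalescence_series`, or a data frame with column `t_s`
#'   and either `A` or both `L_um` and `W_um`.
#' @return A `relaxation_fit` list: `tau_s`, `A0`, `rss`, `n_points`.
#' @seealso [interfacial_tension()]
#' @export
fit_relaxation_time <- function(series) {
  if (!is.data.frame(series) || !("t_s" %in% names(series)))
    stop_param("`series` needs a `t_s` column")
  A <- if ("A" %in% names(series)) series$A
       else if (all(c("L_um", "W_um") %in% names(series)))
         aspect_ratio(series$L_um, series$W_um)
       else stop_param("`series` needs `A` or `L_um`/`W_um` columns")
  t <- series$t_s
  if (length(t) < 4L) stop_param("need >= 4 time points")
  if (!is.finite(A[1L]) || A[1L] <= 0)
    stop_param("aspect ratio must be positive at the first time point")

  pos <- is.finite(A) & A > 0
  fit0 <- lm(log(A[pos]) ~ t[pos])
  slope <- unname(coef(fit0)[2L])
  # total log-decay over the observation window must be resolvable
  if (!is.finite(slope) || slope >= 0 ||
      abs(slope) * diff(range(t)) < 1e-8)
    stop_param("fit error: series does not decay")
  tau0 <- -1 / slope
  A00 <- exp(unname(coef(fit0)[1L]))

  nl <- try(minpack.lm::nlsLM(
    A ~ a0 * exp(-t / tau), data = data.frame(A = A, t = t),
    start = list(a0 = A00, tau = tau0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(nl, "try-error")) {
    tau <- tau0; a0 <- A00; rss <- sum((A - A00 * exp(-t / tau0))^2)
  } else {
    co <- coef(nl)
    tau <- unname(co[["tau"]]); a0 <- unname(co[["a0"]])
    rss <- sum(stats::residuals(nl)^2)
  }
  if (!is.finite(tau) || tau <= 0)
    stop_param("fit error: non-positive relaxation time")
  structure(list(tau_s = tau, A0 = a0, rss = rss, n_points = length(t)),
            class = "relaxation_fit")
}

#' Interfacial tension from a coalescence relaxation time
#'
#' Inverts the viscocapillary relation \eqn{\tau \cong (19/20)\, \eta R /
#' \sigma}: `sigma = (19/20) * eta * R / tau`, with the dense-phase viscosity
#' `eta` from microrheology and `R` the droplet radius after coalescence.
#'
#' @param tau Relaxation time, s (> 0).
#' @param eta Dense-phase viscosity, Pa s (> 0).
#' @param droplet_radius Post-coalescence droplet radius, m (> 0).
#' @return Interfacial tension, N/m.
#' @export
#' @examples
#' interfacial_tension(0.0644, 28.47, 10e-6)  # ~4.2e-3 N/m
interfacial_tension <- function(tau, eta, droplet_radius) {
  assert_scalar_number(tau, "tau")
  if (tau == 0) stop_param("division error: tau must be > 0")
  if (tau < 0) stop_param("`tau` must be > 0")
  assert_positive(eta, "eta")
  assert_positive(droplet_radius, "droplet_radius")
  (19 / 20) * eta * droplet_radius / tau
}
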