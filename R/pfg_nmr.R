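# Stejskal-Tanner echo attenuation and diffusion fitting.

#' Stejskal-Tanner echo attenuation
#'
#' \eqn{\psi = \exp(-(\gamma g \delta)^2 D (\Delta - \delta/3))}. Gradient
#' amplitudes are given in G/cm as acquired and converted to G/m internally
#' (x100) so that with \eqn{\gamma} in s^-1 G^-1 and `D` in m^2/s the
#' exponent is dimensionless.
#'
#' @param g Gradient amplitude(s), G/cm.
#' @param D Self-diffusion coefficient, m^2/s (>= 0).
#' @param delta Effective gradient-pulse duration, s.
#' @param Delta Total diffusion time, s; must exceed `delta/3`.
#' @param gamma Gyromagnetic ratio, s^-1 G^-1 (default: proton,
#'   2.6752e4).
#' @return Attenuation(s) in (0, 1].
#' @export
stejskal_tanner <- function(g, D, delta = 1e-3, Delta = 20e-3,
                            gamma = proton_gamma_sG) {
  assert_nonneg(D, "D")
  assert_positive(delta, "delta")
  assert_positive(gamma, "gamma")
  assert_scalar_number(Delta, "Delta")
  if (Delta <= delta / 3)
    stop_param("`Delta` must exceed `delta`/3")
  if (any(!is.finite(g)) || any(g < 0))
    stop_param("`g` must be finite and non-negative (G/cm)")
  exp(-st_b_values(g, delta, Delta, gamma) * D)
}

# b = (gamma * g * delta)^2 (Delta - delta/3), with g converted G/cm -> G/m
st_b_values <- function(g, delta, Delta, gamma) {
  (gamma * g * 100 * delta)^2 * (Delta - delta / 3)
}

#' Fit a single-exponential diffusion coefficient to an echo decay
#'
#' Transforms the gradient axis to \eqn{b = (\gamma g \delta)^2 (\Delta -
#' \delta/3)} and fits \eqn{\psi = e^{-bD}}. The log-linear solution (least
#' squares of \eqn{-\ln\psi} on \eqn{b} through the origin) initializes a
#' one-dimensional nonlinear refinement minimizing the residual sum of
#' squares in \eqn{\psi}-space (uniform weights; `weighting = "log"` keeps
#' the log-space solution instead). The fitted D is invariant under
#' reordering of the gradient list.
#'
#' @param decay An `echo_decay` (from [gen_echo_decay()] or
#'   [read_echo_decay()]), or a data frame with columns `g_Gcm`, `psi` plus
#'   `delta`, `Delta`, `gamma` arguments.
#' @param weighting `"psi"` (default) or `"log"`.
#' @param delta,Delta,gamma Pulse parameters if not carried as attributes.
#' @return A `diffusion_fit` list: `D_m2_s`, `D_init_m2_s`, `rss`,
#'   `n_points`, `weighting`.
#' @export
fit_diffusion <- function(decay, weighting = c("psi", "log"),
                          delta = NULL, Delta = NULL, gamma = NULL) {
  weighting <- match.arg(weighting)
  delta <- delta %||% attr(decay, "delta_s", exact = TRUE)
  Delta <- Delta %||% attr(decay, "Delta_s", exact = TRUE)
  gamma <- gamma %||% attr(decay, "gamma_sG", exact = TRUE) %||% proton_gamma_sG
  if (is.null(delta) || is.null(Delta))
    stop_param("pulse parameters `delta` and `Delta` are required")
  if (!all(c("g_Gcm", "psi") %in% names(decay)))
    stop_param("`decay` needs columns `g_Gcm` and `psi`")
  g <- decay$g_Gcm
  psi <- decay$psi
  if (length(psi) < 3L) stop_param("need >= 3 points")
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop_param("attenuations must be positive")

  if (length(unique(g)) > 2L && sd(psi) > 0 &&
      stats::cor(g, psi, method = "spearman") > -0.5)
    warning("echo attenuation is non-monotone in gradient beyond noise tolerance",
            call. = FALSE)

  b <- st_b_values(g, delta, Delta, gamma)
  sb2 <- sum(b^2)
  D0 <- if (sb2 > 0) sum(b * (-log(psi))) / sb2 else 0
  if (D0 < 0) {
    if (D0 < -1e-12 * max(abs(D0), 1)) stop_param("fit error: negative fitted D")
    D0 <- 0
  }
  D <- D0
  if (weighting == "psi" && D0 > 0) {
    sse <- function(d) sum((psi - exp(-b * d))^2)
    up <- 5 * D0
    opt <- optimize(sse, interval = c(0, up), tol = up * 1e-10)
    D <- opt$minimum
  }
  if (D < 0) stop_param("fit error: negative fitted D")
  structure(list(D_m2_s = D, D_init_m2_s = D0,
                 rss = sum((psi - exp(-b * D))^2),
                 n_points = length(psi), weighting = weighting),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion fit: D = %.4g m^2/s (%d points, rss %.3g)>\n",
              x$D_m2_s, x$n_points, x$rss))
  invisible(x)
}
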