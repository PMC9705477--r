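# Coarse-grained water counting over union-of-spheres hydration volumes
# (indirect umbrella sampling observable).

#' INDUS parameter set
#'
#' Validated container for the water-counting parameters: probe-sphere radius
#' `Rv` (0.55 nm keeps roughly the first hydration shell around a residue's
#' heavy atoms), Gaussian coarse-graining width `sigma` (0.01 nm), its
#' truncation length `rc` (0.02 nm) and the harmonic bias strength `kappa`
#' (10 kBT). Requires `rc > sigma > 0` and `Rv > rc`.
#'
#' @param Rv,sigma,rc Lengths in nm.
#' @param kappa Bias strength, kBT.
#' @return An `indus_params` list.
#' @export
indus_params <- function(Rv = 0.55, sigma = 0.01, rc = 0.02, kappa = 10) {
  assert_positive(Rv, "Rv"); assert_positive(sigma, "sigma")
  assert_positive(rc, "rc"); assert_positive(kappa, "kappa")
  if (rc <= sigma) stop_param("need rc > sigma")
  if (Rv <= rc) stop_param("need Rv > rc")
  structure(list(Rv = Rv, sigma = sigma, rc = rc, kappa = kappa),
            class = "indus_params")
}

#' Dynamic hydration volume of a tagged residue
#'
#' The hydration volume is the union of spheres of radius `Rv` pinned to the
#' centers of the residue's heavy atoms (carbon, oxygen, nitrogen, sulfur) in
#' the given frame; as the atoms move between frames the volume moves with
#' them.
#'
#' @param frame A `molecular_frame`.
#' @param residue_atom_indices Indices into the frame's heavy atoms defining
#'   the residue; must be non-empty and valid.
#' @param Rv Sphere radius, nm (default 0.55).
#' @return A `hydration_volume` list: `centers` (k x 3 matrix), `Rv`, and the
#'   frame's periodicity information.
#' @export
hydration_volume <- function(frame, residue_atom_indices, Rv = 0.55) {
  assert_positive(Rv, "Rv")
  check_frame(frame)
  idx <- residue_atom_indices
  n_atoms <- nrow(frame$heavy_atom_positions)
  if (length(idx) == 0L)
    stop_param("`residue_atom_indices` must be non-empty")
  if (any(idx != floor(idx)) || any(idx < 1L) || any(idx > n_atoms))
    stop_param("`residue_atom_indices` out of range")
  structure(list(centers = frame$heavy_atom_positions[idx, , drop = FALSE],
                 Rv = Rv, periodic = frame$periodic, box = frame$box),
            class = "hydration_volume")
}

check_frame <- function(frame) {
  if (!inherits(frame, "molecular_frame"))
    stop_param("`frame` must be a molecular_frame")
  invisible(frame)
}

# matrix of water-center distances (n_waters x n_centers), minimum-image if
# periodic
water_center_distances <- function(waters, centers, periodic, box) {
  nw <- nrow(waters); nc <- nrow(centers)
  d <- matrix(0, nw, nc)
  for (k in seq_len(nc)) {
    dd <- sweep(waters, 2L, centers[k, ])
    if (periodic)
      dd <- dd - sweep(round(sweep(dd, 2L, box, `/`)), 2L, box, `*`)
    d[, k] <- sqrt(rowSums(dd^2))
  }
  d
}

#' Sharp (binary) water count in a hydration volume
#'
#' Number of water oxygens whose minimum distance to any sphere center is at
#' most `Rv`. This is the sigma -> 0 limit of the coarse-grained count and
#' serves as its oracle.
#'
#' @param frame A `molecular_frame`.
#' @param volume A `hydration_volume`.
#' @return Integer count.
#' @export
sharp_count <- function(frame, volume) {
  check_frame(frame)
  waters <- frame$water_oxygen_positions
  if (is.null(waters) || nrow(waters) == 0L) return(0L)
  d <- water_center_distances(waters, volume$centers, frame$periodic, frame$box)
  sum(apply(d, 1L, min) <= volume$Rv)
}

# Smoothed radial indicator: integral of the truncated, normalized Gaussian
# kernel (width sigma, truncated at rc, shifted to vanish at the cut) from
# -rc to t. Exactly 0 for t <= -rc and exactly 1 for t >= rc.
smooth_indicator <- function(t, sigma, rc) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  ec <- exp(-rc^2 / (2 * sigma^2))
  k <- 1 / (sqrt(2 * pi) * sigma * erf(rc / (sqrt(2) * sigma)) - 2 * rc * ec)
  tc <- pmin(pmax(t, -rc), rc)
  h <- k * (sqrt(pi / 2) * sigma *
              (erf(tc / (sqrt(2) * sigma)) + erf(rc / (sqrt(2) * sigma))) -
            (tc + rc) * ec)
  h[t <= -rc] <- 0
  h[t >= rc] <- 1
  pmin(pmax(h, 0), 1)
}

#' Coarse-grained water count (INDUS observable)
#'
#' The smoothly varying water number \eqn{N_v} used for biasing: each water's
#' contribution to each sphere is the sharp radial indicator convolved with a
#' truncated, normalized Gaussian of width `sigma` (truncation `rc`), and
#' contributions from the spheres of the union combine by the
#' complement-product rule \eqn{\tilde h = 1 - \prod_j (1 - \tilde h_j)},
#' which reduces to the single-sphere indicator for one or coincident
#' spheres. A water farther than `Rv + rc` from every center contributes
#' exactly 0, and one deeper than `Rv - rc` inside a sphere contributes
#' exactly 1, so the coarse count equals the sharp count whenever no water
#' lies within `rc` of a sphere surface, and converges to it as
#' `sigma, rc -> 0`.
#'
#' @param frame A `molecular_frame`.
#' @param volume A `hydration_volume`.
#' @param sigma Gaussian width, nm (default 0.01).
#' @param rc Truncation length, nm (default 0.02); requires `rc > sigma`.
#' @return Real-valued count in \[0, n_waters\].
#' @export
coarse_count <- function(frame, volume, sigma = 0.01, rc = 0.02) {
  check_frame(frame)
  assert_positive(sigma, "sigma"); assert_positive(rc, "rc")
  if (rc <= sigma) stop_param("need rc > sigma")
  waters <- frame$water_oxygen_positions
  if (is.null(waters) || nrow(waters) == 0L) return(0)
  d <- water_center_distances(waters, volume$centers, frame$periodic, frame$box)
  h <- smooth_indicator(volume$Rv - d, sigma, rc)
  dim(h) <- dim(d)
  comp <- apply(1 - h, 1L, prod)
  sum(1 - comp)
}

#' Monte-Carlo volume of a union of spheres
#'
#' Hit-or-miss estimate of the union-of-spheres volume over its bounding box;
#' the standard error of the estimate is attached as an attribute.
#'
#' @param volume A `hydration_volume`.
#' @param n_samples Number of Monte-Carlo points (default 1e5).
#' @param seed Integer seed.
#' @return Volume in nm^3, with attribute `se`.
#' @export
union_volume <- function(volume, n_samples = 1e5, seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples")
  ctr <- volume$centers
  Rv <- volume$Rv
  lo <- apply(ctr, 2L, min) - Rv
  hi <- apply(ctr, 2L, max) + Rv
  vol_box <- prod(hi - lo)
  inside <- with_seed(seed, {
    pts <- matrix(runif(3L * n_samples), ncol = 3L)
    pts <- sweep(sweep(pts, 2L, hi - lo, `*`), 2L, lo, `+`)
    hit <- rep(FALSE, n_samples)
    for (k in seq_len(nrow(ctr)))
      hit <- hit | rowSums(sweep(pts, 2L, ctr[k, ])^2) <= Rv^2
    mean(hit)
  })
  structure(inside * vol_box,
            se = vol_box * sqrt(inside * (1 - inside) / n_samples))
}

#' Exact biased sampling of a single umbrella window
#'
#' Draws one umbrella window at bias center `nstar` from a model free-energy
#' landscape, delegating to [gen_umbrella_windows()]. Negative bias centers
#' are legal (the harmonic center below zero pushes toward an empty volume)
#' even though sampled counts are non-negative.
#'
#' @param F_model Data frame with columns `N`, `betaF`.
#' @param params An [indus_params()] (supplies `kappa`).
#' @param nstar Bias center (may be negative).
#' @param n_samples Samples to draw.
#' @param seed Integer seed.
#' @return An `umbrella_window`.
#' @export
sample_model_biased <- function(F_model, params, nstar, n_samples, seed = 1L) {
  if (!inherits(params, "indus_params"))
    stop_param("`params` must come from indus_params()")
  gen_umbrella_windows(F_model, params$kappa, nstar, n_samples, seed)[[1L]]
}
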