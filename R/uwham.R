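# Binless UWHAM unbiasing of umbrella-sampled water numbers, and per-water
# dewetting free-energy summaries.

#' Binless UWHAM: unbiased free-energy profile from umbrella windows
#'
#' Solves the binless weighted-histogram (UWHAM/MBAR) self-consistent
#' equations for the per-window free energies \eqn{f_k} of a set of
#' harmonically biased windows, then assembles the unbiased probability
#' \eqn{P_v(N)} on the integer grid and reports
#' \eqn{\beta F(N) = -\ln P_v(N)}, shifted so its minimum is zero.
#'
#' The solver is a damped self-consistent iteration with the first window
#' pinned to \eqn{f_1 = 0}, converged when \eqn{\max_k |\Delta f_k|} falls
#' below `tol` (default 1e-8 kBT) or the iteration cap is reached (an error).
#' Duplicated sample values (exact integer sampling produces many) are
#' collapsed with multiplicities first — a lossless rewrite of the same
#' equations. Per-window equilibration discards
#' (`n_equilibration_discarded`, for Markov-chain inputs) are dropped before
#' pooling. Continuous sample values are assigned to integer bins by
#' nearest-integer rounding, half-integer ties rounding toward the window's
#' own bias center.
#'
#' Adjacent windows (by bias center) are checked for effective overlap of
#' their sampled distributions; pairs below `overlap_floor` (histogram
#' overlap coefficient, default 0.01) trigger a warning since the relative
#' free energies across such a junction are statistically unreliable. A
#' chain whose windows share no representable support at all is an error.
#'
#' @param windows A list of `umbrella_window` objects (fields `nstar`,
#'   `kappa`, `samples`, `n_equilibration_discarded`), e.g. from
#'   [gen_umbrella_windows()] or [read_umbrella_windows()]. A single window
#'   with `kappa = 0` reduces to the normalized histogram.
#' @param tol Convergence tolerance on `max |delta f|`, kBT.
#' @param max_iter Iteration cap (default 1e5).
#' @param damping Step fraction in (0, 1]; 1 is plain iteration.
#' @param overlap_floor Minimum adjacent-window overlap before warning.
#' @return A `free_energy_profile` list: `N` (integer grid), `betaF`
#'   (min-zero, kBT), `N0` (equilibrium water count, the profile argmin),
#'   `window_f` (converged per-window free energies), `iterations`,
#'   `residual`, `overlap` (adjacent-pair overlap coefficients).
#' @seealso [per_water_profile()]
#' @export
uwham_unbias <- function(windows, tol = 1e-8, max_iter = 1e5, damping = 1,
                         overlap_floor = 0.01) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  if (length(windows) == 0L) stop_param("need >= 1 window")
  ok <- vapply(windows, inherits, logical(1L), "umbrella_window")
  if (!all(ok)) stop_param("all elements must be umbrella_window objects")
  assert_positive(tol, "tol")
  max_iter <- assert_count(max_iter, "max_iter")
  if (damping <= 0 || damping > 1) stop_param("`damping` must be in (0, 1]")

  K <- length(windows)
  nstar <- vapply(windows, function(w) w$nstar, numeric(1L))
  kappa <- vapply(windows, function(w) w$kappa, numeric(1L))
  samp <- lapply(windows, function(w) {
    s <- w$samples
    disc <- w$n_equilibration_discarded %||% 0L
    if (disc > 0L) s <- s[-seq_len(disc)]
    if (length(s) == 0L) stop_param("window has no samples after equilibration discard")
    if (any(s < 0)) stop_param("water-number samples must be >= 0")
    s
  })
  Nk <- vapply(samp, length, numeric(1L))
  win_id <- rep(seq_len(K), times = Nk)
  x <- unlist(samp, use.names = FALSE)

  # collapse duplicated sample values (lossless)
  ux <- sort(unique(x))
  g_of_x <- match(x, ux)
  cnt <- tabulate(g_of_x, nbins = length(ux))
  G <- length(ux)

  # bias energies (kBT) of each unique value under each window
  U <- 0.5 * outer(kappa, rep(1, G)) * (outer(nstar, ux, `-`))^2
  E <- exp(-U)                       # K x G, entries in [0, 1]

  # connectivity of the window chain through representable weights
  if (K > 1L) {
    sampled <- matrix(FALSE, K, G)
    sampled[cbind(win_id, g_of_x)] <- TRUE
    covers <- E > 0 & matrix(colSums(sampled) > 0, K, G, byrow = TRUE)
    comp <- window_components(covers)
    if (max(comp) > 1L)
      stop_param("disconnected support: the window chain splits into ",
                 max(comp), " components with no shared representable weight")
  }

  # Deterministic warm start: the self-consistent equations are the
  # stationarity conditions of a convex objective, so a quasi-Newton descent
  # lands essentially at the fixed point before the damped self-consistent
  # iteration verifies and polishes it (the iteration alone contracts very
  # slowly when window overlap is poor).
  f <- numeric(K)
  if (K > 1L) {
    obj <- function(v) {
      fk <- c(0, v)
      denom <- as.vector((Nk * exp(fk)) %*% E)
      sum(cnt * log(denom)) - sum(Nk * fk)
    }
    grad <- function(v) {
      fk <- c(0, v)
      denom <- as.vector((Nk * exp(fk)) %*% E)
      gk <- (Nk * exp(fk)) * as.vector(E %*% (cnt / denom)) - Nk
      gk[-1L]
    }
    ws <- try(stats::optim(numeric(K - 1L), obj, grad, method = "L-BFGS-B",
                           control = list(maxit = 2000L, factr = 10)),
              silent = TRUE)
    if (!inherits(ws, "try-error") && all(is.finite(ws$par)))
      f <- c(0, ws$par)
    # Newton refinement of the stationarity system (convex, so the Hessian
    # is positive semidefinite); quadratic convergence takes the residual to
    # machine precision where the quasi-Newton stop tolerance cannot.
    # Everything is computed from the row-scaled weights
    # W[k, g] = Nk exp(f_k - U_kg), which stay bounded even when f_k is large.
    for (nt in 1:50) {
      W <- exp(sweep(-U, 1L, log(Nk) + f, `+`))
      denom <- colSums(W)
      if (any(!is.finite(denom)) || any(denom <= 0)) break
      Tm <- W * rep(cnt / denom, each = K)
      gk <- rowSums(Tm) - Nk
      V <- W * rep(1 / denom, each = K)
      H <- -Tm %*% t(V)
      diag(H) <- diag(H) + rowSums(Tm)
      step <- try(solve(H[-1L, -1L, drop = FALSE], -gk[-1L]), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      f <- f + c(0, step)
      if (max(abs(gk[-1L]) / Nk[-1L]) < 1e-13) break
    }
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.vector((Nk * exp(f)) %*% E)       # length G
    if (any(!is.finite(denom)) || any(denom <= 0))
      stop_param("numerical failure in UWHAM iteration")
    fhat <- -log(as.vector(E %*% (cnt / denom)))
    fhat <- fhat - fhat[1L]
    delta <- max(abs(fhat - f))
    f <- f + damping * (fhat - f)
    if (delta < tol || iter >= max_iter) break
  }
  if (delta >= tol)
    stop_param("UWHAM did not converge within ", max_iter,
               " iterations (residual ", signif(delta, 3), " kBT)")

  # unbiased weight of every unique sample value
  denom <- as.vector((Nk * exp(f)) %*% E)
  w_u <- cnt / denom
  w_u <- w_u / sum(w_u)

  # integer binning; half-integer ties round toward the window's bias center
  bins <- round_half_to_nstar(x, nstar[win_id])
  binned_w <- (w_u / cnt)[g_of_x]      # per-sample weight
  N_grid <- seq(min(bins), max(bins))
  P <- vapply(N_grid, function(n) sum(binned_w[bins == n]), numeric(1L))
  P <- P / sum(P)
  betaF <- -log(P)
  betaF <- betaF - min(betaF)

  ov <- adjacent_overlap(samp, nstar)
  if (K > 1L && any(ov < overlap_floor))
    warning(sum(ov < overlap_floor), " adjacent window pair(s) with overlap < ",
            overlap_floor, "; relative free energies across those junctions ",
            "are statistically unreliable", call. = FALSE)

  structure(list(N = N_grid, betaF = betaF,
                 N0 = N_grid[which.min(betaF)],
                 window_f = f, nstar = nstar,
                 iterations = iter, residual = delta, overlap = ov),
            class = "free_energy_profile")
}

# connected components of the window graph (edges where two windows both
# have positive weight on some sampled value)
window_components <- function(covers) {
  K <- nrow(covers)
  adj <- covers %*% t(covers) > 0
  comp <- integer(K)
  cid <- 0L
  for (s in seq_len(K)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

round_half_to_nstar <- function(x, nstar) {
  lo <- floor(x)
  frac <- x - lo
  up <- frac > 0.5 | (frac == 0.5 & nstar >= lo + 0.5)
  lo + as.numeric(up)
}

adjacent_overlap <- function(samp, nstar) {
  K <- length(samp)
  if (K < 2L) return(numeric(0))
  ord <- order(nstar)
  vapply(seq_len(K - 1L), function(i) {
    a <- samp[[ord[i]]]; b <- samp[[ord[i + 1L]]]
    lo <- floor(min(a, b)); hi <- ceiling(max(a, b))
    br <- seq(lo - 0.5, hi + 0.5)
    ha <- tabulate(findInterval(a, br), nbins = length(br) - 1L) / length(a)
    hb <- tabulate(findInterval(b, br), nbins = length(br) - 1L) / length(b)
    sum(pmin(ha, hb))
  }, numeric(1L))
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free-energy profile: N in [%d, %d], N0 = %d, %d windows, %d iterations>\n",
              min(x$N), max(x$N), x$N0, length(x$window_f), x$iterations))
  invisible(x)
}

#' Per-water dewetting free energy
#'
#' Normalizes a dewetting free-energy profile to the average cost of
#' expelling one water: for each depletion level \eqn{N < N_0},
#' \deqn{y(N) = \frac{\beta F(N) - \beta F(N_0)}{N_0 - N},}
#' plotted against the fractional occupancy \eqn{x = N / N_0}, where
#' \eqn{N_0} is the equilibrium water count (the profile minimum). A more
#' hydrophobic surface costs less dewetting free energy per water molecule.
#'
#' @param profile A `free_energy_profile` whose minimum is interior to the
#'   grid.
#' @return A tibble with columns `N`, `occupancy` (N/N0) and
#'   `per_water_kBT`.
#' @seealso [compare_hydrophobicity()]
#' @export
per_water_profile <- function(profile) {
  if (!inherits(profile, "free_energy_profile"))
    stop_param("`profile` must be a free_energy_profile")
  N0 <- profile$N0
  if (N0 <= 0) stop_param("N0 must be > 0")
  if (N0 == min(profile$N) || N0 == max(profile$N))
    stop_param("profile has no interior minimum")
  keep <- profile$N < N0
  N <- profile$N[keep]
  F0 <- profile$betaF[profile$N == N0]
  tibble::tibble(
    N = N,
    occupancy = N / N0,
    per_water_kBT = (profile$betaF[keep] - F0) / (N0 - N)
  )
}

#' Average several dewetting profiles on their common grid
#'
#' Residue-level hydrophobicity is context dependent, so dewetting profiles
#' are computed per tagged residue; this helper averages profiles (in kBT,
#' re-shifted to min zero) over the N values common to all of them, e.g.
#' across probed positions along a chain. Averaging can equivalently be
#' applied after per-water normalization; both reducers are available.
#'
#' @param profiles List of `free_energy_profile`s.
#' @return A `free_energy_profile` on the common integer grid.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop_param("empty profile list")
  grids <- lapply(profiles, `[[`, "N")
  common <- Reduce(intersect, grids)
  if (length(common) < 3L) stop_param("profiles share too little support")
  common <- sort(common)
  bf <- rowMeans(vapply(profiles, function(p) p$betaF[match(common, p$N)],
                        numeric(length(common))))
  bf <- bf - min(bf)
  structure(list(N = common, betaF = bf, N0 = common[which.min(bf)],
                 window_f = NULL, nstar = NULL, iterations = 0L,
                 residual = 0, overlap = numeric(0)),
            class = "free_energy_profile")
}

#' Compare two dewetting profiles by per-water cost
#'
#' Ranks two free-energy profiles by their mean per-water dewetting cost over
#' the overlapping occupancy range; the lower-cost profile is classified as
#' the more hydrophobic surface.
#'
#' @param a,b `free_energy_profile`s.
#' @return A list: `more_hydrophobic` (`"a"` or `"b"`), `mean_a`, `mean_b`
#'   (kBT per water).
#' @export
compare_hydrophobicity <- function(a, b) {
  pa <- per_water_profile(a)
  pb <- per_water_profile(b)
  lo <- max(min(pa$occupancy), min(pb$occupancy))
  hi <- min(max(pa$occupancy), max(pb$occupancy))
  if (hi <= lo) stop_param("profiles share no occupancy range")
  ka <- pa$occupancy >= lo & pa$occupancy <= hi
  kb <- pb$occupancy >= lo & pb$occupancy <= hi
  ma <- mean(pa$per_water_kBT[ka])
  mb <- mean(pb$per_water_kBT[kb])
  list(more_hydrophobic = if (ma <= mb) "a" else "b",
       mean_a = ma, mean_b = mb)
}

#' Tabulated double-well model free-energy landscape
#'
#' A quartic double well on an integer water-number grid, used as ground
#' truth for validating the biased sampler and the UWHAM unbiasing:
#' \deqn{\beta F(N) = h \left[\left(\frac{N - c}{w}\right)^2 - 1\right]^2}
#' with wells (F = 0) at `wells[1]` and `wells[2]` and barrier height `h`
#' (kBT) midway between them.
#'
#' @param wells Two integers, the well positions (default c(10, 35)).
#' @param barrier Barrier height, kBT (default 4).
#' @param N_range Integer grid (default 0:60).
#' @return A tibble with columns `N`, `betaF` suitable as `F_model`.
#' @export
double_well_landscape <- function(wells = c(10, 35), barrier = 4,
                                  N_range = 0:60) {
  if (length(wells) != 2L || wells[1L] >= wells[2L])
    stop_param("`wells` must be two increasing positions")
  assert_positive(barrier, "barrier")
  ctr <- mean(wells)
  w <- diff(wells) / 2
  bF <- barrier * (((N_range - ctr) / w)^2 - 1)^2
  tibble::tibble(N = as.numeric(N_range), betaF = bF - min(bF))
}
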