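# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute-force enumeration or textbook binned algorithm) kept
# separate from the package's code paths.

# time-averaged MSD of one track by explicit enumeration of all frame pairs
brute_msd_track <- function(frame, x, y, lag) {
  num <- 0; n <- 0L
  for (i in seq_along(frame)) {
    j <- which(frame == frame[i] + lag)
    if (length(j) == 1L) {
      num <- num + (x[j] - x[i])^2 + (y[j] - y[i])^2
      n <- n + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  num / n
}

brute_msd <- function(tracks, lags) {
  by_id <- split(tracks, tracks$particle_id)
  sapply(lags, function(ell) {
    v <- vapply(by_id, function(tr)
      brute_msd_track(tr$frame, tr$x_um, tr$y_um, ell), numeric(1L))
    mean(v, na.rm = TRUE)
  })
}

# textbook binned WHAM on unit-width integer bins: histogram each window,
# then maximize the WHAM log-likelihood in the window free energies
# (Newton iteration on the G x K binned arrays, written independently of the
# package's binless solver), and assemble
# P(N) = sum_k n_k(N) / sum_k N_k exp(f_k - u_k(N)).
binned_wham <- function(windows, tol = 1e-12, max_iter = 200) {
  samp <- lapply(windows, `[[`, "samples")
  nstar <- vapply(windows, `[[`, numeric(1), "nstar")
  kappa <- vapply(windows, `[[`, numeric(1), "kappa")
  K <- length(windows)
  bins <- lapply(samp, round)
  N_grid <- seq(min(unlist(bins)), max(unlist(bins)))
  cnt <- vapply(bins, function(b) tabulate(b - N_grid[1] + 1L,
                                           nbins = length(N_grid)),
                numeric(length(N_grid)))           # G x K
  ctot <- rowSums(cnt)
  Nk <- vapply(samp, length, numeric(1))
  U <- outer(N_grid, seq_len(K),
             function(n, k) 0.5 * kappa[k] * (n - nstar[k])^2)  # G x K
  obj <- function(fk) {
    W <- exp(sweep(-U, 2, log(Nk) + fk, `+`))
    v <- sum(ctot * log(rowSums(W))) - sum(Nk * fk)
    if (!is.finite(v)) Inf else v
  }
  score <- function(fk) {
    W <- exp(sweep(-U, 2, log(Nk) + fk, `+`))
    colSums(W * (ctot / rowSums(W))) - Nk
  }
  f <- numeric(K)
  it_total <- 0L
  for (round in 1:8) {
    # self-consistent sweeps to get into the basin
    for (it in 1:2000) {
      W <- exp(sweep(-U, 2, log(Nk) + f, `+`))
      P <- ctot / rowSums(W)
      P[ctot == 0] <- 0
      fnew <- -log(as.vector(t(exp(-U)) %*% P))
      fnew <- fnew - fnew[1]
      d <- max(abs(fnew - f))
      f <- fnew
      it_total <- it_total + 1L
      if (d < tol) break
    }
    # guarded Newton polish
    for (it in 1:50) {
      W <- exp(sweep(-U, 2, log(Nk) + f, `+`))
      denom <- rowSums(W)
      Tm <- W * (ctot / denom)
      gk <- colSums(Tm) - Nk
      if (max(abs(gk) / Nk) < tol) break
      V <- W / denom
      H <- -t(Tm) %*% V
      diag(H) <- diag(H) + colSums(Tm)
      ridge <- 0
      repeat {
        step <- try(solve(H[-1, -1, drop = FALSE] +
                            diag(ridge, K - 1), -gk[-1]), silent = TRUE)
        if (!inherits(step, "try-error") && all(is.finite(step))) break
        ridge <- max(ridge * 10, 1e-8 * max(abs(diag(H))))
      }
      if (max(abs(step)) > 30) step <- step * 30 / max(abs(step))
      cur <- obj(f)
      lam <- 1
      repeat {
        cand <- f + lam * c(0, step)
        if (obj(cand) <= cur + 1e-10) break
        lam <- lam / 2
        if (lam < 1e-10) { cand <- f; break }
      }
      f <- cand
      it_total <- it_total + 1L
    }
    if (max(abs(score(f)) / Nk) < tol) break
  }
  W <- exp(sweep(-U, 2, log(Nk) + f, `+`))
  P <- ctot / rowSums(W)
  P[ctot == 0] <- 0
  P <- P / sum(P)
  bF <- -log(P)
  list(N = N_grid, betaF = bF - min(bF), f = f, iterations = it_total)
}

# per-frame all-pairs contact enumeration
brute_contact_map <- function(ensemble, cutoff, min_sep) {
  n <- nrow(ensemble$frames[[1]])
  acc <- matrix(0, n, n)
  for (fr in ensemble$frames) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) < min_sep) next
      if (sqrt(sum((fr[i, ] - fr[j, ])^2)) <= cutoff)
        acc[i, j] <- acc[i, j] + 1
    }
  }
  acc / length(ensemble$frames)
}

# all-pairs hydrogen-bond check
brute_hbond <- function(m, donors, acceptors, d_cut, angle_cut) {
  cnt <- 0L
  for (r in seq_len(nrow(donors))) {
    D <- donors[r, 1]; H <- donors[r, 2]
    for (A in acceptors) {
      if (A %in% c(D, H)) next
      if (sqrt(sum((m[A, ] - m[D, ])^2)) > d_cut) next
      v1 <- m[D, ] - m[H, ]; v2 <- m[A, ] - m[H, ]
      ang <- acos(min(max(sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang >= 180 - angle_cut) cnt <- cnt + 1L
    }
  }
  cnt
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(frame, R, shift) {
  sweep(frame %*% t(R), 2, shift, `+`)
}
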