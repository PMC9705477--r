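# Single-chain conformational observables: radius of gyration, end-to-end
# distance, their distributions, contact maps and hydrogen-bond counts.

as_frame_matrix <- function(frame) {
  m <- as.matrix(frame)
  if (ncol(m) != 3L || any(!is.finite(m)))
    stop_param("a frame must be a finite n x 3 coordinate matrix (nm)")
  m
}

#' Radius of gyration of a frame
#'
#' Mass-weighted root-mean-square distance of the sites from their center of
#' mass.
#'
#' @param frame An n x 3 coordinate matrix, nm (n >= 2).
#' @param masses Site masses (> 0); default all equal.
#' @return Rg in nm.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.5
radius_of_gyration <- function(frame, masses = NULL) {
  m <- as_frame_matrix(frame)
  if (nrow(m) < 2L) stop_param("need >= 2 sites")
  if (is.null(masses)) masses <- rep(1, nrow(m))
  if (length(masses) != nrow(m) || any(!is.finite(masses)) || any(masses < 0))
    stop_param("`masses` must be non-negative, one per site")
  M <- sum(masses)
  if (M <= 0) stop_param("zero total mass")
  com <- colSums(m * masses) / M
  sqrt(sum(masses * rowSums(sweep(m, 2L, com)^2)) / M)
}

#' End-to-end distance of a frame
#'
#' Euclidean distance between the two terminal sites, with minimum-image
#' convention when a periodic box is given.
#'
#' @param frame An n x 3 coordinate matrix, nm.
#' @param terminal_indices Two distinct site indices; default first and last.
#' @param box Optional periodic box edge lengths (length 3).
#' @return dee in nm.
#' @export
end_to_end <- function(frame, terminal_indices = NULL, box = NULL) {
  m <- as_frame_matrix(frame)
  if (is.null(terminal_indices)) terminal_indices <- c(1L, nrow(m))
  ti <- terminal_indices
  if (length(ti) != 2L || ti[1L] == ti[2L])
    stop_param("`terminal_indices` must be two distinct indices")
  if (any(ti < 1L) || any(ti > nrow(m)))
    stop_param("`terminal_indices` out of range")
  d <- m[ti[2L], ] - m[ti[1L], ]
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

#' Distributions of Rg and dee over an ensemble
#'
#' Computes the per-frame radius of gyration and end-to-end distance of a
#' chain ensemble, their normalized histograms (Freedman-Diaconis bin widths
#' by default), and summary statistics. When a second ensemble is given, the
#' difference of means (second minus first) for both observables is reported
#' with a bootstrap percentile confidence interval.
#'
#' @param ensemble A `chain_ensemble` (>= `min_frames` frames).
#' @param other Optional second `chain_ensemble` to compare against.
#' @param min_frames Minimum frames required for histogramming (default 30).
#' @param breaks Histogram bin rule passed to [graphics::hist()]-style
#'   computation: `"fd"` (default) or a number of bins.
#' @param n_boot Bootstrap replicates for the difference CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A list: `rg`, `dee` (numeric vectors), `rg_hist`, `dee_hist`
#'   (tibbles with `mid`, `density`), `summary` (tibble of means, sds,
#'   modes), and `difference` (tibble, only with `other`).
#' @export
ensemble_distributions <- function(ensemble, other = NULL, min_frames = 30L,
                                   breaks = "fd", n_boot = 1000L,
                                   conf = 0.95, seed = 1L) {
  obs <- ensemble_observables(ensemble, min_frames)
  out <- list(
    rg = obs$rg, dee = obs$dee,
    rg_hist = norm_hist(obs$rg, breaks),
    dee_hist = norm_hist(obs$dee, breaks),
    summary = tibble::tibble(
      observable = c("rg", "dee"),
      mean = c(mean(obs$rg), mean(obs$dee)),
      sd = c(sd(obs$rg), sd(obs$dee)),
      mode = c(hist_mode(obs$rg, breaks), hist_mode(obs$dee, breaks))
    )
  )
  if (!is.null(other)) {
    obs2 <- ensemble_observables(other, min_frames)
    out$difference <- with_seed(seed, {
      do.call(rbind, Map(function(nm, a, b) {
        d <- mean(b) - mean(a)
        boot <- vapply(seq_len(n_boot), function(i) {
          mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE))
        }, numeric(1L))
        ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
        tibble::tibble(observable = nm, diff_mean = d,
                       ci_lo = ci[1L], ci_hi = ci[2L])
      }, c("rg", "dee"), list(obs$rg, obs$dee), list(obs2$rg, obs2$dee)))
    })
  }
  out
}

ensemble_observables <- function(ensemble, min_frames) {
  if (!inherits(ensemble, "chain_ensemble"))
    stop_param("`ensemble` must be a chain_ensemble")
  if (length(ensemble$frames) < min_frames)
    stop_param("too few frames: need >= ", min_frames)
  rg <- vapply(ensemble$frames, radius_of_gyration, numeric(1L),
               masses = ensemble$masses)
  dee <- vapply(ensemble$frames, end_to_end, numeric(1L),
                terminal_indices = ensemble$termini)
  list(rg = rg, dee = dee)
}

norm_hist <- function(x, breaks) {
  if (length(unique(x)) == 1L) {
    return(tibble::tibble(mid = x[1L], density = Inf, point_mass = TRUE))
  }
  br <- hist_breaks(x, breaks)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  tibble::tibble(mid = h$mids, density = h$density, point_mass = FALSE)
}

hist_breaks <- function(x, breaks) {
  if (is.numeric(breaks)) return(breaks)
  nb <- max(1L, nclass.FD(x))
  seq(min(x), max(x), length.out = nb + 1L)
}

hist_mode <- function(x, breaks) {
  if (length(unique(x)) == 1L) return(x[1L])
  h <- graphics::hist(x, breaks = hist_breaks(x, breaks), plot = FALSE)
  h$mids[which.max(h$density)]
}

#' Intramolecular contact-frequency map
#'
#' Entry (i, j) is the fraction of frames in which sites i and j lie within
#' `cutoff`; pairs closer in sequence than `min_sequence_separation` are
#' zeroed so that trivially bonded neighbors do not register as contacts
#' (arginine stacking at molar salt shows up as off-diagonal enrichment in
#' such maps).
#'
#' @param ensemble A `chain_ensemble`.
#' @param cutoff Contact distance, nm (default 0.6 between closest heavy
#'   atoms / beads).
#' @param min_sequence_separation Minimum |i - j| retained (default 3).
#' @return A symmetric n x n matrix of contact frequencies in \[0, 1\].
#' @export
contact_map <- function(ensemble, cutoff = 0.6, min_sequence_separation = 3L) {
  if (!inherits(ensemble, "chain_ensemble"))
    stop_param("`ensemble` must be a chain_ensemble")
  assert_positive(cutoff, "cutoff")
  min_sequence_separation <- assert_count(min_sequence_separation,
                                          "min_sequence_separation")
  n <- nrow(ensemble$frames[[1L]])
  acc <- matrix(0, n, n)
  for (fr in ensemble$frames) {
    d <- as.matrix(stats::dist(fr))
    acc <- acc + (d <= cutoff)
  }
  acc <- acc / length(ensemble$frames)
  band <- abs(row(acc) - col(acc)) < min_sequence_separation
  acc[band] <- 0
  dimnames(acc) <- NULL
  acc
}

#' Geometric hydrogen-bond count in a frame
#'
#' Counts donor-acceptor pairs satisfying the standard geometric criterion:
#' donor-acceptor distance at most `d_cut` and donor-hydrogen-acceptor
#' angle within `angle_cut` of linear.
#'
#' @param frame An n x 3 coordinate matrix, nm.
#' @param donors Two-column matrix (or data frame) of site indices, one row
#'   per donor: heavy atom D and its hydrogen H. A donor without a hydrogen
#'   index is an error.
#' @param acceptors Vector of acceptor site indices.
#' @param d_cut Donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cut Maximum deviation of the D-H-A angle from 180 degrees
#'   (default 30).
#' @return Integer count of hydrogen bonds.
#' @export
hbond_count <- function(frame, donors, acceptors, d_cut = 0.35,
                        angle_cut = 30) {
  m <- as_frame_matrix(frame)
  donors <- as.matrix(donors)
  if (length(acceptors) == 0L) return(0L)
  if (ncol(donors) != 2L || any(!is.finite(donors)))
    stop_param("`donors` must be a two-column (D, H) index matrix; a donor ",
               "without a hydrogen is an error")
  if (any(donors < 1L) || any(donors > nrow(m)) ||
      any(acceptors < 1L) || any(acceptors > nrow(m)))
    stop_param("donor/acceptor indices out of range")
  assert_positive(d_cut, "d_cut")
  assert_positive(angle_cut, "angle_cut")

  count <- 0L
  for (r in seq_len(nrow(donors))) {
    Di <- donors[r, 1L]; Hi <- donors[r, 2L]
    for (Ai in acceptors) {
      if (Ai == Di || Ai == Hi) next
      dDA <- sqrt(sum((m[Ai, ] - m[Di, ])^2))
      if (dDA > d_cut) next
      v1 <- m[Di, ] - m[Hi, ]
      v2 <- m[Ai, ] - m[Hi, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= 180 - angle_cut) count <- count + 1L
    }
  }
  count
}

#' Read a single-chain ensemble from PDB files
#'
#' Builds a `chain_ensemble` from one or more PDB files (one frame each),
#' taking the C-alpha trace by default as the per-residue sites. Coordinates
#' are converted from Angstrom to nm. Requires the suggested `bio3d`
#' package.
#'
#' @param paths Character vector of PDB paths.
#' @param selection Atom selection: `"calpha"` (default) or `"heavy"`.
#' @return A `chain_ensemble`.
#' @export
read_chain_pdb <- function(paths, selection = c("calpha", "heavy")) {
  selection <- match.arg(selection)
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop_param("reading PDB files requires the `bio3d` package")
  frames <- lapply(paths, function(p) {
    pdb <- bio3d::read.pdb(p, verbose = FALSE)
    sel <- if (selection == "calpha") bio3d::atom.select(pdb, "calpha")
           else bio3d::atom.select(pdb, "noh")
    matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE) / 10
  })
  n <- nrow(frames[[1L]])
  if (any(vapply(frames, nrow, integer(1L)) != n))
    stop_param("all frames must have the same site count")
  structure(list(frames = frames, masses = rep(1, n), termini = c(1L, n),
                 bond_length_nm = NA_real_, model = "pdb"),
            class = "chain_ensemble")
}
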