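# Phase-window detection, cloud points, amino-acid-analysis calibration and
# dense-phase composition by mass balance.

#' Detect phase-separation windows in a turbidity curve
#'
#' A sample is called phase-separated wherever its turbidity reaches at least
#' `threshold_fraction` of the curve maximum; the detector reports the maximal
#' control-axis intervals satisfying this, with boundaries located by linear
#' interpolation between grid points. Because the threshold is relative, the
#' result is invariant under positive rescaling of the turbidity axis. Two or
#' more windows flag reentrant phase behavior (e.g. dissolution with added
#' salt followed by reappearance at molar salt for arginine-rich systems).
#'
#' Replicate curves may be supplied as a list; by default their turbidities
#' are averaged on the common grid before detection (`per_replicate = FALSE`).
#'
#' @param curve A `turbidity_curve`, or a list of replicate curves on the
#'   same grid.
#' @param threshold_fraction Relative threshold in (0, 1); default 0.1.
#' @param per_replicate If `TRUE` and `curve` is a list, return one result
#'   per replicate instead of averaging.
#' @return A `phase_windows` object: tibble of `lo`, `hi` plus attributes
#'   `reentrant` (>= 2 windows) and `threshold_used` (absolute OD600). An
#'   all-zero curve yields zero windows, not an error.
#' @export
#' @examples
#' cv <- gen_turbidity_profile(list(c(0, 80), c(3000, 4000)), sharpness = 5,
#'                             grid = c(seq(0, 200, 5), seq(250, 4500, 25)))
#' detect_phase_windows(cv)
detect_phase_windows <- function(curve, threshold_fraction = 0.1,
                                 per_replicate = FALSE) {
  if (is.list(curve) && !is.data.frame(curve)) {
    if (per_replicate)
      return(lapply(curve, detect_phase_windows,
                    threshold_fraction = threshold_fraction))
    curve <- average_replicates(curve)
  }
  check_threshold(threshold_fraction)
  x <- curve$control
  od <- curve$od600
  top <- max(od)
  if (top <= 0) return(new_phase_windows(numeric(0), numeric(0), 0))

  thr <- threshold_fraction * top
  above <- od >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lo <- hi <- numeric(0)
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    lo_k <- if (i == 1L) x[1L] else
      x[i - 1L] + (thr - od[i - 1L]) * (x[i] - x[i - 1L]) / (od[i] - od[i - 1L])
    hi_k <- if (j == length(x)) x[length(x)] else
      x[j] + (thr - od[j]) * (x[j + 1L] - x[j]) / (od[j + 1L] - od[j])
    lo <- c(lo, lo_k); hi <- c(hi, hi_k)
  }
  new_phase_windows(lo, hi, thr)
}

new_phase_windows <- function(lo, hi, threshold_used) {
  out <- tibble::tibble(lo = lo, hi = hi)
  structure(out, class = c("phase_windows", class(out)),
            reentrant = length(lo) >= 2L, threshold_used = threshold_used)
}

#' @export
print.phase_windows <- function(x, ...) {
  cat(sprintf("<phase windows: %d, reentrant: %s, threshold OD600 %.4g>\n",
              nrow(x), attr(x, "reentrant"), attr(x, "threshold_used")))
  NextMethod()
}

check_threshold <- function(threshold_fraction) {
  assert_scalar_number(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_param("`threshold_fraction` must lie strictly between 0 and 1")
}

average_replicates <- function(curves) {
  if (length(curves) == 0L) stop_param("empty replicate list")
  ctrl <- curves[[1L]]$control
  for (cv in curves[-1L])
    if (!isTRUE(all.equal(cv$control, ctrl)))
      stop_param("replicates must share the same control grid")
  od <- rowMeans(vapply(curves, function(cv) cv$od600, numeric(length(ctrl))))
  turbidity_curve(ctrl, od, ramp = attr(curves[[1L]], "ramp", exact = TRUE))
}

#' Normalize turbidity curves to relative units
#'
#' Divides each curve by its own maximum (`"per_curve"`, the default) or all
#' curves by the global maximum of the set (`"global"`).
#'
#' @param curves A `turbidity_curve` or list of them.
#' @param mode `"per_curve"` or `"global"`.
#' @return The same structure with od600 rescaled.
#' @export
relative_turbidity <- function(curves, mode = c("per_curve", "global")) {
  mode <- match.arg(mode)
  single <- is.data.frame(curves)
  lst <- if (single) list(curves) else curves
  tops <- vapply(lst, function(cv) max(cv$od600), numeric(1L))
  div <- if (mode == "global") rep(max(tops), length(lst)) else tops
  out <- Map(function(cv, d) {
    if (d > 0) cv$od600 <- cv$od600 / d
    cv
  }, lst, div)
  if (single) out[[1L]] else out
}

#' Detect cloud points and thermal hysteresis from heating/cooling scans
#'
#' Finds every temperature at which the turbidity crosses
#' `threshold_fraction` of the joint curve maximum, classifying each crossing
#' along the temporal direction of its ramp: turbidity rising through the
#' threshold is an `appear` transition (condensation), falling is `dissolve`.
#' A UCST transition therefore shows as `dissolve` on heating / `appear` on
#' cooling, an LCST as the reverse; a low-salt arginine-rich coacervate can
#' show both pairs in one scan. Crossing temperatures are linearly
#' interpolated between grid points. When both ramps report the same number
#' of crossings they are paired in temperature order and the per-pair
#' hysteresis is the heating-minus-cooling crossing temperature.
#'
#' @param heating A `turbidity_curve` with ramp `"heating"`.
#' @param cooling A `turbidity_curve` with ramp `"cooling"`, same range.
#' @param threshold_fraction Relative threshold in (0, 1); default 0.1.
#' @return A `cloud_points` object: list with `transitions` (tibble of
#'   `temperature`, `direction`, `ramp`) and `hysteresis` (numeric vector,
#'   empty when the ramps report unequal crossing counts).
#' @export
detect_cloud_points <- function(heating, cooling, threshold_fraction = 0.1) {
  check_threshold(threshold_fraction)
  for (nm in c("heating", "cooling")) {
    cv <- get(nm)
    rl <- attr(cv, "ramp", exact = TRUE)
    if (is.null(rl) || !identical(rl, nm))
      stop_param("`", nm, "` must be a turbidity_curve labelled ramp = \"", nm, "\"")
  }
  rng_h <- range(heating$control); rng_c <- range(cooling$control)
  if (!isTRUE(all.equal(rng_h, rng_c, tolerance = 1e-8)))
    stop_param("heating and cooling curves must span the same range")

  top <- max(c(heating$od600, cooling$od600))
  if (top <= 0)
    return(structure(list(transitions = tibble::tibble(
      temperature = numeric(0), direction = character(0), ramp = character(0)),
      hysteresis = numeric(0), threshold_used = 0), class = "cloud_points"))
  thr <- threshold_fraction * top

  tr_h <- ramp_crossings(heating, thr, time_forward = TRUE)
  tr_c <- ramp_crossings(cooling, thr, time_forward = FALSE)
  transitions <- rbind(tr_h, tr_c)

  hys <- numeric(0)
  if (nrow(tr_h) == nrow(tr_c) && nrow(tr_h) > 0L) {
    th <- sort(tr_h$temperature); tc <- sort(tr_c$temperature)
    hys <- th - tc
  }
  structure(list(transitions = tibble::as_tibble(transitions),
                 hysteresis = hys, threshold_used = thr),
            class = "cloud_points")
}

# threshold crossings of one ramp, traversed in temporal order
ramp_crossings <- function(curve, thr, time_forward) {
  x <- curve$control; od <- curve$od600
  if (!time_forward) { x <- rev(x); od <- rev(od) }
  above <- od >= thr
  idx <- which(above[-1L] != above[-length(above)])
  if (length(idx) == 0L)
    return(data.frame(temperature = numeric(0), direction = character(0),
                      ramp = character(0)))
  temps <- x[idx] + (thr - od[idx]) * (x[idx + 1L] - x[idx]) / (od[idx + 1L] - od[idx])
  dir <- ifelse(above[idx + 1L], "appear", "dissolve")
  data.frame(temperature = temps, direction = dir,
             ramp = attr(curve, "ramp", exact = TRUE))
}

#' @export
print.cloud_points <- function(x, ...) {
  cat(sprintf("<cloud points: %d transitions, threshold OD600 %.4g>\n",
              nrow(x$transitions), x$threshold_used))
  print(x$transitions)
  if (length(x$hysteresis))
    cat("hysteresis (heating - cooling):",
        paste(signif(x$hysteresis, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit an amino-acid-analysis calibration line
#'
#' Ordinary least squares of blank-corrected peak area on standard
#' concentration, the calibration step of quantitative amino acid analysis
#' (arginine peaks quantify protamine; glucosamine peaks quantify hyaluronic
#' acid). The protocol uses a four-point standard series; at least two
#' distinct concentrations are required for a non-singular fit.
#'
#' @param standards Data frame with columns `concentration` (mg/mL) and
#'   `peak_area`.
#' @param blank_mean Mean peak area of the hydrolyzed water blank,
#'   subtracted from every area before regression (default 0).
#' @param force_zero_intercept Fit through the origin instead of with a free
#'   intercept.
#' @param analyte Optional label (`"arginine_for_protamine"` or
#'   `"glucosamine_for_HA"`).
#' @return A `composition_calibration` list: `slope`, `intercept`, `r2`,
#'   `blank_mean`, `n_standards`, `analyte`.
#' @export
fit_calibration <- function(standards, blank_mean = 0,
                            force_zero_intercept = FALSE, analyte = NULL) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "peak_area") %in% names(standards)))
    stop_param("`standards` needs columns `concentration` and `peak_area`")
  assert_scalar_number(blank_mean, "blank_mean")
  conc <- standards$concentration
  if (length(unique(conc)) < 2L)
    stop_param("singular fit: need >= 2 distinct standard concentrations")
  adj <- standards$peak_area - blank_mean
  fit <- if (force_zero_intercept) lm(adj ~ conc + 0) else lm(adj ~ conc)
  co <- coef(fit)
  slope <- unname(co[["conc"]])
  intercept <- if (force_zero_intercept) 0 else unname(co[["(Intercept)"]])
  structure(list(slope = slope, intercept = intercept,
                 r2 = suppressWarnings(summary(fit)$r.squared), blank_mean = blank_mean,
                 n_standards = nrow(standards), analyte = analyte),
            class = "composition_calibration")
}

#' Convert a sample peak area to a concentration
#'
#' Inverts a calibration line: `(peak_area - blank_mean - intercept) / slope`.
#' Negative results (areas below the blank-adjusted intercept) are clipped to
#' zero with a warning.
#'
#' @param peak_area Peak area(s) of the sample.
#' @param cal A `composition_calibration` with positive slope.
#' @return Concentration(s), mg/mL.
#' @export
quantify_concentration <- function(peak_area, cal) {
  if (!inherits(cal, "composition_calibration"))
    stop_param("`cal` must come from fit_calibration()")
  if (!is.finite(cal$slope) || cal$slope <= 0)
    stop_param("calibration error: slope must be > 0")
  conc <- (peak_area - cal$blank_mean - cal$intercept) / cal$slope
  if (any(conc < 0)) {
    warning("negative concentration(s) clipped to 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Dense-phase concentration from mass balance
#'
#' When the dense phase is too concentrated (or too small) to assay directly,
#' its concentration follows from conservation of mass across the two phases:
#' `c_dense = (c_total * V_total - c_dilute * V_dilute) / V_dense`.
#'
#' @param c_total Overall concentration of the mixed sample, mg/mL.
#' @param c_dilute Measured dilute-phase concentration, mg/mL.
#' @param V_total,V_dilute,V_dense Phase volumes (any common unit);
#'   `V_dense + V_dilute` must not exceed `V_total` beyond `volume_tol`
#'   (relative).
#' @param volume_tol Relative tolerance on the volume balance (default 1e-6).
#' @param mass_tol Relative tolerance below zero before a negative result is
#'   treated as inconsistent data (default 1e-8); small negatives within it
#'   are clipped to 0.
#' @return Dense-phase concentration, mg/mL.
#' @export
dense_from_mass_balance <- function(c_total, c_dilute, V_total, V_dilute,
                                    V_dense, volume_tol = 1e-6,
                                    mass_tol = 1e-8) {
  assert_nonneg(c_total, "c_total"); assert_nonneg(c_dilute, "c_dilute")
  assert_positive(V_total, "V_total"); assert_nonneg(V_dilute, "V_dilute")
  assert_positive(V_dense, "V_dense")
  if (V_dense + V_dilute > V_total * (1 + volume_tol))
    stop_param("volumes inconsistent: V_dense + V_dilute exceeds V_total")
  c_dense <- (c_total * V_total - c_dilute * V_dilute) / V_dense
  if (c_dense < 0) {
    if (c_dense < -mass_tol * max(c_total, 1))
      stop_param("mass-balance inconsistency: negative dense-phase concentration")
    c_dense <- 0
  }
  c_dense
}

#' Ratio of two component concentrations
#'
#' The protamine:HA packing ratio of a coacervate phase, or any other
#' concentration ratio.
#'
#' @param c_a,c_b Concentrations (same units); `c_b` must be > 0.
#' @return `c_a / c_b`, dimensionless.
#' @export
#' @examples
#' composition_ratio(1227.8, 680.9)  # ~1.8 (high-salt dense phase)
#' composition_ratio(158.3, 165.2)   # ~1   (low-salt dense phase)
composition_ratio <- function(c_a, c_b) {
  if (any(!is.finite(c_a)) || any(!is.finite(c_b)) || any(c_a < 0))
    stop_param("concentrations must be finite and non-negative")
  if (any(c_b == 0)) stop_param("division error: `c_b` must be > 0")
  if (any(c_b < 0)) stop_param("`c_b` must be > 0")
  c_a / c_b
}
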