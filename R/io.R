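# Tabular readers/writers. Every schema encodes its units in the column
# names (x_um, t_s, g_Gcm, ...), carries scalar metadata as "# key: value"
# header lines, and round-trips exactly through write/read. All computation
# inside the package is SI except molecular coordinates (nm) and tracking
# lengths (um), matching how the source data are acquired.

schema_registry <- list(
  tracks = list(cols = c("particle_id", "frame", "x_um", "y_um"),
                meta = c("frame_interval_s", "probe_radius_m", "temperature_K")),
  echo = list(cols = c("g_Gcm", "psi"),
              meta = c("delta_s", "Delta_s", "gamma_sG")),
  coalescence = list(cols = c("t_s", "L_um", "W_um"),
                     meta = c("droplet_radius_m")),
  turbidity = list(cols = c("control", "od600"),
                   meta = c("ramp", "replicate_id")),
  umbrella = list(cols = c("sample"), meta = character(0)),
  msd = list(cols = c("lag_s", "msd_um2", "n_pairs", "n_tracks"),
             meta = c("frame_interval_s")),
  profile = list(cols = c("N", "betaF_kBT"), meta = character(0))
)

#' Table schemas understood by the readers and writers
#'
#' @return Named list of schemas; each has `cols` (required column names,
#'   units encoded in the names) and `meta` (header keys).
#' @export
io_schemas <- function() schema_registry

get_schema <- function(schema_id) {
  sc <- schema_registry[[schema_id]]
  if (is.null(sc))
    stop_param("unknown schema `", schema_id, "`; known: ",
               paste(names(schema_registry), collapse = ", "))
  sc
}

#' Write a typed table with metadata header
#'
#' Writes `# key: value` header lines followed by a CSV body. Locale
#' independent (decimal point, UTF-8); full double precision.
#'
#' @param x Data frame with at least the schema's columns.
#' @param path Output path.
#' @param schema_id One of `names(io_schemas())`.
#' @param meta Named list of scalar metadata.
#' @return `path`, invisibly.
#' @export
write_input_table <- function(x, path, schema_id, meta = list()) {
  sc <- get_schema(schema_id)
  missing <- setdiff(sc$cols, names(x))
  if (length(missing))
    stop_param("schema error: missing column(s) ", paste(missing, collapse = ", "))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s",
                       nm, format(meta[[nm]], digits = 17, scientific = NA)), con)
  write.csv(as.data.frame(x)[, sc$cols, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}

#' Read a typed table, validating columns and metadata
#'
#' Parses the `# key: value` header, checks the schema's required columns by
#' name (so a unit mismatch in a column name is a schema error), rejects
#' non-finite cells, and reports malformed rows with their line numbers.
#'
#' @param path File path.
#' @param schema_id One of `names(io_schemas())`.
#' @return A tibble with a `meta` attribute (named list, numeric where
#'   possible).
#' @export
read_input_table <- function(path, schema_id) {
  sc <- get_schema(schema_id)
  if (!file.exists(path)) stop_param("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- list()
  for (i in hdr) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1L]]
    if (length(m) == 3L) {
      val <- m[3L]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2L])]] <- if (!is.na(num)) num else val
    }
  }
  missing_meta <- setdiff(sc$meta, names(meta))
  if (length(missing_meta))
    stop_param("schema error in ", basename(path), ": missing header field(s) ",
               paste(missing_meta, collapse = ", "))
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  x <- read.csv(text = paste(lines[body_start:length(lines)], collapse = "\n"),
                stringsAsFactors = FALSE)
  missing <- setdiff(sc$cols, names(x))
  if (length(missing))
    stop_param("schema error in ", basename(path), ": missing column(s) ",
               paste(missing, collapse = ", "))
  x <- x[, sc$cols, drop = FALSE]
  num_cols <- vapply(x, is.numeric, logical(1L))
  bad <- !complete.cases(x) |
    rowSums(as.matrix(!is.finite(as.matrix(x[, num_cols, drop = FALSE])))) > 0
  if (any(bad)) {
    lineno <- body_start + which(bad)   # +1 for the CSV header line
    stop_param("malformed row(s) in ", basename(path), " at line(s) ",
               paste(head(lineno, 10L), collapse = ", "),
               ": non-finite or missing cells are rejected")
  }
  structure(tibble::as_tibble(x), meta = meta)
}

#' Write the ground-truth record of a synthetic dataset as a JSON sidecar
#'
#' @param x Object carrying a `ground_truth` attribute.
#' @param path Output path (conventionally `<data>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- get_ground_truth(x)
  if (is.null(gt)) stop_param("`x` carries no ground truth")
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

# --- object-level round-trip wrappers ------------------------------------

#' Write / read probe tracks
#' @param tracks A `probe_tracks`.
#' @param path CSV path.
#' @return The written path / a `probe_tracks` tibble.
#' @export
write_probe_tracks <- function(tracks, path) {
  write_input_table(tracks, path, "tracks", meta = list(
    frame_interval_s = attr(tracks, "frame_interval_s", exact = TRUE),
    probe_radius_m = attr(tracks, "probe_radius_m", exact = TRUE) %||% 1e-6,
    temperature_K = attr(tracks, "temperature_K", exact = TRUE) %||% 295.15
  ))
}

#' @rdname write_probe_tracks
#' @export
read_probe_tracks <- function(path) {
  x <- read_input_table(path, "tracks")
  meta <- attr(x, "meta", exact = TRUE)
  structure(x, class = c("probe_tracks", class(x)),
            frame_interval_s = meta$frame_interval_s,
            probe_radius_m = meta$probe_radius_m,
            temperature_K = meta$temperature_K)
}

#' Write / read an echo decay
#' @param decay An `echo_decay`.
#' @param path CSV path.
#' @return The written path / an `echo_decay` tibble.
#' @export
write_echo_decay <- function(decay, path) {
  write_input_table(decay, path, "echo", meta = list(
    delta_s = attr(decay, "delta_s", exact = TRUE),
    Delta_s = attr(decay, "Delta_s", exact = TRUE),
    gamma_sG = attr(decay, "gamma_sG", exact = TRUE)
  ))
}

#' @rdname write_echo_decay
#' @export
read_echo_decay <- function(path) {
  x <- read_input_table(path, "echo")
  meta <- attr(x, "meta", exact = TRUE)
  structure(x, class = c("echo_decay", class(x)),
            delta_s = meta$delta_s, Delta_s = meta$Delta_s,
            gamma_sG = meta$gamma_sG)
}

#' Write / read a coalescence series
#' @param series A `coalescence_series` (columns `t_s`, `L_um`, `W_um`).
#' @param path CSV path.
#' @return The written path / a `coalescence_series` tibble (with the
#'   aspect-ratio column `A` recomputed from L and W).
#' @export
write_coalescence_series <- function(series, path) {
  write_input_table(series, path, "coalescence", meta = list(
    droplet_radius_m = attr(series, "droplet_radius_m", exact = TRUE)
  ))
}

#' @rdname write_coalescence_series
#' @export
read_coalescence_series <- function(path) {
  x <- read_input_table(path, "coalescence")
  meta <- attr(x, "meta", exact = TRUE)
  x$A <- aspect_ratio(x$L_um, x$W_um)
  structure(x, class = c("coalescence_series", class(x)),
            droplet_radius_m = meta$droplet_radius_m)
}

#' Write / read a turbidity curve
#' @param curve A `turbidity_curve`.
#' @param path CSV path.
#' @return The written path / a `turbidity_curve`.
#' @export
write_turbidity_curve <- function(curve, path) {
  write_input_table(curve, path, "turbidity", meta = list(
    ramp = attr(curve, "ramp", exact = TRUE) %||% "none",
    replicate_id = attr(curve, "replicate_id", exact = TRUE) %||% NA
  ))
}

#' @rdname write_turbidity_curve
#' @export
read_turbidity_curve <- function(path) {
  x <- read_input_table(path, "turbidity")
  meta <- attr(x, "meta", exact = TRUE)
  turbidity_curve(x$control, x$od600, ramp = meta$ramp,
                  replicate_id = meta$replicate_id)
}

#' Write / read a set of umbrella windows
#'
#' Each window's samples go to `<stem>_w<k>.csv` and a JSON manifest
#' `<stem>.json` records, per window, the bias center, spring constant and
#' equilibration discard.
#'
#' @param windows List of `umbrella_window`s.
#' @param stem Path stem (no extension).
#' @return The manifest path / a list of `umbrella_window`s.
#' @export
write_umbrella_windows <- function(windows, stem) {
  manifest <- lapply(seq_along(windows), function(k) {
    w <- windows[[k]]
    f <- sprintf("%s_w%03d.csv", stem, k)
    write_input_table(data.frame(sample = w$samples), f, "umbrella")
    list(file = basename(f), nstar = w$nstar, kappa = w$kappa,
         n_equilibration_discarded = w$n_equilibration_discarded)
  })
  jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_windows <- function(stem) {
  manifest <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = FALSE)
  windows <- lapply(manifest, function(mf) {
    x <- read_input_table(file.path(dirname(stem), mf$file), "umbrella")
    structure(list(nstar = mf$nstar, kappa = mf$kappa,
                   samples = x$sample,
                   n_equilibration_discarded = mf$n_equilibration_discarded),
              class = "umbrella_window")
  })
  structure(windows, class = "umbrella_window_set")
}

#' Write / read a free-energy profile
#' @param profile A `free_energy_profile`.
#' @param path CSV path.
#' @return The written path / a `free_energy_profile`.
#' @export
write_free_energy_profile <- function(profile, path) {
  write_input_table(data.frame(N = profile$N, betaF_kBT = profile$betaF),
                    path, "profile")
}

#' @rdname write_free_energy_profile
#' @export
read_free_energy_profile <- function(path) {
  x <- read_input_table(path, "profile")
  bf <- x$betaF_kBT - min(x$betaF_kBT)
  structure(list(N = x$N, betaF = bf, N0 = x$N[which.min(bf)],
                 window_f = NULL, nstar = NULL, iterations = 0L,
                 residual = 0, overlap = numeric(0)),
            class = "free_energy_profile")
}
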