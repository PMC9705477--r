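# internal validation and RNG helpers

stop_param <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("`", name, "` must be a single finite number")
  invisible(x)
}

assert_positive <- function(x, name) {
  assert_scalar_number(x, name)
  if (x <= 0) stop_param("`", name, "` must be > 0")
  invisible(x)
}

assert_nonneg <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0) stop_param("`", name, "` must be >= 0")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != floor(x)) stop_param("`", name, "` must be an integer >= ", min)
  invisible(as.integer(x))
}

assert_seed <- function(seed) {
  assert_scalar_number(seed, "seed")
  if (seed != floor(seed)) stop_param("`seed` must be an integer")
  invisible(as.integer(seed))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. All generators route their randomness through this,
# which is what makes identical (params, seed) byte-identical.
with_seed <- function(seed, code) {
  seed <- assert_seed(seed)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

ground_truth <- function(...) {
  gt <- list(...)
  structure(gt, class = "ground_truth")
}

#' Retrieve the ground truth attached to a synthetic dataset
#'
#' Every synthetic generator in the package records the exact parameter set
#' (plus the seed) used to produce its output, so downstream estimators can be
#' validated against known truth.
#'
#' @param x An object produced by one of the `gen_*()` generators.
#' @return A named list of generating parameters, or `NULL` when `x` did not
#'   come from a generator.
#' @export
get_ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground truth>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
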