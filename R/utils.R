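# Internal helpers shared across modules.

#' Parse a clock time to seconds since midnight
#'
#' @param x character "HH:MM" (24 h).
#' @return seconds since midnight (numeric).
#' @keywords internal
#' @noRd
parse_clock <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl("^\\d{1,2}:\\d{2}$", x)) {
    abort(paste0("clock time must be 'HH:MM', got '", x, "'"))
  }
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (parts[1] > 23 || parts[2] > 59) {
    abort(paste0("invalid clock time '", x, "'"))
  }
  parts[1] * 3600 + parts[2] * 60
}

# Centred moving average with NA passthrough; width in samples (odd).
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  if (width %% 2 == 0) width <- width + 1L
  n <- length(x)
  if (n < width) abort("series shorter than smoothing window")
  k <- rep(1 / width, width)
  # filter() handles interior; pad edges with shrinking one-sided windows
  out <- stats::filter(x, k, sides = 2)
  out <- as.numeric(out)
  half <- (width - 1L) / 2L
  for (i in seq_len(half)) {
    out[i] <- mean(x[1:(i + half)])
    out[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  out
}

# Check a numeric vector forms a uniform grid (constant step within tol).
is_uniform_grid <- function(time, tol = 1e-6) {
  d <- diff(time)
  length(d) > 0 && all(abs(d - d[1]) < tol * max(abs(d[1]), 1))
}

# Deterministic child seed from a parent seed and an index (keeps results
# reproducible when one seed fans out into many independent streams).
child_seed <- function(seed, index) {
  # double arithmetic: exact for |seed| < 2^31 and avoids integer overflow
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483562) + 1L
}

# scalar numeric validation
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("'", name, "' must be a finite numeric scalar"))
  }
  if (x < lower || x > upper) {
    abort(paste0("'", name, "' must be in [", lower, ", ", upper, "], got ", x))
  }
  invisible(x)
}
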