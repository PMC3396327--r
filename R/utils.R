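# internal helpers: classed errors, seed handling, separable convolution

#' @keywords internal
"_PACKAGE"

# classed condition so callers can test for specific failure modes
stop_chord <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "chord_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 32-bit sub-seed derived from a master seed and a stream index
sub_seed <- function(master, k) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 1103 + as.numeric(k) * 7919 + 12345) %% 2147483629) + 1L
}

# Banded matrix M such that M %*% x is the 'same'-size, zero-padded
# cross-correlation of x with the (odd-length, centred) tap vector.
corr_band_matrix <- function(n, taps) {
  stopifnot(length(taps) %% 2 == 1)
  r <- (length(taps) - 1L) / 2L
  idx <- outer(seq_len(n), seq_len(n), function(i, j) j - i + r + 1L)
  M <- matrix(0, n, n)
  ok <- idx >= 1L & idx <= length(taps)
  M[ok] <- taps[idx[ok]]
  M
}

# separable 2-D filtering: rows with `mr`, columns with `mc` (band matrices)
sep_filter <- function(img, mr, mc) mr %*% img %*% t(mc)

gaussian_taps <- function(sigma, radius = ceiling(2.5 * sigma)) {
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

check_numeric_vector <- function(x, what = "input") {
  if (!is.numeric(x) || length(x) < 1 || !all(is.finite(x)))
    stop_chord("chord_domain_error", "%s must be a finite numeric vector", what)
  as.numeric(x)
}
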