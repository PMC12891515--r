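#' Derive a reproducible child seed from a master seed and identifiers
#'
#' Hashes the master seed together with an arbitrary set of identifier values
#' (subject, trial, ROI pair, frequency, ...) into a 32-bit integer seed.
#' Used to give every surrogate stream its own deterministic RNG state so
#' results do not depend on execution order.
#'
#' @param master integer master seed.
#' @param ... identifier values (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# 1/f^alpha Gaussian noise via spectral amplitude shaping of white noise.
# Exact exponent control at O(n log n); unit variance on output.
noise_one_over_f <- function(n, fs, exponent, n_series = 1L) {
  k <- seq_len(n) - 1L
  k2 <- pmin(k, n - k)             # two-sided frequency index
  fk <- k2 * fs / n
  amp <- ifelse(fk == 0, 0, fk^(-exponent / 2))
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * amp, inverse = TRUE)) / n
    out[, j] <- x / stats::sd(x)
  }
  out
}

# Narrowband Gaussian noise: white noise restricted to [f0 - bw/2, f0 + bw/2]
# by FFT masking (raised-cosine edges), unit variance.
noise_narrowband <- function(n, fs, f0, bw) {
  x <- stats::rnorm(n)
  y <- fft_band_filter(x, fs, f0, bw, analytic = FALSE)
  y / stats::sd(y)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(...) stop(..., call. = FALSE)
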