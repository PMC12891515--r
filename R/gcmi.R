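#' Zero-phase FFT band filter, optionally returning the analytic signal
#'
#' Multiplies the spectrum by a flat passband `[f0 - bw/2, f0 + bw/2]` with
#' raised-cosine roll-offs of width `bw/2` on each side. Exactly zero phase
#' shift by construction. With `analytic = TRUE` the negative frequencies are
#' zeroed and the positive ones doubled, returning the complex analytic
#' band-limited signal in the same pass.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate (Hz).
#' @param f0 centre frequency (Hz).
#' @param bw passband width (Hz).
#' @param analytic return the complex analytic signal instead of the real
#'   filtered signal.
#' @return filtered vector/matrix (complex if `analytic`).
#' @export
fft_band_filter <- function(x, fs, f0, bw, analytic = FALSE) {
  was_vec <- !is.matrix(x)
  if (was_vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  k <- seq_len(n) - 1L
  f_signed <- ifelse(k <= n / 2, k, k - n) * fs / n
  f <- abs(f_signed)
  lo <- f0 - bw / 2; hi <- f0 + bw / 2; tw <- bw / 2
  w <- numeric(n)
  w[f >= lo & f <= hi] <- 1
  ramp_lo <- f < lo & f > lo - tw
  w[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo]) / tw))
  ramp_hi <- f > hi & f < hi + tw
  w[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi) / tw))
  if (analytic) {
    w <- w * ifelse(f_signed > 0, 2, ifelse(f_signed == 0, 1, 0))
  }
  out <- apply(x, 2, function(col) stats::fft(stats::fft(col) * w, inverse = TRUE) / n)
  out <- matrix(out, nrow = n)
  if (!analytic) out <- Re(out)
  if (was_vec) out[, 1] else out
}

#' Copula normalization: map each column to Gaussian scores by rank
#'
#' Column-wise, ranks (ties broken by stable input order, first occurrence
#' lowest) are mapped through `qnorm(r / (n + 1))`. The output is invariant
#' to any strictly increasing transform of each input column, which is what
#' makes the downstream Gaussian MI a robust, distribution-free estimator.
#'
#' @param data numeric vector or samples x d matrix; at least 4 samples per
#'   column, no constant columns.
#' @return matrix of normal scores with the same dimensions.
#' @export
copula_normalize <- function(data) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  n <- nrow(data)
  if (n < 3) stop_invalid("copula_normalize requires at least 3 samples")
  if (any(!is.finite(data))) stop_invalid("non-finite values in input")
  const <- which(apply(data, 2, function(c) max(c) == min(c)))
  if (length(const))
    stop_invalid("degenerate (constant) column(s): ", paste(const, collapse = ", "))
  apply(data, 2, function(col)
    stats::qnorm(rank(col, ties.method = "first") / (n + 1)))
}

# Gaussian entropy (nats) of a covariance via Cholesky; errors on singularity.
.gauss_entropy <- function(C, n, bias_correct, block_name) {
  d <- ncol(C)
  ch <- tryCatch(chol(C), error = function(e)
    stop_invalid("rank-deficient covariance in block `", block_name,
                 "`: ", conditionMessage(e)))
  if (min(diag(ch)) < 1e-7 * max(diag(ch)))
    stop_invalid("rank-deficient covariance in block `", block_name,
                 "`: near-singular Cholesky factor")
  H <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  if (bias_correct) {
    psiterms <- digamma((n - seq_len(d)) / 2) / 2
    dterm <- log(2 / (n - 1)) / 2
    H <- H - d * dterm - sum(psiterms)
  }
  H
}

# Fast path: MI (bits) between the first dx and remaining columns of a
# joint normal-scores matrix.
.mi_from_scores <- function(z, dx, bias_correct = TRUE) {
  n <- nrow(z); d <- ncol(z)
  z <- sweep(z, 2, colMeans(z))
  C <- crossprod(z) / (n - 1)
  Hx <- .gauss_entropy(C[1:dx, 1:dx, drop = FALSE], n, bias_correct, "x")
  Hy <- .gauss_entropy(C[(dx + 1):d, (dx + 1):d, drop = FALSE], n, bias_correct, "y")
  Hxy <- .gauss_entropy(C, n, bias_correct, "xy")
  (Hx + Hy - Hxy) / log(2)
}

#' Gaussian mutual information between two score matrices
#'
#' Computes `I(X; Y) = Hx + Hy - Hxy` from Gaussian entropies of the sample
#' covariances, in bits. Inputs are normally the output of
#' [copula_normalize()], making this the Gaussian-copula MI (GCMI) estimator.
#' With `bias_correct = TRUE` the analytic small-sample bias of each Gaussian
#' entropy estimate (digamma series in the dimension and sample count) is
#' subtracted, so independent data yield values centred on zero.
#'
#' @param x samples x dx numeric matrix (or vector).
#' @param y samples x dy numeric matrix (or vector).
#' @param bias_correct subtract the parametric bias terms (default `TRUE`).
#' @return an object of class `mi_estimate` with fields `value` (bits),
#'   `bias_corrected`, `n_samples`, `dims`.
#' @examples
#' z <- copula_normalize(matrix(rnorm(2000), ncol = 2))
#' mi_gg(z[, 1], z[, 2])$value   # near 0 for independent columns
#' @export
mi_gg <- function(x, y, bias_correct = TRUE) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  if (nrow(x) != nrow(y)) stop_invalid("x and y must have the same sample count")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("non-finite values in input")
  n <- nrow(x); dx <- ncol(x); dy <- ncol(y)
  if (n <= dx + dy + 3)
    stop_invalid("need n > dx + dy + 3 samples (n = ", n, ", dims = ",
                 dx + dy, ")")
  value <- .mi_from_scores(cbind(x, y), dx, bias_correct)
  structure(list(value = value, bias_corrected = bias_correct,
                 n_samples = n, dims = c(dx = dx, dy = dy)),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("GCMI estimate: %.4f bits (n = %d, dims = %d + %d, %s)\n",
              x$value, x$n_samples, x$dims[["dx"]], x$dims[["dy"]],
              if (x$bias_corrected) "bias-corrected" else "raw"))
  invisible(x)
}

#' Per-trial PCA denoising of a parcel's voxel time series
#'
#' Keeps the top `k` principal components by explained variance, fitted on
#' the trial itself. If the data rank is below `k`, `k` is truncated with a
#' warning.
#'
#' @param parcel_data samples x voxels numeric matrix.
#' @param k number of components to retain (the usual choice is 3, which
#'   captures about 90% of parcel variance in source-localized data).
#' @return list with `scores` (samples x k), `variance_explained`
#'   (proportions for the retained components, non-increasing), and
#'   `k` (possibly truncated).
#' @export
pca_reduce <- function(parcel_data, k = 3L) {
  stopifnot(is.matrix(parcel_data))
  if (k > ncol(parcel_data))
    stop_invalid("k = ", k, " exceeds the number of voxels (", ncol(parcel_data), ")")
  p <- stats::prcomp(parcel_data, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  prop <- ev / sum(ev)
  rank <- sum(ev > ev[1] * 1e-12)
  if (rank < k) {
    warning("data rank ", rank, " < k = ", k, "; truncating")
    k <- rank
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_explained = prop[seq_len(k)], k = k)
}

#' Band-limited phase representation of multichannel data
#'
#' Applies the zero-phase FFT band filter at `f0 +/- bw/2`, takes the
#' analytic signal, and unit-normalizes each sample, yielding per-channel
#' (cos, sin) phase pairs. Samples within `edge_trim` seconds of either epoch
#' edge are flagged for exclusion (filter transients).
#'
#' @param data samples x k numeric matrix (e.g. PCA scores), or a vector.
#' @param fs sampling rate (Hz); must exceed `2 * (f0 + bw/2)`.
#' @param f0 centre frequency (Hz).
#' @param bw bandwidth (Hz), default 2.
#' @param edge_trim seconds to flag at each edge; default `1/bw`.
#' @param keep_amplitude if `TRUE`, pairs are the raw analytic (Re, Im)
#'   instead of unit-normalized phase (amplitude retained).
#' @return object of class `spectral_phase`: list with `freq`, `pairs`
#'   (samples x 2k matrix of interleaved cos/sin columns), `valid` (index
#'   range free of edge transients), `fs`.
#' @export
band_phase <- function(data, fs, f0, bw = 2, edge_trim = 1 / bw,
                       keep_amplitude = FALSE) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  if (fs <= 2 * (f0 + bw / 2))
    stop_invalid("fs must exceed 2 * (f0 + bw/2)")
  n <- nrow(data)
  min_n <- ceiling(3 * fs / f0)
  if (n < min_n)
    stop_invalid("epoch too short: need at least 3 cycles of ", f0,
                 " Hz = ", min_n, " samples, got ", n)
  a <- fft_band_filter(data, fs, f0, bw, analytic = TRUE)
  k <- ncol(data)
  pairs <- matrix(0, n, 2 * k)
  for (j in seq_len(k)) {
    re <- Re(a[, j]); im <- Im(a[, j])
    if (!keep_amplitude) {
      amp <- sqrt(re^2 + im^2)
      amp[amp == 0] <- 1
      re <- re / amp; im <- im / amp
    }
    pairs[, 2 * j - 1] <- re
    pairs[, 2 * j] <- im
  }
  trim <- min(floor(edge_trim * fs), floor((n - 8) / 2))
  structure(list(freq = f0, pairs = pairs,
                 valid = c(trim + 1L, n - trim), fs = fs),
            class = "spectral_phase")
}

#' Delay-resolved GCMI between two band-phase representations
#'
#' For each delay `d`, the second (e.g. motor) region's phase series is
#' shifted so that `x[t]` is paired with `y[t + d]`; the trailing overhang is
#' dropped (no wrap-around), and every delay uses the same effective sample
#' count (truncated to the largest delay). Copula normalization and Gaussian
#' MI are then applied to the stacked phase-pair matrices.
#'
#' @param x_phase,y_phase `spectral_phase` objects on the same sampling grid.
#' @param delays numeric vector of delays in seconds; each must be an integer
#'   number of samples at `fs`.
#' @param bias_correct passed to the MI estimator.
#' @return data frame with columns `delay_s` and `mi_bits`.
#' @export
delay_gcmi <- function(x_phase, y_phase, delays, bias_correct = TRUE) {
  stopifnot(inherits(x_phase, "spectral_phase"), inherits(y_phase, "spectral_phase"))
  fs <- x_phase$fs
  if (y_phase$fs != fs) stop_invalid("sampling rates differ")
  shifts <- delays * fs
  if (any(abs(shifts - round(shifts)) > 1e-6))
    stop_invalid("delays must be integer sample shifts at fs = ", fs, " Hz")
  shifts <- as.integer(round(shifts))
  lo <- max(x_phase$valid[1], y_phase$valid[1])
  hi <- min(x_phase$valid[2], y_phase$valid[2])
  n_eff <- hi - lo + 1L - max(shifts)
  if (n_eff < ncol(x_phase$pairs) + ncol(y_phase$pairs) + 4)
    stop_invalid("largest delay leaves too few samples (", n_eff, ")")
  xs <- x_phase$pairs[lo:(lo + n_eff - 1L), , drop = FALSE]
  zx <- copula_normalize(xs)
  mi <- vapply(shifts, function(d) {
    ys <- y_phase$pairs[(lo + d):(lo + d + n_eff - 1L), , drop = FALSE]
    zy <- copula_normalize(ys)
    .mi_from_scores(cbind(zx, zy), ncol(zx), bias_correct)
  }, numeric(1))
  data.frame(delay_s = delays, mi_bits = mi)
}

#' Shuffle a series in contiguous segments
#'
#' Splits the rows into non-overlapping contiguous segments of
#' `segment_length` seconds (a trailing remainder shorter than one segment is
#' dropped), and rearranges the segments by a uniformly random permutation.
#' The marginal sample multiset is preserved up to the dropped tail; only the
#' cross-segment temporal order is destroyed.
#'
#' @param data numeric vector or samples x d matrix.
#' @param segment_length segment length in seconds.
#' @param fs sampling rate (Hz).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return matrix of `n_segments * segment_samples` rows.
#' @export
segment_shuffle <- function(data, segment_length, fs, seed = NULL) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  seg <- floor(segment_length * fs)
  if (seg < 1) stop_invalid("segment shorter than one sample")
  n_seg <- floor(nrow(data) / seg)
  if (n_seg < 2)
    stop_invalid("epoch holds fewer than 2 segments of ", segment_length, " s")
  perm <- if (is.null(seed)) sample(n_seg) else local_seed(seed, sample(n_seg))
  idx <- as.vector(vapply(perm, function(p) ((p - 1L) * seg + 1L):(p * seg),
                          integer(seg)))
  data[idx, , drop = FALSE]
}

#' Standardize an observed coupling value against its surrogate distribution
#'
#' `z = (observed - mean(surrogates)) / sd(surrogates)` with the n-1 SD.
#' Under this sign convention stronger-than-chance coupling gives positive z.
#'
#' @param observed scalar observed GCMI value.
#' @param surrogate_values numeric vector of surrogate GCMI values (>= 2,
#'   nonzero spread).
#' @return z score (scalar).
#' @export
surrogate_z <- function(observed, surrogate_values) {
  if (length(surrogate_values) < 2)
    stop_invalid("need at least 2 surrogate values")
  s <- stats::sd(surrogate_values)
  if (s == 0) stop_invalid("surrogate distribution has zero spread")
  (observed - mean(surrogate_values)) / s
}
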