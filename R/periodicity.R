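#' Inter-syllable-nuclei intervals of a train
#'
#' @param train a `syllable_train`, or a numeric vector of ascending nuclei
#'   times in seconds.
#' @return numeric vector of first differences (seconds), all > 0.
#' @export
nuclei_intervals <- function(train) {
  times <- if (inherits(train, "syllable_train")) train$nuclei_times else train
  if (length(times) < 2)
    stop_invalid("at least 2 nuclei are required to form intervals")
  if (any(diff(times) <= 0))
    stop_invalid("nuclei times must be strictly increasing")
  diff(times)
}

#' Median absolute deviation of intervals
#'
#' `scale_constant * median(|x - median(x)|)`. The default constant 1.4826 is
#' the Gaussian consistency constant used by [stats::mad()]; set it to 1 for
#' the unscaled convention. Larger values mean less periodic timing.
#'
#' @param values non-empty numeric vector (typically inter-nuclei intervals).
#' @param scale_constant multiplicative constant; 1.4826 (default) or 1.
#' @return non-negative scalar, same units as `values`.
#' @export
interval_mad <- function(values, scale_constant = 1.4826) {
  if (length(values) == 0 || !is.numeric(values))
    stop_invalid("`values` must be a non-empty numeric vector")
  stats::mad(values, constant = scale_constant)
}

#' Build per-sentence periodicity records from syllable trains
#'
#' @param trains list of `syllable_train` objects.
#' @param scale_constant passed to [interval_mad()].
#' @return data frame with one row per sentence: `sentence_id`,
#'   `rate_condition`, `empirical_rate` (intervals per second over the train's
#'   span), `mad`, plus the stimulus covariates.
#' @export
periodicity_records <- function(trains, scale_constant = 1.4826) {
  do.call(rbind, lapply(trains, function(tr) {
    iv <- nuclei_intervals(tr)
    data.frame(sentence_id = tr$sentence_id,
               rate_condition = tr$rate_condition,
               empirical_rate = length(iv) / sum(iv),
               mad = interval_mad(iv, scale_constant),
               compression_factor = tr$compression_factor,
               n_syllables = tr$n_syllables,
               mean_word_frequency = tr$mean_word_frequency)
  }))
}

#' Decorrelate MAD from syllabic rate within rate groups
#'
#' Within each rate condition, the linear dependence of MAD on the empirical
#' per-sentence rate is removed by OLS, leaving `residual_mad` with zero mean
#' and zero rate correlation per group. Mode `"demean"` simply centres MAD
#' within each group (the fallback when no within-group rate variation is
#' meaningful).
#'
#' @param records data frame as returned by [periodicity_records()]; must
#'   contain `mad`, `rate_condition`, and (for mode `"ols_on_rate"`)
#'   `empirical_rate`.
#' @param mode `"ols_on_rate"` (default) or `"demean"`.
#' @return `records` with an added `residual_mad` column (seconds).
#' @export
residualize_mad <- function(records, mode = c("ols_on_rate", "demean")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), all(c("mad", "rate_condition") %in% names(records)))
  groups <- split(seq_len(nrow(records)), records$rate_condition)
  small <- names(groups)[vapply(groups, length, 0L) < 3]
  if (length(small))
    stop_invalid("rate group(s) with fewer than 3 sentences: ",
                 paste(small, collapse = ", "))
  records$residual_mad <- NA_real_
  for (idx in groups) {
    g <- records[idx, ]
    if (mode == "demean" || stats::var(g$empirical_rate) == 0) {
      res <- g$mad - mean(g$mad)
    } else {
      res <- stats::residuals(stats::lm(mad ~ empirical_rate, data = g))
    }
    records$residual_mad[idx] <- res
  }
  records
}

#' Detect syllable nuclei as intensity peaks of an amplitude envelope
#'
#' A simplified stand-in for voicedness-based nuclei detection scripts:
#' the envelope is smoothed with a moving average, local maxima are collected
#' greedily from the highest down subject to a refractory interval, and each
#' surviving peak must be flanked on both sides by dips at least `min_dip_db`
#' below it (edges of the signal count as dips).
#'
#' @param envelope non-negative numeric vector (amplitude envelope).
#' @param fs sampling rate of the envelope (Hz); must be > 0.
#' @param min_dip_db minimum flanking dip depth in dB (20*log10 amplitude
#'   ratio); default 2 dB.
#' @param min_peak_interval refractory interval between nuclei, seconds;
#'   default 0.04 s (supports rates up to ~20 Syl/s).
#' @param smooth moving-average smoothing window, seconds; default 0.03 s.
#' @return numeric vector of nucleus times in seconds (possibly empty).
#' @export
detect_nuclei <- function(envelope, fs, min_dip_db = 2,
                          min_peak_interval = 0.04, smooth = 0.03) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop_invalid("`fs` must be a single positive number")
  if (length(envelope) < fs * 0.1)
    stop_invalid("envelope must span at least 0.1 s")
  if (any(envelope < 0)) stop_invalid("envelope must be non-negative")
  w <- max(1L, round(smooth * fs))
  env <- as.numeric(stats::filter(envelope, rep(1 / w, w), sides = 2))
  ok <- which(!is.na(env))
  if (length(ok)) {            # hold first/last smoothed value at the edges
    env[seq_len(ok[1] - 1)] <- env[ok[1]]
    env[seq(ok[length(ok)] + 1, length.out = length(env) - ok[length(ok)])] <-
      env[ok[length(ok)]]
  } else env[] <- 0
  n <- length(env)
  is_max <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                     env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  min_gap <- round(min_peak_interval * fs)
  accepted <- integer(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  eps <- max(env) * 1e-6 + .Machine$double.eps
  keep <- vapply(seq_along(accepted), function(j) {
    i <- accepted[j]
    lo <- if (j == 1) 1L else accepted[j - 1]
    hi <- if (j == length(accepted)) n else accepted[j + 1]
    dip_l <- min(env[lo:i]); dip_r <- min(env[i:hi])
    20 * log10(env[i] / max(dip_l, eps)) >= min_dip_db &&
      20 * log10(env[i] / max(dip_r, eps)) >= min_dip_db
  }, TRUE)
  (accepted[keep] - 1) / fs
}

#' Render a synthetic amplitude envelope from a syllable train
#'
#' Places a Gaussian intensity bump at each nucleus time on a silent
#' background, optionally adding white noise at a given SNR. Used to exercise
#' [detect_nuclei()] against known ground truth.
#'
#' @param train a `syllable_train`.
#' @param fs envelope sampling rate (Hz).
#' @param bump_sd bump width (Gaussian SD, seconds).
#' @param snr_db signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param pad silence padding before the first and after the last nucleus (s).
#' @param seed RNG seed for the noise.
#' @return list with `envelope` (non-negative vector), `fs`, and `times`
#'   (the true nucleus times within the rendered envelope).
#' @export
render_envelope <- function(train, fs = 100, bump_sd = 0.02, snr_db = Inf,
                            pad = 0.25, seed = 1L) {
  times <- train$nuclei_times + pad
  dur <- max(times) + pad
  t <- seq(0, dur, by = 1 / fs)
  env <- rowSums(vapply(times, function(tc) exp(-(t - tc)^2 / (2 * bump_sd^2)),
                        numeric(length(t))))
  if (is.finite(snr_db)) {
    noise_sd <- stats::sd(env) / 10^(snr_db / 20)
    env <- env + local_seed(seed, abs(stats::rnorm(length(env), 0, noise_sd)))
  }
  list(envelope = pmax(env, 0), fs = fs, times = times)
}

#' Read nuclei times from a CSV of (sentence_id, time_s)
#' @param path CSV path with columns `sentence_id` and `time_s`.
#' @return named list of ascending numeric time vectors, one per sentence.
#' @export
read_nuclei_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("sentence_id", "time_s") %in% names(df)))
  lapply(split(df$time_s, df$sentence_id), sort)
}

#' Read a point tier from a Praat TextGrid text file
#'
#' Supports the long ("full") TextGrid text format in UTF-8 or UTF-16, point
#' tiers only (`class = "TextTier"`).
#'
#' @param path TextGrid file path.
#' @param tier name of the point tier to read.
#' @return numeric vector of point times in seconds.
#' @export
read_textgrid_points <- function(path, tier) {
  bytes <- readBin(path, "raw", 4)
  enc <- if (length(bytes) >= 2 &&
             ((bytes[1] == as.raw(0xFE) && bytes[2] == as.raw(0xFF)) ||
              (bytes[1] == as.raw(0xFF) && bytes[2] == as.raw(0xFE)))) "UTF-16" else "UTF-8"
  con <- file(path, encoding = enc)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  grab <- function(pattern, x) sub(pattern, "\\1", x[grepl(pattern, x)])
  tier_starts <- grep("item\\s*\\[\\d+\\]", lines)
  if (!length(tier_starts)) stop_invalid("no tiers found in ", path)
  bounds <- c(tier_starts, length(lines) + 1L)
  for (k in seq_along(tier_starts)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    name <- grab('.*name\\s*=\\s*"(.*)".*', block)[1]
    cls <- grab('.*class\\s*=\\s*"(.*)".*', block)[1]
    if (!is.na(name) && name == tier) {
      if (is.na(cls) || cls != "TextTier")
        stop_invalid("tier `", tier, "` is not a point tier (class ", cls, ")")
      nums <- grab(".*(?:number|time)\\s*=\\s*([-0-9.eE+]+).*", block)
      return(sort(as.numeric(nums)))
    }
  }
  stop_invalid("tier `", tier, "` not found in ", path)
}

#' Read a PCM WAV file (minimal RIFF reader)
#'
#' Reads uncompressed PCM (8/16/32-bit integer) mono or multichannel WAV.
#'
#' @param path WAV file path.
#' @return list with `samples` (samples x channels matrix, scaled to
#'   `[-1, 1]`) and `fs` (Hz).
#' @export
read_wav_pcm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop_invalid("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || length(id) == 0) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  fs = readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      fmt$bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_invalid("malformed WAV: data before fmt chunk")
      bytes_per <- fmt$bits / 8
      n <- size / bytes_per
      data <- if (fmt$bits == 8) {
        readBin(con, "integer", n, 1, signed = FALSE) / 127.5 - 1
      } else {
        readBin(con, "integer", n, bytes_per, endian = "little", signed = TRUE) /
          2^(fmt$bits - 1)
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(data)) stop_invalid("incomplete WAV file: ", path)
  if (fmt$audio_format != 1) stop_invalid("only PCM WAV is supported")
  list(samples = matrix(data, ncol = fmt$channels, byrow = TRUE), fs = fmt$fs)
}

#' Amplitude envelope of a waveform
#'
#' Rectifies and smooths (moving average) a waveform; channels are averaged.
#'
#' @param samples numeric vector or samples x channels matrix in `[-1, 1]`.
#' @param fs sampling rate (Hz).
#' @param smooth smoothing window in seconds.
#' @return non-negative numeric envelope at rate `fs`.
#' @export
wave_envelope <- function(samples, fs, smooth = 0.03) {
  x <- if (is.matrix(samples)) rowMeans(abs(samples)) else abs(samples)
  w <- max(1L, round(smooth * fs))
  env <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  env
}
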