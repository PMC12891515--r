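#' Specification for a synthetic syllable train
#'
#' Describes one synthetic "sentence" as a quasi-periodic train of syllable
#' nuclei: a nominal syllabic rate plus Gaussian jitter on the inter-nucleus
#' intervals. The five rate conditions studied experimentally span
#' 5-17.5 Syl/s; faster natural speech is more periodic (smaller jitter).
#'
#' @param rate syllabic rate in syllables per second (Syl/s); must be > 0.
#' @param jitter_sd standard deviation of the interval noise, in seconds;
#'   must be >= 0.
#' @param n_syllables number of nuclei; must be >= 2.
#' @param seed RNG seed.
#' @return an object of class `syllable_train_spec`.
#' @export
syllable_train_spec <- function(rate, jitter_sd = 0, n_syllables = 10L, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop_invalid("`rate` must be a single positive number (Syl/s)")
  if (!is.numeric(jitter_sd) || jitter_sd < 0)
    stop_invalid("`jitter_sd` must be >= 0")
  if (n_syllables < 2)
    stop_invalid("`n_syllables` must be >= 2")
  structure(list(rate = rate, jitter_sd = jitter_sd,
                 n_syllables = as.integer(n_syllables), seed = as.integer(seed)),
            class = "syllable_train_spec")
}

#' Generate a synthetic syllable train
#'
#' Intervals are drawn as `1/rate + N(0, jitter_sd)`, truncated below at 10%
#' of the nominal interval so that nuclei times remain strictly increasing
#' even at high jitter. Deterministic given the spec's seed.
#'
#' @param spec a [syllable_train_spec()].
#' @param sentence_id identifier carried into downstream records.
#' @param rate_condition nominal rate-condition label (Syl/s); defaults to
#'   `spec$rate`.
#' @param compression_factor unitless time-compression covariate.
#' @param mean_word_frequency sentence-level average word-frequency covariate.
#' @return an object of class `syllable_train` with fields `sentence_id`,
#'   `nuclei_times` (strictly increasing, seconds), `rate_condition`,
#'   `compression_factor`, `n_syllables`, `mean_word_frequency`.
#' @examples
#' tr <- gen_syllable_train(syllable_train_spec(5, 0, 10, seed = 1))
#' diff(tr$nuclei_times)   # all exactly 0.2 s
#' @export
gen_syllable_train <- function(spec, sentence_id = "s1",
                               rate_condition = spec$rate,
                               compression_factor = 1,
                               mean_word_frequency = 0) {
  stopifnot(inherits(spec, "syllable_train_spec"))
  nominal <- 1 / spec$rate
  intervals <- local_seed(spec$seed, {
    noise <- stats::rnorm(spec$n_syllables - 1L, 0, spec$jitter_sd)
    pmax(nominal + noise, 0.1 * nominal)
  })
  structure(list(sentence_id = sentence_id,
                 nuclei_times = cumsum(c(0, intervals)),
                 rate_condition = rate_condition,
                 compression_factor = compression_factor,
                 n_syllables = spec$n_syllables,
                 mean_word_frequency = mean_word_frequency,
                 spec = spec),
            class = "syllable_train")
}

#' Specification for a lag-coupled two-region trial
#'
#' Describes one synthetic trial of two-region multichannel activity: each
#' channel is 1/f^alpha background noise plus a shared narrowband theta
#' oscillation. The second region's theta component is the first region's,
#' delayed by `lag` seconds and scaled by `coupling_strength`, mixed with an
#' independent theta component so total theta power is constant; with
#' `coupling_strength = 0` the regions are statistically independent.
#'
#' @param fs sampling rate (Hz); must exceed `2 * theta_freq`.
#' @param duration epoch length in seconds.
#' @param theta_freq centre frequency of the shared oscillation (Hz).
#' @param theta_bw bandwidth of the oscillation (Hz); natural theta activity
#'   spans roughly the full 4-8 Hz band, so the default is 4.
#' @param coupling_strength unitless gain in `[0, 1]`.
#' @param lag delay of region 2's coupled component relative to region 1,
#'   in seconds; `0 <= lag < duration`.
#' @param noise_exponent alpha of the 1/f^alpha background.
#' @param n_channels channels (voxels) per region.
#' @param theta_amp amplitude of the theta component relative to the
#'   unit-variance broadband background.
#' @param broadband_coupling if `TRUE`, the 1/f background is also shared
#'   (delayed and scaled) across regions; by default coupling is injected
#'   only into the theta component, isolating the analysed band.
#' @param seed RNG seed.
#' @return an object of class `coupled_signal_spec`.
#' @export
coupled_signal_spec <- function(fs = 100, duration = 6, theta_freq = 6,
                                theta_bw = 4, coupling_strength = 0.5,
                                lag = 0.05, noise_exponent = 1,
                                n_channels = 8L, theta_amp = 0.7,
                                broadband_coupling = FALSE, seed = 1L) {
  if (fs <= 2 * theta_freq)
    stop_invalid("`fs` must exceed 2 * theta_freq")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop_invalid("`coupling_strength` must lie in [0, 1]")
  if (lag < 0 || lag >= duration)
    stop_invalid("`lag` must satisfy 0 <= lag < duration")
  structure(list(fs = fs, duration = duration, theta_freq = theta_freq,
                 theta_bw = theta_bw, coupling_strength = coupling_strength,
                 lag = lag, noise_exponent = noise_exponent,
                 n_channels = as.integer(n_channels), theta_amp = theta_amp,
                 broadband_coupling = broadband_coupling,
                 seed = as.integer(seed)),
            class = "coupled_signal_spec")
}

#' Generate one lag-coupled two-region trial
#'
#' @param spec a [coupled_signal_spec()].
#' @param region_labels labels for the two regions (auditory first).
#' @return an object of class `trial_data`: a list with `regions` (named list
#'   of samples x channels matrices), `fs`, and the generating `spec`.
#' @export
gen_coupled_trial <- function(spec, region_labels = c("pSTG", "iPCG")) {
  stopifnot(inherits(spec, "coupled_signal_spec"))
  n <- round(spec$fs * spec$duration)
  lag_samp <- round(spec$lag * spec$fs)
  cs <- spec$coupling_strength
  local_seed(spec$seed, {
    master <- noise_narrowband(n + lag_samp, spec$fs, spec$theta_freq, spec$theta_bw)
    th1 <- master[(lag_samp + 1):(lag_samp + n)]
    th2 <- cs * master[1:n] +
      sqrt(1 - cs^2) * noise_narrowband(n, spec$fs, spec$theta_freq, spec$theta_bw)
    if (spec$broadband_coupling) {
      bb_master <- noise_one_over_f(n + lag_samp, spec$fs, spec$noise_exponent,
                                    spec$n_channels)
      bb1 <- bb_master[(lag_samp + 1):(lag_samp + n), , drop = FALSE]
      bb2 <- cs * bb_master[1:n, , drop = FALSE] +
        sqrt(1 - cs^2) * noise_one_over_f(n, spec$fs, spec$noise_exponent,
                                          spec$n_channels)
    } else {
      bb1 <- noise_one_over_f(n, spec$fs, spec$noise_exponent, spec$n_channels)
      bb2 <- noise_one_over_f(n, spec$fs, spec$noise_exponent, spec$n_channels)
    }
    w1 <- stats::runif(spec$n_channels, 0.5, 1.5)
    w2 <- stats::runif(spec$n_channels, 0.5, 1.5)
    r1 <- bb1 + spec$theta_amp * outer(th1, w1)
    r2 <- bb2 + spec$theta_amp * outer(th2, w2)
    regions <- stats::setNames(list(r1, r2), region_labels)
    structure(list(regions = regions, fs = spec$fs, spec = spec),
              class = "trial_data")
  })
}

#' Specification for synthetic comprehension outcomes
#'
#' Scores in `[0, 1]` are generated from a beta distribution whose mean
#' follows a logit-linear model in the design covariates, with optional
#' subject-level intercept heterogeneity:
#' `score_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)`,
#' `logit(mu_i) = x_i' beta + b_subject`.
#'
#' @param fixed_coefficients named numeric vector on the logit scale. The
#'   name `"(Intercept)"` denotes the intercept; a name like `"a:b"` denotes
#'   the product of design columns `a` and `b`.
#' @param precision beta precision `phi > 0`.
#' @param subject_sd SD of subject random intercepts (logit scale), >= 0.
#' @param seed RNG seed.
#' @return an object of class `behavior_gen_spec`.
#' @export
behavior_gen_spec <- function(fixed_coefficients, precision = 30,
                              subject_sd = 0, seed = 1L) {
  if (is.null(names(fixed_coefficients)) || any(names(fixed_coefficients) == ""))
    stop_invalid("`fixed_coefficients` must be a fully named numeric vector")
  if (precision <= 0) stop_invalid("`precision` must be > 0")
  if (subject_sd < 0) stop_invalid("`subject_sd` must be >= 0")
  structure(list(fixed_coefficients = fixed_coefficients,
                 precision = precision, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "behavior_gen_spec")
}

#' Generate beta-distributed comprehension scores from a covariate design
#'
#' @param design data frame of covariates; must contain every column named by
#'   the spec's coefficients (interaction terms `"a:b"` require columns `a`
#'   and `b`). An optional `subject` column groups rows for random
#'   intercepts.
#' @param spec a [behavior_gen_spec()].
#' @return `design` with added columns `score` (in `(0, 1)`) and `mu_true`
#'   (the generating mean).
#' @export
gen_behavior <- function(design, spec) {
  stopifnot(is.data.frame(design), inherits(spec, "behavior_gen_spec"))
  beta <- spec$fixed_coefficients
  eta <- rep(0, nrow(design))
  for (term in names(beta)) {
    if (term == "(Intercept)") {
      eta <- eta + beta[[term]]
      next
    }
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    missing_cols <- setdiff(parts, names(design))
    if (length(missing_cols))
      stop_invalid("coefficient `", term, "` names unknown design column(s): ",
                   paste(missing_cols, collapse = ", "))
    col <- Reduce(`*`, lapply(parts, function(p) design[[p]]))
    eta <- eta + beta[[term]] * col
  }
  local_seed(spec$seed, {
    if (spec$subject_sd > 0 && !is.null(design$subject)) {
      subj <- factor(design$subject)
      b <- stats::rnorm(nlevels(subj), 0, spec$subject_sd)
      eta <- eta + b[as.integer(subj)]
    }
    mu <- stats::plogis(eta)
    design$mu_true <- mu
    design$score <- stats::rbeta(nrow(design), mu * spec$precision,
                                 (1 - mu) * spec$precision)
    design
  })
}

#' Write syllable trains to CSV (one row per nucleus)
#' @param trains list of `syllable_train` objects.
#' @param path output CSV path.
#' @export
write_syllable_trains <- function(trains, path) {
  rows <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(sentence_id = tr$sentence_id, time_s = tr$nuclei_times,
               rate_condition = tr$rate_condition,
               compression_factor = tr$compression_factor,
               n_syllables = tr$n_syllables,
               mean_word_frequency = tr$mean_word_frequency)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a trial to a directory of per-region CSV arrays plus a JSON sidecar
#'
#' Layout: `region_<label>.csv` (samples x channels, no header index) and
#' `meta.json` with `fs`, region labels, and the generating spec.
#'
#' @param trial a `trial_data` object.
#' @param dir output directory (created if needed).
#' @export
write_trial_data <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(trial$regions))
    utils::write.csv(trial$regions[[lab]],
                     file.path(dir, paste0("region_", lab, ".csv")),
                     row.names = FALSE)
  meta <- list(fs = trial$fs, labels = names(trial$regions),
               spec = unclass(trial$spec))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial written by [write_trial_data()]
#' @param dir directory containing `region_*.csv` and `meta.json`.
#' @return a `trial_data` object (spec restored as a plain list).
#' @export
read_trial_data <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  regions <- lapply(meta$labels, function(lab)
    as.matrix(utils::read.csv(file.path(dir, paste0("region_", lab, ".csv")))))
  names(regions) <- meta$labels
  structure(list(regions = regions, fs = meta$fs, spec = meta$spec),
            class = "trial_data")
}
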