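#' Surrogate segment length from syllabic rate
#'
#' The segment used for surrogate shuffling is a fixed fraction of the
#' syllabic cycle: `fraction / rate` seconds. With the standard fraction 0.8
#' this gives 160.0 ms at 5 Syl/s and 72.72 ms at 11 Syl/s, so segment
#' length varies across rate conditions while its relative length is
#' constant.
#'
#' @param rate syllabic rate (Syl/s), > 0.
#' @param fraction fraction of the syllabic cycle, in `(0, 1]`; default 0.8.
#' @return segment length in seconds.
#' @export
segment_length <- function(rate, fraction = 0.8) {
  if (!is.numeric(rate) || any(rate <= 0)) stop_invalid("`rate` must be > 0")
  if (fraction <= 0 || fraction > 1) stop_invalid("`fraction` must be in (0, 1]")
  fraction / rate
}

#' Configuration for the coupling pipeline
#'
#' @param freq_grid frequency centres (Hz); default the theta centres 4-8 Hz
#'   in 1 Hz steps.
#' @param bw spectral bandwidth per centre (Hz).
#' @param delay_grid delays in seconds; default 0-300 ms in 10 ms steps.
#' @param extraction_delay delay at which coupling is extracted and
#'   surrogate-normalized (s); must be on `delay_grid`. Default 0.05 s,
#'   where delay-resolved coupling plateaus.
#' @param theta_band inclusive band (Hz) averaged into the theta summary.
#' @param n_surrogates surrogate count per trial x frequency; default 500.
#' @param surrogate_fraction fraction of the syllabic cycle per segment.
#' @param n_components PCA components retained per region.
#' @param delay_scan if `TRUE` (default) a full delay-resolved GCMI grid is
#'   computed per frequency in addition to the surrogate-normalized value at
#'   the extraction delay; disable when only the theta summary is needed.
#' @param shuffle_both if `TRUE` both regions are segment-shuffled for the
#'   surrogates; default shuffles only the motor (second) region, which
#'   suffices to destroy cross-regional dependence.
#' @param keep_amplitude use amplitude-retaining analytic pairs instead of
#'   unit-normalized phase.
#' @param seed master seed; all surrogate streams are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(freq_grid = 4:8, bw = 2,
                            delay_grid = seq(0, 0.3, by = 0.01),
                            extraction_delay = 0.05,
                            theta_band = c(4, 8),
                            n_surrogates = 500L,
                            surrogate_fraction = 0.8,
                            n_components = 3L,
                            delay_scan = TRUE,
                            shuffle_both = FALSE,
                            keep_amplitude = FALSE,
                            seed = 1L) {
  if (!any(abs(delay_grid - extraction_delay) < 1e-9))
    stop_invalid("`extraction_delay` must be on `delay_grid`")
  if (surrogate_fraction <= 0 || surrogate_fraction > 1)
    stop_invalid("`surrogate_fraction` must be in (0, 1]")
  structure(list(freq_grid = freq_grid, bw = bw, delay_grid = delay_grid,
                 extraction_delay = extraction_delay, theta_band = theta_band,
                 n_surrogates = as.integer(n_surrogates),
                 surrogate_fraction = surrogate_fraction,
                 n_components = as.integer(n_components),
                 delay_scan = delay_scan,
                 shuffle_both = shuffle_both,
                 keep_amplitude = keep_amplitude,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Observed-vs-surrogate GCMI at a single delay for one frequency.
# x_scores / y_scores are PCA-reduced raw series; surrogates shuffle the raw
# motor series and re-extract the band phase, so segment seams are smoothed
# by the filter and the surrogate null shares the band's coherence time.
# Both series are truncated to a whole number of segments up front so the
# observed and surrogate statistics use identical sample counts (a length
# mismatch shifts the small-sample bias between them and miscalibrates z).
.freq_surrogate_z <- function(x_scores, y_scores, fs, f0, bw, shift,
                              seg_len, n_surrogates, shuffle_both,
                              keep_amplitude, stream_seed) {
  seg <- floor(seg_len * fs)
  n_keep <- floor(nrow(y_scores) / seg) * seg
  x_scores <- x_scores[seq_len(n_keep), , drop = FALSE]
  y_scores <- y_scores[seq_len(n_keep), , drop = FALSE]
  phx <- band_phase(x_scores, fs, f0, bw, keep_amplitude = keep_amplitude)
  phy <- band_phase(y_scores, fs, f0, bw, keep_amplitude = keep_amplitude)
  lo <- max(phx$valid[1], phy$valid[1])
  hi <- min(phx$valid[2], phy$valid[2])
  n_eff <- hi - lo + 1L - shift
  xs <- phx$pairs[lo:(lo + n_eff - 1L), , drop = FALSE]
  ys <- phy$pairs[(lo + shift):(lo + shift + n_eff - 1L), , drop = FALSE]
  zx <- copula_normalize(xs)
  dx <- ncol(zx)
  observed <- .mi_from_scores(cbind(zx, copula_normalize(ys)), dx)
  surr <- local_seed(stream_seed, {
    vapply(seq_len(n_surrogates), function(s) {
      ysh_raw <- segment_shuffle(y_scores, seg_len, fs)
      physh <- band_phase(ysh_raw, fs, f0, bw, keep_amplitude = keep_amplitude)
      yss <- physh$pairs[(lo + shift):(lo + shift + n_eff - 1L), , drop = FALSE]
      if (shuffle_both) {
        xsh_raw <- segment_shuffle(x_scores, seg_len, fs)
        phxsh <- band_phase(xsh_raw, fs, f0, bw, keep_amplitude = keep_amplitude)
        xss <- phxsh$pairs[lo:(lo + n_eff - 1L), , drop = FALSE]
        .mi_from_scores(cbind(copula_normalize(xss), copula_normalize(yss)), dx)
      } else {
        .mi_from_scores(cbind(zx, copula_normalize(yss)), dx)
      }
    }, numeric(1))
  })
  list(observed = observed, z = surrogate_z(observed, surr))
}

#' Run the coupling analysis for one trial
#'
#' Per frequency: PCA reduction, band-phase extraction, a delay-resolved
#' GCMI scan, and surrogate z-normalization at the extraction delay
#' (`n_surrogates` segment-shuffle recomputations of the motor region). The
#' theta summary `theta_mean_z` averages z over the theta band at the
#' extraction delay. Trials too short to hold two segments at their rate's
#' segment length are skipped with a logged reason rather than failing.
#'
#' @param trial a `trial_data` object (first region auditory, second motor).
#' @param rate the trial's syllabic rate (Syl/s), which sets the surrogate
#'   segment length.
#' @param config a [pipeline_config()].
#' @param subject,trial_id,roi_pair,hemisphere identifiers carried into the
#'   output and into the surrogate seed derivation.
#' @return object of class `coupling_result`: list with `grid` (data frame
#'   freq_hz x delay_ms x gcmi_bits), `z_table` (freq_hz, gcmi_bits, z_gcmi at
#'   the extraction delay), `theta_mean_z`, identifiers, and `skipped`
#'   (with `reason` when `TRUE`).
#' @export
run_trial_coupling <- function(trial, rate, config = pipeline_config(),
                               subject = "s1", trial_id = "t1",
                               roi_pair = "iPCG-pSTG", hemisphere = "L") {
  stopifnot(inherits(trial, "trial_data"), inherits(config, "pipeline_config"))
  if (length(trial$regions) < 2) stop_invalid("trial must hold two regions")
  fs <- trial$fs
  seg_len <- segment_length(rate, config$surrogate_fraction)
  n <- nrow(trial$regions[[1]])
  base <- list(subject = subject, trial = trial_id, roi_pair = roi_pair,
               hemisphere = hemisphere)
  if (floor(n / floor(seg_len * fs)) < 2) {
    return(structure(c(base, list(
      skipped = TRUE,
      reason = sprintf("epoch %.2f s holds fewer than 2 segments of %.4f s",
                       n / fs, seg_len))), class = "coupling_result"))
  }
  x_scores <- pca_reduce(trial$regions[[1]], config$n_components)$scores
  y_scores <- pca_reduce(trial$regions[[2]], config$n_components)$scores
  shift <- as.integer(round(config$extraction_delay * fs))
  rows <- vector("list", length(config$freq_grid))
  ztab <- data.frame(freq_hz = config$freq_grid, gcmi_bits = NA_real_,
                     z_gcmi = NA_real_)
  for (i in seq_along(config$freq_grid)) {
    f0 <- config$freq_grid[i]
    if (isTRUE(config$delay_scan)) {
      phx <- band_phase(x_scores, fs, f0, config$bw,
                        keep_amplitude = config$keep_amplitude)
      phy <- band_phase(y_scores, fs, f0, config$bw,
                        keep_amplitude = config$keep_amplitude)
      scan <- delay_gcmi(phx, phy, config$delay_grid)
      rows[[i]] <- data.frame(freq_hz = f0, delay_ms = scan$delay_s * 1000,
                              gcmi_bits = scan$mi_bits)
    }
    sz <- .freq_surrogate_z(x_scores, y_scores, fs, f0, config$bw, shift,
                            seg_len, config$n_surrogates, config$shuffle_both,
                            config$keep_amplitude,
                            derive_seed(config$seed, subject, trial_id,
                                        roi_pair, hemisphere, f0))
    ztab$gcmi_bits[i] <- sz$observed
    ztab$z_gcmi[i] <- sz$z
  }
  in_theta <- ztab$freq_hz >= config$theta_band[1] &
              ztab$freq_hz <= config$theta_band[2]
  structure(c(base, list(
    skipped = FALSE,
    grid = if (isTRUE(config$delay_scan)) do.call(rbind, rows) else NULL,
    z_table = ztab,
    theta_mean_z = mean(ztab$z_gcmi[in_theta]))), class = "coupling_result")
}

#' Run the coupling pipeline over a set of trials
#'
#' @param trials named list of `trial_data` objects (names used as trial ids).
#' @param rates numeric vector of syllabic rates, one per trial.
#' @param config a [pipeline_config()].
#' @param subject,roi_pair,hemisphere identifiers (scalars or per-trial
#'   vectors).
#' @param verbose log skipped trials via `message()`.
#' @return list with `results` (tidy data frame: subject, trial, roi_pair,
#'   hemisphere, theta_mean_z plus per-frequency z columns) and `skipped`
#'   (data frame of skipped trials and reasons).
#' @export
run_coupling <- function(trials, rates, config = pipeline_config(),
                         subject = "s1", roi_pair = "iPCG-pSTG",
                         hemisphere = "L", verbose = FALSE) {
  stopifnot(length(trials) == length(rates))
  ids <- names(trials)
  if (is.null(ids)) ids <- sprintf("t%03d", seq_along(trials))
  rec <- function(x, i) if (length(x) == 1) x else x[i]
  out <- vector("list", length(trials))
  skipped <- list()
  for (i in seq_along(trials)) {
    r <- run_trial_coupling(trials[[i]], rates[i], config,
                            subject = rec(subject, i), trial_id = ids[i],
                            roi_pair = rec(roi_pair, i),
                            hemisphere = rec(hemisphere, i))
    if (isTRUE(r$skipped)) {
      if (verbose) message("skipping trial ", ids[i], ": ", r$reason)
      skipped[[length(skipped) + 1]] <-
        data.frame(trial = ids[i], reason = r$reason)
      next
    }
    out[[i]] <- data.frame(subject = r$subject, trial = r$trial,
                           roi_pair = r$roi_pair, hemisphere = r$hemisphere,
                           theta_mean_z = r$theta_mean_z)
  }
  list(results = do.call(rbind, out),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(trial = character(0), reason = character(0)))
}

#' Join coupling, behavioral, and periodicity records into one analysis table
#'
#' Inner join on the `trial` key: one row per trial x roi_pair x hemisphere.
#' Unmatched trial keys on either side are reported in the `unmatched`
#' attribute (and by message); duplicated keys are an error.
#'
#' @param coupling data frame with `trial`, `roi_pair`, `hemisphere`,
#'   `theta_mean_z` (e.g. `run_coupling()$results`).
#' @param behavior data frame with `trial`, `score`, and covariates.
#' @param periodicity data frame with `trial`, `mad`, `residual_mad`.
#' @return merged data frame with attribute `unmatched`.
#' @export
assemble_dataset <- function(coupling, behavior, periodicity) {
  for (nm in c("trial")) {
    if (anyDuplicated(behavior[[nm]]))
      stop_invalid("duplicate behavior keys: ",
                   paste(unique(behavior[[nm]][duplicated(behavior[[nm]])]),
                         collapse = ", "))
    if (anyDuplicated(periodicity[[nm]]))
      stop_invalid("duplicate periodicity keys: ",
                   paste(unique(periodicity[[nm]][duplicated(periodicity[[nm]])]),
                         collapse = ", "))
  }
  ckey <- paste(coupling$trial, coupling$roi_pair, coupling$hemisphere)
  if (anyDuplicated(ckey))
    stop_invalid("duplicate coupling keys: ",
                 paste(unique(ckey[duplicated(ckey)]), collapse = ", "))
  bp_cols <- setdiff(names(periodicity), names(behavior))
  bp <- merge(behavior, periodicity[, c("trial", bp_cols), drop = FALSE],
              by = "trial")
  joined <- merge(coupling, bp, by = intersect(names(coupling), names(bp)))
  all_keys <- union(union(coupling$trial, behavior$trial), periodicity$trial)
  present <- intersect(intersect(coupling$trial, behavior$trial),
                       periodicity$trial)
  unmatched <- setdiff(all_keys, present)
  if (length(unmatched))
    message(length(unmatched), " trial key(s) unmatched: ",
            paste(utils::head(unmatched, 10), collapse = ", "))
  attr(joined, "unmatched") <- unmatched
  joined
}

#' Simulate a full synthetic study cohort with known ground truth
#'
#' Builds, end to end, the data a desk-scale replication of the experiment
#' needs: syllable trains across the five rate conditions (faster speech
#' generated more periodic), per-trial lag-coupled neural signals whose
#' coupling strength increases with syllabic rate and with interval jitter
#' (so true coupling rises with rate and with residual MAD), and
#' beta-distributed comprehension scores that fall with rate and rise with
#' residual MAD (negative rate x periodicity interaction). The coupling
#' pipeline is then run and everything joined into one analysis table.
#'
#' @param n_per_rate sentences per rate condition.
#' @param rates the rate conditions (Syl/s).
#' @param config a [pipeline_config()] (its `seed` is ignored in favour of
#'   `seed`).
#' @param seed master seed for every random component.
#' @param n_subjects number of synthetic subjects (trials split evenly).
#' @param behavior_coefficients generating logit-scale coefficients; the
#'   defaults correspond to comprehension near 85% at 5 Syl/s falling to
#'   roughly 30% at 17.5 Syl/s, a positive residual-MAD effect, and a
#'   negative rate x MAD interaction.
#' @param precision,subject_sd beta precision and subject intercept SD.
#' @param coupling_base,coupling_per_rate,coupling_per_jitterdev parameters
#'   of the true coupling strength
#'   `base + per_rate * (rate - mean(rate)) + per_jitterdev * zdev`, clamped
#'   to `[0.05, 0.95]`, where `zdev` is the sentence's standard-normal
#'   log-jitter deviation from its rate condition's typical jitter. True
#'   coupling therefore rises with syllabic rate and with within-condition
#'   aperiodicity — the decorrelated quantity residual MAD estimates.
#' @param duration,lag neural epoch length and auditory-to-motor lag (s).
#' @return list with `analysis` (assembled table), `periodicity`, `coupling`,
#'   `behavior`, `skipped`, and `truth` (the generating parameters, including
#'   each trial's true coupling strength).
#' @export
simulate_cohort <- function(n_per_rate = 16,
                            rates = c(5, 11, 14, 16, 17.5),
                            config = pipeline_config(n_surrogates = 40L,
                                                     delay_scan = FALSE),
                            seed = 1L, n_subjects = 6L,
                            behavior_coefficients = c(
                              "(Intercept)" = 0.4, rate_c = -0.21,
                              residual_mad = 15, "rate_c:residual_mad" = -1.2,
                              compression_c = 0.2, n_syll_c = -0.05),
                            precision = 30, subject_sd = 0.3,
                            coupling_base = 0.45, coupling_per_rate = 0.02,
                            coupling_per_jitterdev = 0.12,
                            duration = 6, lag = 0.05) {
  n_trials <- n_per_rate * length(rates)
  ids <- sprintf("t%03d", seq_len(n_trials))
  cond <- rep(rates, each = n_per_rate)
  meta <- local_seed(derive_seed(seed, "design"), {
    zdev <- stats::rnorm(n_trials)
    jitter_cv <- 0.18 * (5 / cond)^0.35 * exp(0.5 * zdev)
    data.frame(trial = ids, rate = cond, zdev = zdev,
               jitter_sd = jitter_cv / cond,
               n_syllables = round(stats::runif(n_trials, 14, 24)),
               compression = stats::rnorm(n_trials, 1, 0.08),
               word_freq = stats::rnorm(n_trials),
               subject = sprintf("subj%02d",
                                 rep_len(seq_len(n_subjects), n_trials)))
  })
  trains <- lapply(seq_len(n_trials), function(i)
    gen_syllable_train(
      syllable_train_spec(meta$rate[i], meta$jitter_sd[i], meta$n_syllables[i],
                          seed = derive_seed(seed, "train", ids[i])),
      sentence_id = ids[i], rate_condition = meta$rate[i],
      compression_factor = meta$compression[i],
      mean_word_frequency = meta$word_freq[i]))
  perio <- periodicity_records(trains)
  names(perio)[names(perio) == "sentence_id"] <- "trial"
  perio <- residualize_mad(perio)
  cs_true <- clamp(coupling_base + coupling_per_rate * (meta$rate - mean(rates)) +
                     coupling_per_jitterdev * meta$zdev, 0.05, 0.95)
  trials <- lapply(seq_len(n_trials), function(i)
    gen_coupled_trial(coupled_signal_spec(
      duration = duration, coupling_strength = cs_true[i], lag = lag,
      seed = derive_seed(seed, "neural", ids[i]))))
  names(trials) <- ids
  cfg <- config
  cfg$seed <- derive_seed(seed, "surrogates")
  coup <- run_coupling(trials, meta$rate, cfg, subject = meta$subject)
  rate_mean <- mean(meta$rate)
  design <- data.frame(trial = ids, subject = meta$subject,
                       rate = meta$rate, rate_c = meta$rate - rate_mean,
                       residual_mad = perio$residual_mad,
                       compression_c = meta$compression - 1,
                       n_syll_c = meta$n_syllables - mean(meta$n_syllables),
                       word_freq = meta$word_freq)
  behavior <- gen_behavior(design,
                           behavior_gen_spec(behavior_coefficients, precision,
                                             subject_sd,
                                             seed = derive_seed(seed, "behavior")))
  analysis <- assemble_dataset(coup$results, behavior,
                               perio[, c("trial", "mad", "residual_mad",
                                         "empirical_rate")])
  list(analysis = analysis, periodicity = perio, coupling = coup$results,
       behavior = behavior, skipped = coup$skipped,
       truth = list(coupling_strength = stats::setNames(cs_true, ids),
                    behavior_coefficients = behavior_coefficients,
                    precision = precision, subject_sd = subject_sd,
                    lag = lag, rate_mean = rate_mean))
}

#' Fit the cohort's comprehension and coupling models
#'
#' Comprehension: `score ~ rate_c * residual_mad + compression_c + n_syll_c`
#' with boundary adjustment. Coupling: min-max-normalized, boundary-adjusted
#' `theta_mean_z ~ rate_c + residual_mad`. Both are beta regressions with a
#' logit link.
#'
#' @param analysis table from [simulate_cohort()]/[assemble_dataset()].
#' @return list with `comprehension` and `coupling` (`beta_fit` objects) and
#'   `signs`, the named sign vector of the four headline effects
#'   (comprehension rate and residual MAD; coupling rate and residual MAD).
#' @export
fit_cohort_models <- function(analysis) {
  a <- analysis
  a$score_adj <- boundary_adjust(a$score)
  a$z01 <- boundary_adjust(minmax_normalize(a$theta_mean_z))
  comp <- beta_regression_fit(
    score_adj ~ rate_c * residual_mad + compression_c + n_syll_c, data = a)
  coup <- beta_regression_fit(z01 ~ rate_c + residual_mad, data = a)
  list(comprehension = comp, coupling = coup,
       signs = c(comp_rate = unname(sign(stats::coef(comp)["rate_c"])),
                 comp_mad = unname(sign(stats::coef(comp)["residual_mad"])),
                 coup_rate = unname(sign(stats::coef(coup)["rate_c"])),
                 coup_mad = unname(sign(stats::coef(coup)["residual_mad"]))))
}
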