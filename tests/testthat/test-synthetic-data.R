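test_that("syllable trains follow the stated generative rule", {
  # zero jitter: exactly periodic at 1/rate
  tr <- gen_syllable_train(syllable_train_spec(5, 0, 10, seed = 1))
  expect_equal(diff(tr$nuclei_times), rep(0.2, 9))
  expect_equal(interval_mad(nuclei_intervals(tr)), 0)

  # Monte-Carlo: mean interval close to the nominal cycle
  tr2 <- gen_syllable_train(syllable_train_spec(5, 0.02, 200, seed = 1))
  expect_lt(abs(mean(diff(tr2$nuclei_times)) - 0.2), 0.005)

  # strictly increasing even at extreme jitter (truncation rule)
  tr3 <- gen_syllable_train(syllable_train_spec(10, 0.5, 100, seed = 3))
  expect_true(all(diff(tr3$nuclei_times) > 0))

  # seeding contract
  a <- gen_syllable_train(syllable_train_spec(5, 0.02, 50, seed = 1))
  b <- gen_syllable_train(syllable_train_spec(5, 0.02, 50, seed = 1))
  c <- gen_syllable_train(syllable_train_spec(5, 0.02, 50, seed = 2))
  expect_identical(a$nuclei_times, b$nuclei_times)
  expect_false(identical(a$nuclei_times, c$nuclei_times))

  expect_error(syllable_train_spec(-1, 0, 10), "positive")
  expect_error(syllable_train_spec(5, 0, 1), "n_syllables")
})

test_that("empirical MAD increases with generator jitter", {
  jitters <- c(0, 0.005, 0.01, 0.02, 0.04)
  mean_mads <- sapply(jitters, function(j) {
    mean(sapply(1:100, function(r) {
      tr <- gen_syllable_train(syllable_train_spec(5, j, 25, seed = r))
      interval_mad(nuclei_intervals(tr))
    }))
  })
  expect_true(all(diff(mean_mads) > 0))
})

test_that("1/f background has the requested spectral exponent", {
  for (alpha in c(0.5, 1, 1.5)) {
    tr <- gen_coupled_trial(coupled_signal_spec(duration = 40,
                                                noise_exponent = alpha,
                                                theta_amp = 0,
                                                seed = 10 + alpha * 10))
    x <- tr$regions[[1]][, 1]
    sp <- stats::spec.pgram(stats::ts(x, frequency = tr$fs), plot = FALSE,
                            taper = 0.1, spans = 5)
    keep <- sp$freq > 1 & sp$freq < 40
    slope <- coef(lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2]
    expect_lt(abs(slope + alpha), 0.3)
  }
})

test_that("coupled trials are reproducible and respect the lag/strength spec", {
  sp <- coupled_signal_spec(coupling_strength = 0.8, lag = 0.05, seed = 4)
  t1 <- gen_coupled_trial(sp)
  t2 <- gen_coupled_trial(sp)
  expect_identical(t1$regions, t2$regions)
  expect_error(coupled_signal_spec(lag = 10, duration = 4), "lag")
  expect_error(coupled_signal_spec(coupling_strength = 1.2), "coupling_strength")

  # delay-resolved coupling peaks at the injected lag (theta-averaged scan)
  hits <- sapply(1:10, function(i) {
    tr <- gen_coupled_trial(coupled_signal_spec(coupling_strength = 0.9,
                                                lag = 0.05, seed = 100 + i))
    xs <- pca_reduce(tr$regions[[1]], 3)$scores
    ys <- pca_reduce(tr$regions[[2]], 3)$scores
    mi <- Reduce(`+`, lapply(4:8, function(f0)
      delay_gcmi(band_phase(xs, tr$fs, f0), band_phase(ys, tr$fs, f0),
                 seq(0, 0.3, 0.01))$mi_bits))
    abs(seq(0, 0.3, 0.01)[which.max(mi)] - 0.05) <= 0.0100001
  })
  expect_gte(mean(hits), 0.8)
})

test_that("uncoupled regions are statistically independent", {
  # GCMI needs near-independent samples for its bias term to apply, so the
  # check thins long epochs far beyond the band's coherence time.
  mis <- sapply(1:100, function(i) {
    tr <- gen_coupled_trial(coupled_signal_spec(duration = 120,
                                                coupling_strength = 0,
                                                seed = 500 + i))
    idx <- seq(1, nrow(tr$regions[[1]]), by = 75)
    x <- tr$regions[[1]][idx, 1]
    y <- tr$regions[[2]][idx, 1]
    mi_gg(copula_normalize(x), copula_normalize(y))$value
  })
  expect_lt(abs(mean(mis)), 0.01)
})

test_that("behavioral generator matches its beta model", {
  d <- data.frame(x = rnorm(500))
  s0 <- behavior_gen_spec(c("(Intercept)" = 0), precision = 30, seed = 1)
  g <- gen_behavior(d, s0)
  expect_lt(abs(mean(g$score) - 0.5), 0.02)
  expect_true(all(g$score > 0 & g$score < 1))

  # negative rate coefficient: mean score decreases across rate bins
  d2 <- data.frame(rate = rep(c(5, 11, 14, 16, 17.5), each = 300))
  g2 <- gen_behavior(d2, behavior_gen_spec(
    c("(Intercept)" = 2, rate = -0.2), precision = 30, seed = 2))
  bins <- tapply(g2$score, g2$rate, mean)
  expect_true(all(diff(bins) < 0))

  # precision -> large collapses per-cell variance
  g_hi <- gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0.5),
                                            precision = 5000, seed = 3))
  g_lo <- gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0.5),
                                            precision = 5, seed = 3))
  expect_lt(var(g_hi$score), var(g_lo$score) / 50)

  # unknown coefficient name is a schema error
  expect_error(gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0, zz = 1))),
               "unknown design column")

  # subject intercept heterogeneity widens the between-subject spread
  d3 <- data.frame(x = rnorm(2000),
                   subject = rep(sprintf("s%02d", 1:20), each = 100))
  g_flat <- gen_behavior(d3, behavior_gen_spec(c("(Intercept)" = 0),
                                               subject_sd = 0, seed = 4))
  g_het <- gen_behavior(d3, behavior_gen_spec(c("(Intercept)" = 0),
                                              subject_sd = 1, seed = 4))
  sd_flat <- sd(tapply(qlogis(g_flat$score), d3$subject, mean))
  sd_het <- sd(tapply(qlogis(g_het$score), d3$subject, mean))
  expect_gt(sd_het, 3 * sd_flat)
})

test_that("trial data survives the directory round trip", {
  tr <- gen_coupled_trial(coupled_signal_spec(duration = 2, seed = 6))
  dir <- withr::local_tempdir()
  write_trial_data(tr, dir)
  back <- read_trial_data(dir)
  expect_equal(back$fs, tr$fs)
  expect_equal(unname(back$regions[[1]]), unname(tr$regions[[1]]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_named(back$regions, c("pSTG", "iPCG"))
})
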