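test_that("copula normalization maps ranks to the normal grid", {
  expect_equal(drop(copula_normalize(c(5, 1, 9))),
               qnorm(c(0.5, 0.25, 0.75)), tolerance = 1e-10)
  # rank invariance under strictly monotone transforms, exactly
  x <- matrix(rnorm(200), ncol = 2)
  expect_identical(copula_normalize(x), copula_normalize(exp(x)))
  # symmetric rank grid: column medians are 0
  z <- copula_normalize(matrix(runif(201), ncol = 1))
  expect_lt(abs(median(z)), 1e-12)
  expect_error(copula_normalize(cbind(1:10, rep(2, 10))), "degenerate")
})

test_that("GCMI matches the bivariate Gaussian closed form", {
  set.seed(11)
  n <- 50000
  x <- rnorm(n)
  for (r in c(0.3, 0.6, 0.9)) {
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    z <- copula_normalize(cbind(x, y))
    est <- mi_gg(z[, 1], z[, 2])
    expect_lt(abs(est$value - (-0.5 * log2(1 - r^2))), 0.01)
  }
  # independence: bias-corrected value near zero
  zi <- copula_normalize(cbind(rnorm(n), rnorm(n)))
  expect_lt(abs(mi_gg(zi[, 1], zi[, 2])$value), 0.005)
})

test_that("GCMI is non-negative without bias correction, errors on rank deficiency", {
  set.seed(12)
  for (rep in 1:20) {
    z <- copula_normalize(matrix(rnorm(200), ncol = 2))
    expect_gte(mi_gg(z[, 1], z[, 2], bias_correct = FALSE)$value, 0)
  }
  x <- rnorm(100)
  expect_error(mi_gg(x, x), "rank-deficient")
  expect_error(mi_gg(rnorm(10), matrix(rnorm(80), ncol = 8)), "n > dx")
})

test_that("PCA reduction recovers designed subspaces and orders variance", {
  set.seed(13)
  n <- 400
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  lat <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1))
  dat <- lat %*% t(basis)
  # exact rank 2: k truncated with warning, retained proportions sum to 1
  expect_warning(p <- pca_reduce(dat, 3), "rank")
  expect_equal(p$k, 2)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  # principal angles between recovered and true subspace ~ 0
  load <- t(qr.solve(cbind(p$scores), dat))   # n x k -> fitted loadings
  ang <- svd(t(qr.Q(qr(load))) %*% basis)$d
  expect_true(all(abs(ang - 1) < 1e-6))
  expect_error(pca_reduce(dat, 9), "exceeds")
})

test_that("band phase tracks frequency, rejects out-of-band, discards amplitude", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  f0 <- 6
  x <- cos(2 * pi * f0 * t + 1)
  ph <- band_phase(matrix(x), fs, f0)
  v <- ph$valid[1]:ph$valid[2]
  ang <- atan2(ph$pairs[v, 2], ph$pairs[v, 1])
  inst_f <- diff(ang) / (2 * pi / fs)
  inst_f[inst_f < 0] <- inst_f[inst_f < 0] + fs   # unwrap jumps
  expect_lt(abs(median(inst_f) - f0), 0.01 * f0)
  # unit norm per sample
  norms <- sqrt(ph$pairs[, 1]^2 + ph$pairs[, 2]^2)
  expect_true(all(abs(norms - 1) < 1e-9))

  # tone 3 bandwidths away: residual power < 5% of in-band case
  x_out <- cos(2 * pi * (f0 + 3 * 2) * t)
  a_in <- fft_band_filter(x, fs, f0, 2)
  a_out <- fft_band_filter(x_out, fs, f0, 2)
  expect_lt(mean(a_out^2) / mean(a_in^2), 0.05)

  # amplitude modulation leaves the phase sequence unchanged
  am <- (1 + 0.5 * sin(2 * pi * 0.3 * t)) * cos(2 * pi * f0 * t + 1)
  ph_am <- band_phase(matrix(am), fs, f0)
  dphi <- atan2(ph_am$pairs[v, 2], ph_am$pairs[v, 1]) - ang
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_lt(max(abs(dphi)), 0.05)

  expect_error(band_phase(matrix(rnorm(20)), fs, f0), "too short")
  expect_error(band_phase(matrix(rnorm(1000)), 10, f0), "fs must exceed")
})

test_that("delay grid [0] reduces to plain GCMI on the full overlap", {
  set.seed(14)
  tr <- gen_coupled_trial(coupled_signal_spec(duration = 3,
                                              coupling_strength = 0.7, seed = 3))
  xs <- pca_reduce(tr$regions[[1]], 2)$scores
  ys <- pca_reduce(tr$regions[[2]], 2)$scores
  phx <- band_phase(xs, tr$fs, 6)
  phy <- band_phase(ys, tr$fs, 6)
  sc <- delay_gcmi(phx, phy, 0)
  v <- max(phx$valid[1], phy$valid[1]):min(phx$valid[2], phy$valid[2])
  direct <- mi_gg(copula_normalize(phx$pairs[v, ]),
                  copula_normalize(phy$pairs[v, ]))$value
  expect_equal(sc$mi_bits, direct, tolerance = 1e-12)
  expect_error(delay_gcmi(phx, phy, 0.0033), "integer sample")
  expect_error(delay_gcmi(phx, phy, 10), "too few samples")
})

test_that("independent regions show no delay structure", {
  set.seed(15)
  tr <- gen_coupled_trial(coupled_signal_spec(duration = 110,
                                              coupling_strength = 0, seed = 9))
  # thin far beyond the band coherence time so the bias term applies
  idx <- seq(1, nrow(tr$regions[[1]]), by = 60)
  x <- copula_normalize(tr$regions[[1]][idx, 1:2])
  y <- copula_normalize(tr$regions[[2]][idx, 1:2])
  expect_lt(abs(mi_gg(x, y)$value), 0.02)
})

test_that("segment shuffling permutes blocks uniformly and preserves values", {
  x <- matrix(seq_len(40), ncol = 1)
  # 2 segments: identity or swap, each about half the time
  swaps <- sapply(1:1000, function(i)
    segment_shuffle(x, 2, 10, seed = i)[1, 1] != 1)
  expect_gt(mean(swaps), 0.45); expect_lt(mean(swaps), 0.55)
  # rearrangement only (tail dropped)
  y <- segment_shuffle(x, 0.7, 10, seed = 1)
  expect_true(all(y %in% x))
  expect_equal(nrow(y), 35)
  # seeding contract
  expect_identical(segment_shuffle(x, 0.5, 10, seed = 7),
                   segment_shuffle(x, 0.5, 10, seed = 7))
  expect_error(segment_shuffle(x, 10, 10), "fewer than 2 segments")
})

test_that("surrogate z-scoring is exact arithmetic with affine invariances", {
  s <- c(1, 2, 3, 4, 5)
  expect_equal(surrogate_z(3, s), 0)
  expect_equal(surrogate_z(mean(s) + 2 * sd(s), s), 2)
  expect_error(surrogate_z(1, c(2, 2)), "zero spread")
  expect_error(surrogate_z(1, 2), "at least 2")
  # invariant under common shift and positive common scaling
  expect_equal(surrogate_z(4 + 10, s + 10), surrogate_z(4, s))
  expect_equal(surrogate_z(4 * 3, s * 3), surrogate_z(4, s))
})
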