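test_that("boundary adjustment implements the median/n rule", {
  expect_equal(boundary_adjust(c(0, 0.5, 1)), c(1 / 6, 0.5, 5 / 6))
  y <- c(0.2, 0.5, 0.9)
  expect_identical(boundary_adjust(y), y)
  expect_error(boundary_adjust(c(0, 0, 0)), "eps = 0")
  expect_error(boundary_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
  # per-group medians behind the group argument
  g <- boundary_adjust(c(0, 0.4, 0.6, 1), group = c(1, 1, 2, 2))
  expect_equal(g[1], median(c(0, 0.4)) / 2)
  expect_equal(g[4], 1 - median(c(0.6, 1)) / 2)
})

test_that("min-max normalization is a monotone map onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  y <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(y), y)
  x <- rnorm(50)
  expect_equal(order(minmax_normalize(x)), order(x))
  expect_error(minmax_normalize(rep(3, 5)), "constant")
})

test_that("orthonormal polynomial basis is centred, orthonormal, sign-fixed", {
  x <- c(rexp(97), 0.1, 0.2, 0.3)
  P <- ortho_poly(x, 3)
  expect_equal(crossprod(P), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(P))), 1e-12)
  for (j in 1:3) expect_gt(sum(P[, j] * x^j), 0)
  # degree 1 on symmetric x equals standardized x up to normalization
  xs <- seq(-2, 2, by = 0.1)
  P1 <- ortho_poly(xs, 1)
  expect_equal(drop(P1), (xs - mean(xs)) / sqrt(sum((xs - mean(xs))^2)))
  expect_error(ortho_poly(c(1, 1, 2), 2), "distinct")
})

test_that("beta regression recovers generating parameters", {
  set.seed(21)
  n <- 3000
  d <- data.frame(x1 = rnorm(n), x2 = runif(n) - 0.5)
  truth <- c("(Intercept)" = 0.3, x1 = -0.5, x2 = 0.8)
  d <- gen_behavior(d, behavior_gen_spec(truth, precision = 30, seed = 22))
  fit <- beta_regression_fit(score ~ x1 + x2, data = d)
  expect_true(fit$converged)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
  expect_lt(abs(fit$phi - 30) / 30, 0.15)
  # intercept-only fit matches the mean on the response scale
  f0 <- beta_regression_fit(score ~ 1, data = d)
  expect_lt(abs(plogis(coef(f0)[1]) - mean(d$score)), 1e-3)
  # likelihood never below the starting values (monotone safeguard)
  expect_gte(fit$logLik, fit$logLik_null)
})

test_that("beta regression agrees with an independent fixed-effects fitter", {
  skip_if_not_installed("glmmTMB")
  set.seed(23)
  n <- 800
  d <- data.frame(x = rnorm(n))
  d <- gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0.2, x = 0.6),
                                         precision = 20, seed = 24))
  ours <- beta_regression_fit(score ~ x, data = d)
  ref <- glmmTMB::glmmTMB(score ~ x, data = d,
                          family = glmmTMB::beta_family())
  expect_equal(unname(coef(ours)),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
  expect_equal(ours$phi, unname(exp(glmmTMB::fixef(ref)$disp[[1]])),
               tolerance = 1e-2)
})

test_that("beta regression rejects boundary responses and collinearity", {
  d <- data.frame(y = c(0, runif(20)), x = rnorm(21))
  expect_error(beta_regression_fit(y ~ x, data = d), "boundary_adjust")
  d2 <- data.frame(y = runif(30, 0.1, 0.9), x = rnorm(30))
  d2$x2 <- 2 * d2$x
  expect_error(beta_regression_fit(y ~ x + x2, data = d2), "collinear")
})

test_that("null covariates stay within 2 SEs at the nominal rate", {
  inside <- sapply(1:200, function(r) {
    d <- data.frame(x = rnorm(300), z = rnorm(300))
    d <- gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0.3, x = -0.4),
                                           precision = 25, seed = 3000 + r))
    fit <- beta_regression_fit(score ~ x + z, data = d)
    abs(coef(fit)["z"]) < 2 * sqrt(vcov(fit)["z", "z"])
  })
  expect_gte(mean(inside), 0.93)
})

test_that("cluster bootstrap matches model SEs for independent rows and widens under clustering", {
  set.seed(26)
  n <- 400
  d <- data.frame(x = rnorm(n), cl = sprintf("c%03d", seq_len(n)))
  d <- gen_behavior(d, behavior_gen_spec(c("(Intercept)" = 0.2, x = 0.5),
                                         precision = 20, seed = 27))
  fit <- beta_regression_fit(score ~ x, data = d)
  bs <- cluster_bootstrap(fit, d, "cl", B = 200, seed = 28)
  model_se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(bs$se - model_se) / model_se < 0.15))

  # strong subject intercept heterogeneity: bootstrap SEs exceed naive ones
  d2 <- data.frame(x = rnorm(600),
                   subject = rep(sprintf("s%02d", 1:20), each = 30))
  d2 <- gen_behavior(d2, behavior_gen_spec(c("(Intercept)" = 0), precision = 20,
                                           subject_sd = 1, seed = 29))
  fit2 <- beta_regression_fit(score ~ x, data = d2)
  bs2 <- cluster_bootstrap(fit2, d2, "subject", B = 200, seed = 30)
  expect_gt(bs2$se[["(Intercept)"]],
            sqrt(vcov(fit2)["(Intercept)", "(Intercept)"]))
  expect_error(cluster_bootstrap(fit2, d2, "subject", B = 50), "B >= 200")
})

test_that("BH adjustment equals the brute-force step-up on small sets", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (m in 1:6) {
    for (rep in 1:50) {
      p <- round(runif(m), 2)
      expect_equal(bh_fdr(p), bh_stepup_bruteforce(p))
    }
  }
})

test_that("slope contrasts reduce correctly with and without interactions", {
  set.seed(32)
  n <- 1500
  d <- data.frame(rate = sample(c(5, 11, 14, 16, 17.5), n, TRUE),
                  mad = rnorm(n, 0, 0.5))
  d$rate_c <- d$rate - mean(d$rate)
  # no interaction: slope identical at every level
  d1 <- gen_behavior(d, behavior_gen_spec(
    c("(Intercept)" = 0.3, rate_c = -0.1, mad = 0.5), precision = 25, seed = 33))
  f1 <- beta_regression_fit(score ~ rate_c + mad, data = d1)
  sc1 <- slope_contrast(f1, "mad", "rate_c", c(-5, 0, 4))
  expect_lt(diff(range(sc1$slopes$slope)), 1e-10)
  expect_lt(max(abs(sc1$differences$difference)), 1e-10)

  # known interaction: recovered slopes near beta_mad + beta_int * level
  d2 <- gen_behavior(d, behavior_gen_spec(
    c("(Intercept)" = 0.3, rate_c = -0.1, mad = 0.5, "rate_c:mad" = -0.08),
    precision = 25, seed = 34))
  f2 <- beta_regression_fit(score ~ rate_c * mad, data = d2)
  lv <- c(-6, 0, 4)
  sc2 <- slope_contrast(f2, "mad", "rate_c", lv)
  expect_true(all(abs(sc2$slopes$slope - (0.5 - 0.08 * lv)) <
                    3 * sc2$slopes$se))
  # contrast of a level with itself is exactly zero
  same <- slope_contrast(f2, "mad", "rate_c", c(2, 2))
  expect_equal(same$differences$difference, 0)
  expect_warning(slope_contrast(f2, "mad", "rate_c", 50), "outside")
})
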