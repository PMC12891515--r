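#' Nudge boundary responses into the open unit interval
#'
#' Responses exactly at 0 or 1 are replaced by `eps` and `1 - eps`, where
#' `eps = median(y) / n` (the full-vector median by default; per-group
#' medians and sizes with `group`). Interior values are unchanged. Required
#' before beta-likelihood fitting, which needs `y` strictly inside `(0, 1)`.
#'
#' @param y numeric vector in `[0, 1]`.
#' @param group optional grouping vector; `eps` is then computed per group.
#' @return vector in `(0, 1)`.
#' @export
boundary_adjust <- function(y, group = NULL) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop_invalid("`y` must lie in [0, 1]")
  adjust <- function(v) {
    eps <- stats::median(v) / length(v)
    if (eps == 0)
      stop_invalid("median(y) is 0: boundary adjustment degenerates to eps = 0")
    v[v == 0] <- eps
    v[v == 1] <- 1 - eps
    v
  }
  if (is.null(group)) return(adjust(y))
  out <- y
  for (idx in split(seq_along(y), group)) out[idx] <- adjust(y[idx])
  out
}

#' Min-max normalization to the unit interval
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`, attaining 0 and 1.
#' @export
minmax_normalize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) stop_invalid("`x` is constant; min-max normalization undefined")
  (x - r[1]) / (r[2] - r[1])
}

#' Orthonormal polynomial basis with a deterministic sign convention
#'
#' Columns span the centred monomials up to `degree` and are mutually
#' orthonormal ([stats::poly()] underneath); each column's sign is fixed so
#' that its projection onto the corresponding raw monomial is positive.
#'
#' @param x numeric vector with at least `degree + 1` distinct values.
#' @param degree polynomial degree (1-3 in typical use).
#' @return n x degree matrix.
#' @export
ortho_poly <- function(x, degree) {
  if (length(unique(x)) < degree + 1)
    stop_invalid("need at least degree + 1 distinct values")
  P <- unclass(stats::poly(x, degree))
  for (j in seq_len(degree)) {
    s <- sign(sum(P[, j] * x^j))
    if (s == 0) s <- sign(P[, j][which(P[, j] != 0)[1]])
    P[, j] <- s * P[, j]
  }
  P[, , drop = FALSE]
}

# Beta log-likelihood and analytic gradient in theta = (beta, log phi).
.beta_ll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[1:p])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.beta_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[1:p])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gp <- sum(digamma(phi) - mu * digamma(mu * phi) -
              (1 - mu) * digamma((1 - mu) * phi) +
              mu * log(y) + (1 - mu) * log1p(-y)) * phi
  c(gb, gp)
}

#' Beta regression with logit link by maximum likelihood
#'
#' Fits `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = x_i' beta` and constant precision `phi`, by BFGS on
#' `(beta, log phi)` with analytic gradient, started from a least-squares fit
#' on the logit-transformed response. A monotone safeguard keeps the starting
#' values if the optimizer fails to improve the likelihood.
#'
#' @param formula model formula; the response must lie strictly in `(0, 1)`
#'   (see [boundary_adjust()]).
#' @param data data frame.
#' @return object of class `beta_fit`: coefficients (logit scale), `phi`,
#'   `vcov` (coefficients + log phi), `logLik`, `pseudo_R2` (squared
#'   correlation of `logit(y)` with the linear predictor), `pseudo_R2_LR`
#'   (likelihood-ratio based), `converged`, `n`, and the model frame for
#'   downstream contrast/bootstrap machinery.
#' @export
beta_regression_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(y <= 0 | y >= 1))
    stop_invalid("response must lie strictly in (0, 1); apply boundary_adjust() first")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("design is rank deficient; collinear column(s): ",
                 paste(drop_cols, collapse = ", "))
  }
  n <- length(y)
  ly <- stats::qlogis(y)
  b0 <- qr.coef(qrX, ly)
  mu0 <- stats::plogis(drop(X %*% b0))
  ve <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(ve, 1e-8) - 1, 1)
  start <- c(b0, log(phi0))
  ll_start <- .beta_ll(start, X, y)
  opt <- stats::optim(start, .beta_ll, .beta_grad, X = X, y = y,
                      method = "BFGS", hessian = TRUE,
                      control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  monotone_ok <- opt$value >= ll_start - 1e-8
  theta <- if (monotone_ok) opt$par else start
  ll <- max(opt$value, ll_start)
  p <- ncol(X)
  V <- tryCatch(solve(-opt$hessian), error = function(e) matrix(NA, p + 1, p + 1))
  coefs <- stats::setNames(theta[1:p], colnames(X))
  eta <- drop(X %*% theta[1:p])
  # intercept-only fit for the likelihood-ratio pseudo-R2
  opt0 <- stats::optim(c(mean(ly), log(phi0)), .beta_ll, .beta_grad,
                       X = matrix(1, n, 1), y = y, method = "BFGS",
                       control = list(fnscale = -1, maxit = 200))
  dimnames(V) <- list(c(colnames(X), "log_phi"), c(colnames(X), "log_phi"))
  structure(list(coefficients = coefs, phi = unname(exp(theta[p + 1])),
                 vcov = V, logLik = ll, logLik_null = opt0$value,
                 pseudo_R2 = if (stats::var(eta) > 0)
                   stats::cor(ly, eta)^2 else 0,
                 pseudo_R2_LR = 1 - exp(-2 / n * (ll - opt0$value)),
                 converged = monotone_ok && opt$convergence == 0 &&
                   all(is.finite(V)),
                 n = n, formula = formula, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 model = mf),
            class = "beta_fit")
}

#' @export
coef.beta_fit <- function(object, ...) object$coefficients

#' @export
vcov.beta_fit <- function(object, ...) {
  p <- length(object$coefficients)
  object$vcov[1:p, 1:p, drop = FALSE]
}

#' @export
logLik.beta_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta regression (logit link), n =", x$n,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("phi = %.2f  logLik = %.2f  pseudo-R2 = %.3f (LR: %.3f)\n",
              x$phi, x$logLik, x$pseudo_R2, x$pseudo_R2_LR))
  invisible(x)
}

#' @export
summary.beta_fit <- function(object, ...) {
  se <- sqrt(diag(vcov(object)))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, fit = object), class = "summary.beta_fit")
}

#' @export
print.summary.beta_fit <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Cluster bootstrap for beta-regression coefficients
#'
#' Resamples clusters (e.g. subjects) with replacement, refits, and reports
#' the bootstrap SD and percentile intervals of every coefficient. This is
#' the supported route to uncertainty that respects within-subject dependence
#' (in place of random-effect estimation).
#'
#' @param fit a `beta_fit`.
#' @param data the data the model was fitted on.
#' @param cluster name of the clustering column in `data` (>= 10 clusters).
#' @param B bootstrap replicates (>= 200).
#' @param seed RNG seed.
#' @param conf confidence level for percentile intervals.
#' @return list with `se`, `ci` (matrix with lower/upper), `replicates`
#'   (B_ok x p matrix), `n_failed`.
#' @export
cluster_bootstrap <- function(fit, data, cluster, B = 500, seed = 1L,
                              conf = 0.95) {
  stopifnot(inherits(fit, "beta_fit"), cluster %in% names(data))
  cl <- data[[cluster]]
  ids <- unique(cl)
  if (length(ids) < 10) stop_invalid("need at least 10 clusters")
  if (B < 200) stop_invalid("need B >= 200 bootstrap replicates")
  rows_by_cluster <- split(seq_len(nrow(data)), cl)
  reps <- local_seed(seed, {
    lapply(seq_len(B), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      d <- data[unlist(rows_by_cluster[as.character(take)], use.names = FALSE), ]
      tryCatch(stats::coef(beta_regression_fit(fit$formula, d)),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  n_failed <- sum(!ok)
  if (n_failed / B > 0.05)
    warning(n_failed, " of ", B, " bootstrap refits failed")
  R <- do.call(rbind, reps[ok])
  a <- (1 - conf) / 2
  list(se = apply(R, 2, stats::sd),
       ci = t(apply(R, 2, stats::quantile, probs = c(a, 1 - a))),
       replicates = R, n_failed = n_failed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; monotone and bounded by 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length/order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Simple slopes of a predictor at chosen moderator levels
#'
#' For a fitted interaction model, computes the slope of `var` at each level
#' of `moderator` (all other covariates held at their in-sample means /
#' reference levels) as an exact linear combination `L beta` of the fitted
#' coefficients, with delta-method SEs and all pairwise slope differences.
#' Percentile CIs can be attached from [cluster_bootstrap()] replicates.
#'
#' @param fit a `beta_fit` containing an interaction with `moderator`.
#' @param var name of the focal (metric) predictor.
#' @param moderator name of the moderating metric predictor.
#' @param levels moderator values at which to evaluate the slope.
#' @param replicates optional bootstrap coefficient matrix
#'   (`cluster_bootstrap()$replicates`) for percentile CIs.
#' @param conf confidence level.
#' @return list with `slopes` (data frame: level, slope, se, lwr, upr) and
#'   `differences` (data frame of pairwise contrasts).
#' @export
slope_contrast <- function(fit, var, moderator, levels, replicates = NULL,
                           conf = 0.95) {
  stopifnot(inherits(fit, "beta_fit"))
  tt <- stats::delete.response(fit$terms)
  mf <- fit$model
  obs_mod <- mf[[moderator]]
  if (!is.null(obs_mod) &&
      (min(levels) < min(obs_mod) || max(levels) > max(obs_mod)))
    warning("moderator level(s) outside the observed range; extrapolating")
  base_row <- lapply(mf, function(col) {
    if (is.numeric(col)) mean(col)
    else if (is.factor(col)) factor(levels(col)[1], levels = levels(col))
    else col[1]
  })
  v0 <- mean(mf[[var]])
  h <- max(stats::sd(mf[[var]]), 1e-6) * 1e-3
  Lrow <- function(level) {
    nd <- as.data.frame(base_row)[rep(1, 2), , drop = FALSE]
    nd[[moderator]] <- level
    nd[[var]] <- c(v0 + h, v0 - h)
    mm <- stats::model.matrix(tt, nd, xlev = fit$xlevels)
    (mm[1, ] - mm[2, ]) / (2 * h)
  }
  L <- t(vapply(levels, Lrow, numeric(length(fit$coefficients))))
  beta <- fit$coefficients
  V <- vcov(fit)
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  slopes <- data.frame(level = levels, slope = est, se = se,
                       lwr = est - zq * se, upr = est + zq * se)
  if (length(levels) < 2) {
    return(list(slopes = slopes,
                differences = data.frame(level_a = numeric(0),
                                         level_b = numeric(0),
                                         difference = numeric(0),
                                         se = numeric(0))))
  }
  pairs <- utils::combn(seq_along(levels), 2)
  diffs <- apply(pairs, 2, function(ij) {
    lc <- L[ij[1], ] - L[ij[2], ]
    d <- sum(lc * beta)
    s <- sqrt(drop(t(lc) %*% V %*% lc))
    c(d, s)
  })
  differences <- data.frame(level_a = levels[pairs[1, ]],
                            level_b = levels[pairs[2, ]],
                            difference = diffs[1, ], se = diffs[2, ],
                            lwr = diffs[1, ] - zq * diffs[2, ],
                            upr = diffs[1, ] + zq * diffs[2, ])
  if (!is.null(replicates)) {
    a <- (1 - conf) / 2
    bs <- replicates %*% t(L)
    slopes$boot_lwr <- apply(bs, 2, stats::quantile, a)
    slopes$boot_upr <- apply(bs, 2, stats::quantile, 1 - a)
    bd <- apply(pairs, 2, function(ij) bs[, ij[1]] - bs[, ij[2]])
    differences$boot_lwr <- apply(bd, 2, stats::quantile, a)
    differences$boot_upr <- apply(bd, 2, stats::quantile, 1 - a)
  }
  list(slopes = slopes, differences = differences)
}
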