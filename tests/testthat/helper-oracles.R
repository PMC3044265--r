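# Independent oracles used to validate the analytic implementations.
# These deliberately take different computational routes from the package
# (brute-force series, explicit projection + numeric integration, Monte
# Carlo, exhaustive pair counting).

# Matrix exponential of -gamma*L by truncated Taylor series (Horner-free,
# term-by-term); adequate for small sparse graphs where ||gamma*L|| is
# moderate.
taylor_expm_neg <- function(L, gamma, n_terms = 20L) {
  n <- nrow(L)
  S <- diag(n)
  P <- diag(n)
  for (k in seq_len(n_terms)) {
    P <- P %*% (-gamma * L) / k
    S <- S + P
  }
  S
}

# Log marginal likelihood by explicit projection onto the orthogonal
# complement of the constant vector and one-dimensional numeric
# integration over log(sigma2). Same dropped-constant convention as the
# package (improper-prior constant omitted), so values are directly
# comparable.
quadrature_log_ml <- function(y, X, sigma_i = 1) {
  m <- length(y)
  Q <- qr.Q(qr(matrix(1, m, 1)), complete = TRUE)[, -1, drop = FALSE]
  yt <- drop(crossprod(Q, y))
  k <- ncol(X) - 1L
  nu <- m - 1L
  if (k > 0L) {
    Xt <- crossprod(Q, X[, -1L, drop = FALSE])
    if (length(sigma_i) == 1L) sigma_i <- rep(sigma_i, k)
    M <- diag(nu) + Xt %*% (sigma_i^2 * t(Xt))
  } else {
    M <- diag(nu)
  }
  Minv <- solve(M)
  ldM <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  a <- drop(t(yt) %*% Minv %*% yt)
  # integrand over t = log(sigma2): N(yt; 0, e^t M) (the 1/sigma2 prior
  # times dsigma2 becomes dt)
  log_f <- function(t) {
    -(nu / 2) * (log(2 * pi) + t) - ldM / 2 - a / (2 * exp(t))
  }
  t_star <- log(a / (nu + 2))  # mode of the integrand
  offset <- log_f(t_star)
  val <- stats::integrate(function(t) exp(log_f(t) - offset),
                          lower = t_star - 60, upper = t_star + 60,
                          rel.tol = 1e-10, subdivisions = 400L)$value
  offset + log(val)
}

# Monte-Carlo estimate of the same integral with a wide lognormal
# proposal for sigma2; returns the estimate and its standard error on the
# log scale.
mc_log_ml <- function(y, X, sigma_i = 1, n_draws = 2e5, seed = 1) {
  m <- length(y)
  Q <- qr.Q(qr(matrix(1, m, 1)), complete = TRUE)[, -1, drop = FALSE]
  yt <- drop(crossprod(Q, y))
  k <- ncol(X) - 1L
  nu <- m - 1L
  if (k > 0L) {
    Xt <- crossprod(Q, X[, -1L, drop = FALSE])
    if (length(sigma_i) == 1L) sigma_i <- rep(sigma_i, k)
    M <- diag(nu) + Xt %*% (sigma_i^2 * t(Xt))
  } else {
    M <- diag(nu)
  }
  Minv <- solve(M)
  ldM <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  a <- drop(t(yt) %*% Minv %*% yt)
  mu <- log(a / (nu + 2))
  sd_p <- 2
  withr::with_seed(seed, {
    t <- stats::rnorm(n_draws, mu, sd_p)
    lw <- -(nu / 2) * (log(2 * pi) + t) - ldM / 2 - a / (2 * exp(t)) -
      stats::dnorm(t, mu, sd_p, log = TRUE)
    c_off <- max(lw)
    w <- exp(lw - c_off)
    est <- c_off + log(mean(w))
    se_log <- stats::sd(w) / (mean(w) * sqrt(n_draws))
    list(est = est, se = se_log)
  })
}

# AUC by exhaustive pair comparison (lower rank ratio = better), ties 1/2.
pair_count_auc <- function(pos, ctl) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p < ctl) + 0.5 * sum(p == ctl)
  wins / (length(pos) * length(ctl))
}
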