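#' Prior for the Bayesian regression model
#'
#' The model is y = X beta + eps with eps ~ N(0, sigma2 I), a conjugate
#' normal prior beta | sigma2 ~ N(0, sigma2 Sigma) with Sigma diagonal,
#' and the scale-reference prior p(sigma2) proportional to 1/sigma2. The
#' intercept coefficient's prior standard deviation sigma0 is taken to
#' +Inf and handled analytically (see [log_marginal_likelihood()]); the
#' remaining coefficients share prior standard deviation `sigma_i`
#' (optionally one value per coefficient). Prior means are zero. This
#' combination makes the Bayes factor invariant to shifting or rescaling
#' the response.
#'
#' @param sigma_i prior standard deviation of each non-intercept
#'   coefficient (scalar, or vector recycled/matched to the non-intercept
#'   columns); default 1
#' @return an object of class `regression_prior`
#' @export
regression_prior <- function(sigma_i = 1) {
  if (!is.numeric(sigma_i) || any(!is.finite(sigma_i)) || any(sigma_i <= 0)) {
    stop("`sigma_i` must be positive and finite")
  }
  structure(list(sigma_i = sigma_i, sigma0 = Inf, beta0 = 0),
            class = "regression_prior")
}

# Validate (y, X), center out the flat-prior intercept, and return the
# pieces every marginal-likelihood computation needs.
prepare_regression <- function(y, X, prior) {
  if (!inherits(prior, "regression_prior")) prior <- do.call(regression_prior, as.list(prior))
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  y <- as.numeric(y)
  m <- length(y)
  if (nrow(X) != m) stop("rows of X must align with entries of y")
  if (ncol(X) < 1L) stop("X must have at least the intercept column")
  if (any(X[, 1L] != 1)) stop("first column of X must be all 1s (intercept)")
  k <- ncol(X) - 1L
  if (m < k + 2L) {
    stop(sprintf("need at least k + 2 = %d observations, got %d", k + 2L, m))
  }
  yc <- y - mean(y)
  ss_null <- sum(yc^2)
  if (ss_null <= 0) stop("constant response: y has zero variance")
  Xc <- X[, -1L, drop = FALSE]
  if (k > 0L) Xc <- sweep(Xc, 2L, colMeans(Xc))
  sigma_i <- prior$sigma_i
  if (k > 0L) {
    if (length(sigma_i) == 1L) sigma_i <- rep(sigma_i, k)
    if (length(sigma_i) != k) stop("length of `sigma_i` does not match the non-intercept columns")
  } else {
    sigma_i <- numeric(0)
  }
  list(yc = yc, Xc = Xc, k = k, nu = m - 1L, ss_null = ss_null, sigma_i = sigma_i)
}

#' Log marginal likelihood of the Bayesian regression model
#'
#' Computes, in closed form and in the log domain, the marginal likelihood
#' of y given X after integrating out the coefficients (conjugate normal
#' prior scaled by sigma2) and the noise variance (reference prior
#' 1/sigma2). The flat intercept prior (sigma0 -> +Inf) is applied
#' analytically: y and the non-intercept columns of X are centered, the
#' intercept is dropped, and m - 1 effective observations remain. With
#' nu = m - 1, M = I + Xc Sigma1 Xc', and a = yc' M^-1 yc, the result is
#'
#'   log Gamma(nu/2) - (nu/2) log(pi * a) - (1/2) log det M ,
#'
#' where the (model-independent) normalizing constant of the improper
#' priors is dropped; it cancels from every Bayes factor. The quadratic
#' form and determinant are evaluated through the Cholesky factor of
#' Sigma1^-1 + Xc'Xc, which is positive definite by construction even for
#' collinear or all-zero design columns, so no columns are ever dropped.
#'
#' @param y numeric response vector (phenotype similarities)
#' @param X design matrix with a leading column of 1s
#' @param prior a [regression_prior()]
#' @return a single number, the log marginal likelihood (up to a constant
#'   shared by all models on the same y)
#' @export
log_marginal_likelihood <- function(y, X, prior = regression_prior()) {
  pr <- prepare_regression(y, X, prior)
  log_ml_prepared(pr)
}

log_ml_prepared <- function(pr) {
  nu <- pr$nu
  if (pr$k == 0L) {
    return(lgamma(nu / 2) - (nu / 2) * log(pi * pr$ss_null))
  }
  A <- crossprod(pr$Xc) + diag(1 / pr$sigma_i^2, pr$k)
  R <- tryCatch(chol(A), error = function(e) stop("design Gram matrix is not positive definite"))
  logdet_M <- 2 * sum(log(diag(R))) + 2 * sum(log(pr$sigma_i))
  b <- crossprod(pr$Xc, pr$yc)
  w <- backsolve(R, forwardsolve(t(R), b))
  a <- pr$ss_null - sum(b * w)
  if (!is.finite(a) || a <= 0) stop("non-finite or non-positive residual quadratic form")
  out <- lgamma(nu / 2) - (nu / 2) * log(pi * a) - logdet_M / 2
  if (!is.finite(out)) stop("non-finite log marginal likelihood")
  out
}

#' Bayes factor of a candidate regression model against the null
#'
#' The alternative model explains y by the full design X; the null model
#' keeps only the intercept. The Bayes factor is the ratio of their
#' marginal likelihoods; values above 1 favour a linear relationship
#' between the phenotype similarities and the gene proximities in X.
#'
#' @inheritParams log_marginal_likelihood
#' @return an object of class `bayes_score`: a list with `log_ml_alt`,
#'   `log_ml_null`, `log_bf` and `bf` (`bf` may overflow to `Inf`; the
#'   log stays finite)
#' @export
bayes_factor <- function(y, X, prior = regression_prior()) {
  pr <- prepare_regression(y, X, prior)
  log_ml_alt <- log_ml_prepared(pr)
  pr_null <- pr
  pr_null$k <- 0L
  log_ml_null <- log_ml_prepared(pr_null)
  log_bf <- log_ml_alt - log_ml_null
  structure(list(log_ml_alt = log_ml_alt, log_ml_null = log_ml_null,
                 log_bf = log_bf, bf = exp(log_bf)),
            class = "bayes_score")
}

#' @export
print.bayes_score <- function(x, ...) {
  cat(sprintf("bayes_score: log BF = %.4f (BF = %.4g)\n", x$log_bf, x$bf))
  invisible(x)
}
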