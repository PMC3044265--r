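as_kernel_list <- function(kernels) {
  if (inherits(kernels, "proximity_matrix")) kernels <- list(kernels)
  if (!is.list(kernels) || length(kernels) == 0L ||
      !all(vapply(kernels, inherits, TRUE, "proximity_matrix"))) {
    stop("`kernels` must be a proximity matrix or a non-empty list of them")
  }
  kernels
}

#' Design matrix for scoring a candidate gene
#'
#' Builds the regression design for a query disease and candidate gene.
#' The model genes are the candidate alone (scheme 1, the "novel disease"
#' assumption) or the candidate together with the disease's known genes
#' (scheme 2). With p model genes and q kernels the design has pq + 1
#' columns: the intercept, then one gene-proximity-vector column per
#' model gene, kernel by kernel (columns 2..p+1 from the first kernel,
#' and so on). Each proximity column is computed with the query disease's
#' gene set overridden by the model genes, so the candidate hypothesis —
#' not the current annotation — defines the query entry.
#'
#' @param disease query disease identifier (must be in the profile)
#' @param candidate candidate gene identifier (need not be in any network)
#' @param kernels a [diffusion_kernel()] or list of them (q kernels)
#' @param profile a [phenotype_profile()]
#' @param assoc an [association_set()]
#' @param scheme 1 (candidate as the disease's only gene) or 2 (candidate
#'   plus known genes)
#' @return list with `y` (response = profile row of the disease) and `X`
#'   (design matrix)
#' @export
build_design <- function(disease, candidate, kernels, profile, assoc, scheme = 1L) {
  kernels <- as_kernel_list(kernels)
  if (!disease %in% profile$diseases) stop(sprintf("unknown disease '%s'", disease))
  scheme <- as.integer(scheme)
  if (!scheme %in% c(1L, 2L)) stop("`scheme` must be 1 or 2")
  model_genes <- if (scheme == 1L) candidate else
    unique(c(candidate, disease_genes(assoc, disease)))
  override <- stats::setNames(list(model_genes), disease)
  cols <- lapply(kernels, function(kern) {
    vapply(model_genes, function(g) {
      gene_proximity_vector(kern, g, profile, assoc, override = override)
    }, numeric(profile$m))
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- NULL
  y <- profile$S[match(disease, profile$diseases), ]
  list(y = as.numeric(y), X = X)
}

#' Bayes-factor score of a candidate gene
#'
#' Scores a candidate gene for a query disease as the log Bayes factor of
#' the regression of the disease's phenotype-similarity vector on the
#' candidate's gene-proximity vectors (one per kernel; see
#' [build_design()]). A candidate absent from every network yields
#' all-zero proximity columns and hence log BF = 0 (no evidence).
#'
#' @inheritParams build_design
#' @param prior a [regression_prior()]
#' @param exclude_self if `TRUE`, drop the query disease's own entry from
#'   the response and design before scoring (sensitivity switch; the
#'   default keeps it, reading "all m diseases" literally)
#' @return the log Bayes factor (a single number)
#' @export
score_candidate_bf <- function(disease, candidate, kernels, profile, assoc,
                               scheme = 1L, prior = regression_prior(),
                               exclude_self = FALSE) {
  d <- build_design(disease, candidate, kernels, profile, assoc, scheme)
  if (exclude_self) {
    i <- match(disease, profile$diseases)
    d$y <- d$y[-i]
    d$X <- d$X[-i, , drop = FALSE]
  }
  bayes_factor(d$y, d$X, prior)$log_bf
}

#' Rank candidate genes for a disease
#'
#' Candidates are ordered by non-increasing score. Rank ratios use
#' average ranks for ties (so a block of tied candidates shares one
#' unbiased rank ratio); the display order breaks ties by gene
#' identifier, which keeps output deterministic.
#'
#' @param disease query disease identifier
#' @param candidates unique character vector of candidate genes
#' @param scorer either a numeric vector of scores aligned with
#'   `candidates`, or a function `f(disease, candidates, assoc)` returning
#'   one
#' @param assoc an [association_set()] passed through to a scorer function
#' @return a data frame of class `ranked_list` with columns `gene`,
#'   `score`, `rank` (average rank, ties shared) and `rank_ratio`
#'   (= rank / number of candidates), ordered for display; attributes
#'   `disease`, `method`
#' @export
rank_candidates <- function(disease, candidates, scorer, assoc = NULL) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) stop("no candidates")
  if (anyDuplicated(candidates)) stop("duplicate candidate genes")
  scores <- if (is.function(scorer)) scorer(disease, candidates, assoc) else as.numeric(scorer)
  if (length(scores) != length(candidates)) stop("scores do not align with candidates")
  rk <- rank(-scores, ties.method = "average")
  out <- data.frame(gene = candidates, score = scores, rank = rk,
                    rank_ratio = rk / length(candidates),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "disease") <- disease
  class(out) <- c("ranked_list", class(out))
  out
}

#' CIPHER gene-gene proximity matrix
#'
#' The CIPHER baseline measures gene proximity by a Gaussian kernel on
#' the unweighted shortest-path distance: w(g, g') = exp(-d^2 /
#' bandwidth), with w = 1 at distance 0 and w = 0 for disconnected pairs.
#'
#' @param net a [ppi_network()]
#' @param bandwidth Gaussian kernel bandwidth (default 1, i.e. exp(-d^2))
#' @return a proximity matrix usable wherever a kernel is expected
#' @export
cipher_proximity <- function(net, bandwidth = 1) {
  g <- as_igraph(net)
  D <- igraph::distances(g)
  D <- D[net$genes, net$genes, drop = FALSE]
  W <- exp(-(D^2) / bandwidth)
  W[is.infinite(D)] <- 0
  proximity_matrix(net$genes, W, kind = "cipher_kernel", bandwidth = bandwidth)
}

#' CIPHER concordance score of a candidate gene
#'
#' The CIPHER baseline scores a candidate by the Pearson correlation
#' between the disease's phenotype-similarity vector and the candidate's
#' gene-proximity vector (scheme-1 style: the query disease's gene set is
#' the candidate alone). Proximity uses the shortest-path Gaussian kernel
#' by default, or the diffusion kernel when `sp_kernel = FALSE`.
#'
#' @inheritParams build_design
#' @param net a [ppi_network()]
#' @param sp_kernel use the shortest-path Gaussian kernel (`TRUE`) or the
#'   diffusion kernel (`FALSE`)
#' @param gamma diffusion magnitude when `sp_kernel = FALSE`
#' @param bandwidth Gaussian bandwidth when `sp_kernel = TRUE`
#' @param exclude_self drop the query disease's own entry before
#'   correlating
#' @return Pearson correlation; 0 (with a warning) when either vector has
#'   zero variance, as happens for candidates with no proximity anywhere
#' @export
cipher_score <- function(disease, candidate, net, profile, assoc,
                         sp_kernel = TRUE, gamma = 0.2, bandwidth = 1,
                         exclude_self = FALSE) {
  kern <- if (sp_kernel) cipher_proximity(net, bandwidth) else diffusion_kernel(net, gamma)
  cipher_score_kernel(disease, candidate, kern, profile, assoc, exclude_self)
}

cipher_score_kernel <- function(disease, candidate, kern, profile, assoc,
                                exclude_self = FALSE) {
  override <- stats::setNames(list(candidate), disease)
  x <- gene_proximity_vector(kern, candidate, profile, assoc, override = override)
  y <- as.numeric(profile$S[match(disease, profile$diseases), ])
  if (exclude_self) {
    i <- match(disease, profile$diseases)
    x <- x[-i]; y <- y[-i]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(sprintf("zero variance when scoring '%s' for '%s'; score set to 0",
                    candidate, disease))
    return(0)
  }
  stats::cor(x, y)
}

#' Ordinary-regression R-squared score of a candidate gene
#'
#' Baseline that fits the same scheme-1 design as the Bayes-factor score
#' by ordinary least squares and returns the coefficient of determination
#' R^2. Collinear or all-zero columns are handled by the minimum-norm
#' least-squares fit (R^2 is invariant to which solution is taken).
#'
#' @inheritParams score_candidate_bf
#' @return R^2 in \[0, 1\]
#' @export
ols_r2_score <- function(disease, candidate, kernels, profile, assoc,
                         exclude_self = FALSE) {
  d <- build_design(disease, candidate, kernels, profile, assoc, scheme = 1L)
  if (exclude_self) {
    i <- match(disease, profile$diseases)
    d$y <- d$y[-i]
    d$X <- d$X[-i, , drop = FALSE]
  }
  y <- d$y
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("constant response: y has zero variance")
  fit <- qr(d$X)
  resid <- qr.resid(fit, y)
  r2 <- 1 - sum(resid^2) / sst
  min(max(r2, 0), 1)
}

#' Scorer factories for ranking and cross-validation
#'
#' A *scorer* is a function `f(disease, candidates, assoc)` returning one
#' numeric score per candidate (higher is better); validation protocols
#' are parameterized by scorers so the Bayes-factor method and the
#' baselines run under identical protocols. `bf_scorer()` scores by log
#' Bayes factor, `cipher_scorer()` by CIPHER correlation (with the
#' shortest-path kernel precomputed once), `ols_scorer()` by ordinary
#' least-squares R^2, and `random_scorer()` by i.i.d. uniform noise (the
#' calibration null).
#'
#' @inheritParams score_candidate_bf
#' @param net a [ppi_network()] (CIPHER is a single-network method)
#' @param sp_kernel,gamma,bandwidth see [cipher_score()]
#' @return a scorer function
#' @export
bf_scorer <- function(kernels, profile, scheme = 1L, prior = regression_prior(),
                      exclude_self = FALSE) {
  kernels <- as_kernel_list(kernels)
  function(disease, candidates, assoc) {
    vapply(candidates, function(g) {
      score_candidate_bf(disease, g, kernels, profile, assoc,
                         scheme = scheme, prior = prior,
                         exclude_self = exclude_self)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' @rdname bf_scorer
#' @export
cipher_scorer <- function(net, profile, sp_kernel = TRUE, gamma = 0.2,
                          bandwidth = 1, exclude_self = FALSE) {
  kern <- if (sp_kernel) cipher_proximity(net, bandwidth) else diffusion_kernel(net, gamma)
  function(disease, candidates, assoc) {
    vapply(candidates, function(g) {
      suppressWarnings(
        cipher_score_kernel(disease, g, kern, profile, assoc, exclude_self)
      )
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' @rdname bf_scorer
#' @export
ols_scorer <- function(kernels, profile, exclude_self = FALSE) {
  kernels <- as_kernel_list(kernels)
  function(disease, candidates, assoc) {
    vapply(candidates, function(g) {
      ols_r2_score(disease, g, kernels, profile, assoc, exclude_self)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' @rdname bf_scorer
#' @export
random_scorer <- function() {
  function(disease, candidates, assoc) stats::runif(length(candidates))
}
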