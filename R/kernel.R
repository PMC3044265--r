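#' Graph Laplacian of a PPI network
#'
#' Returns L = D - A where D is the diagonal matrix of node degrees and A
#' the adjacency matrix. Every row of L sums to zero.
#'
#' @param net a [ppi_network()] with at least one gene
#' @return symmetric numeric matrix with dimnames = genes
#' @export
laplacian <- function(net) {
  if (net$n == 0L) stop("network has no genes")
  A <- adjacency_matrix(net)
  L <- -A
  diag(L) <- rowSums(A)
  L
}

# Shared representation for gene-gene proximity matrices: the diffusion
# kernel and the CIPHER shortest-path kernel both use it, so the proximity
# accessors and x_g construction work on either.
proximity_matrix <- function(genes, Z, kind = "proximity_matrix", ...) {
  dimnames(Z) <- list(genes, genes)
  structure(
    c(list(genes = genes, Z = Z), list(...)),
    class = unique(c(kind, "proximity_matrix"))
  )
}

#' Diffusion kernel of a PPI network
#'
#' Computes Z = exp(-gamma * L), the matrix exponential of the negative
#' scaled graph Laplacian, via symmetric eigendecomposition. Entry z_ij is
#' the proximity of genes i and j: the amount of "heat" that diffuses from
#' i to j. Because L annihilates the constant vector, every row of Z sums
#' to 1; Z is symmetric, nonnegative and positive definite.
#'
#' The result is symmetrized as (Z + t(Z))/2 and entries within round-off
#' of zero are clamped to 0, so the stated invariants hold exactly enough
#' to be asserted.
#'
#' @param net a [ppi_network()]
#' @param gamma diffusion magnitude, dimensionless; the model is intended
#'   for 0 < gamma < 1 (a warning is issued outside this range). Default
#'   0.2.
#' @return an object of class `diffusion_kernel` with elements `genes`,
#'   `Z` and `gamma`
#' @export
diffusion_kernel <- function(net, gamma = 0.2) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    stop("`gamma` must be a single finite nonnegative number")
  }
  if (gamma <= 0 || gamma >= 1) {
    warning(sprintf("gamma = %g is outside the intended range (0, 1)", gamma))
  }
  L <- laplacian(net)
  eg <- eigen(L, symmetric = TRUE)
  Z <- eg$vectors %*% (exp(-gamma * eg$values) * t(eg$vectors))
  Z <- (Z + t(Z)) / 2
  if (!all(is.finite(Z))) stop("diffusion kernel is not finite")
  Z[Z < 0 & Z > -1e-10] <- 0
  if (any(Z < 0)) stop("diffusion kernel has negative entries beyond round-off")
  proximity_matrix(net$genes, Z, kind = "diffusion_kernel", gamma = gamma)
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("%s: %d genes", class(x)[[1L]], length(x$genes)))
  if (!is.null(x$gamma)) cat(sprintf(", gamma = %g", x$gamma))
  cat("\n")
  invisible(x)
}

#' Proximity of two genes
#'
#' Looks up the kernel entry for a gene pair. If either gene is absent
#' from the kernel's network the proximity is 0, the minimum proximity —
#' the convention used when scoring genes against networks that do not
#' cover them.
#'
#' @param kernel a [diffusion_kernel()] (or any proximity matrix)
#' @param g,g2 gene identifiers
#' @return a single nonnegative number
#' @export
proximity <- function(kernel, g, g2) {
  i <- match(g, kernel$genes)
  j <- match(g2, kernel$genes)
  if (is.na(i) || is.na(j)) return(0)
  kernel$Z[i, j]
}

#' Write a kernel to a plain-text cache file
#'
#' The cache is a TSV: a `# gamma=<value>` header line, a header row of
#' gene identifiers, then one row per gene (identifier + proximities).
#'
#' @param kernel a [diffusion_kernel()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_kernel <- function(kernel, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# gamma=%.17g", kernel$gamma %||% NA_real_), con)
  writeLines(paste(c("gene", kernel$genes), collapse = "\t"), con)
  for (i in seq_along(kernel$genes)) {
    writeLines(paste(c(kernel$genes[[i]], sprintf("%.17g", kernel$Z[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a kernel cache written by [write_kernel()]
#' @param path cache file
#' @return a `diffusion_kernel`
#' @export
read_kernel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !startsWith(lines[[1L]], "# gamma="))
    stop(sprintf("not a kernel cache file: %s", path))
  gamma <- as.numeric(sub("# gamma=", "", lines[[1L]], fixed = TRUE))
  hdr <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  genes <- hdr[-1L]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (length(body) != length(genes)) stop("kernel cache is truncated")
  Z <- t(vapply(body, function(tok) as.numeric(tok[-1L]), numeric(length(genes))))
  if (!identical(vapply(body, `[[`, "", 1L), genes)) {
    stop("kernel cache row labels do not match the header")
  }
  proximity_matrix(genes, Z, kind = "diffusion_kernel", gamma = gamma)
}
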