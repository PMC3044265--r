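#' Protein-protein interaction networks
#'
#' A `ppi_network` is a simple undirected graph over gene identifiers:
#' no self-loops, no duplicate edges, and a deterministic (lexicographic)
#' node order. Gene identifiers are opaque, case-sensitive strings; no
#' symbol normalization is attempted. Disconnected networks are allowed.
#'
#' @param edges two-column character matrix or data frame of interactions
#'   (one row per edge, unordered). Self-loops and duplicate pairs are
#'   removed.
#' @param genes optional character vector of additional (possibly isolated)
#'   genes to include beyond the edge endpoints.
#' @return An object of class `ppi_network` with elements `genes` (sorted
#'   character vector), `edges` (two-column character matrix, each row a
#'   sorted pair, rows in lexicographic order) and `n` (node count).
#' @examples
#' net <- ppi_network(cbind(c("a", "b"), c("b", "c")))
#' net$n
#' @export
ppi_network <- function(edges, genes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L) {
    stop("`edges` must be a two-column matrix or data frame")
  }
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- order(lo, hi, method = "radix")
  em <- cbind(lo[ord], hi[ord])
  colnames(em) <- c("gene1", "gene2")
  gs <- sort(unique(c(as.character(genes), em[, 1L], em[, 2L])), method = "radix")
  structure(
    list(genes = gs, edges = em, n = length(gs)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d genes, %d interactions\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a network
#' @param net a [ppi_network()]
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

#' Per-gene degrees
#' @param net a [ppi_network()]
#' @return named integer vector over `net$genes`
#' @export
degree_sequence <- function(net) {
  d <- integer(net$n)
  names(d) <- net$genes
  if (nrow(net$edges) > 0L) {
    tab <- table(factor(c(net$edges[, 1L], net$edges[, 2L]), levels = net$genes))
    d[] <- as.integer(tab)
  }
  d
}

#' Dense adjacency matrix
#' @param net a [ppi_network()]
#' @return symmetric 0/1 matrix with zero diagonal, dimnames = genes
#' @export
adjacency_matrix <- function(net) {
  A <- matrix(0, net$n, net$n, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$genes)
    j <- match(net$edges[, 2L], net$genes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$genes, stringsAsFactors = FALSE)
  )
}

#' Read a PPI network from an edge-list file
#'
#' The file is plain text with one interaction per line: two
#' whitespace/tab-separated gene identifiers (extra columns are ignored).
#' Lines starting with `#` and blank lines are skipped. Duplicate edges
#' (regardless of orientation) and self-interactions are removed.
#'
#' @param path path to the edge-list file
#' @return a [ppi_network()]
#' @export
load_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty edge-list file: %s", path))
  a <- character(0); b <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (nchar(line) == 0L || startsWith(line, "#")) next
    tok <- strsplit(line, "[ \t]+")[[1L]]
    if (length(tok) < 2L) {
      stop(sprintf("malformed edge-list line %d in %s: %s", ln, path, line))
    }
    a <- c(a, tok[[1L]]); b <- c(b, tok[[2L]])
  }
  if (length(a) == 0L) stop(sprintf("no interactions found in %s", path))
  net <- ppi_network(cbind(a, b))
  if (nrow(net$edges) == 0L) {
    stop(sprintf("no interactions left after removing self-loops in %s", path))
  }
  net
}

#' Write a network as a sorted edge list
#' @param net a [ppi_network()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Union of several networks
#'
#' Combines networks by taking the union of their gene sets and the union
#' of their edge sets, forming one large network.
#'
#' @param nets a non-empty list of [ppi_network()] objects
#' @return a [ppi_network()]
#' @export
combine_networks <- function(nets) {
  if (!is.list(nets) || length(nets) == 0L) stop("`nets` must be a non-empty list")
  edges <- do.call(rbind, lapply(nets, function(x) x$edges))
  genes <- unique(unlist(lapply(nets, function(x) x$genes), use.names = FALSE))
  ppi_network(edges, genes = genes)
}

#' High-confidence network from edge support
#'
#' Keeps exactly those interactions that occur in at least `min_support`
#' of the input networks; the gene set is restricted to the endpoints of
#' the kept edges.
#'
#' @param nets list of [ppi_network()] objects
#' @param min_support minimum number of networks an edge must occur in
#' @return a [ppi_network()]
#' @export
high_confidence_network <- function(nets, min_support = 2L) {
  if (!is.list(nets) || length(nets) == 0L) stop("`nets` must be a non-empty list")
  min_support <- as.integer(min_support)
  if (min_support < 1L) stop("`min_support` must be >= 1")
  if (min_support > length(nets)) {
    stop(sprintf("`min_support` (%d) exceeds the number of networks (%d)",
                 min_support, length(nets)))
  }
  keys <- unlist(lapply(nets, function(x) edge_key(x$edges[, 1L], x$edges[, 2L])),
                 use.names = FALSE)
  tab <- table(keys)
  kept <- names(tab)[as.integer(tab) >= min_support]
  if (length(kept) == 0L) {
    return(ppi_network(matrix(character(), ncol = 2L)))
  }
  parts <- do.call(rbind, strsplit(kept, "\t", fixed = TRUE))
  ppi_network(parts)
}

#' Degree-preserving network rewiring
#'
#' Randomizes the edge set by repeated double-edge swaps: two edges
#' (a,b), (c,d) are picked at random and replaced by (a,d), (c,b) (or
#' (a,c), (b,d), chosen at random); swaps that would create a self-loop
#' or a duplicate edge are rejected. Every gene keeps its exact degree,
#' which makes the result a degree-matched null network for permutation
#' tests.
#'
#' @param net a [ppi_network()]
#' @param n_swaps number of attempted swaps (rejected attempts count);
#'   default 10 times the number of edges
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards
#' @return a [ppi_network()] with the same genes and degree sequence
#' @export
degree_preserving_rewire <- function(net, n_swaps = NULL, seed = NULL) {
  n_swaps <- as.integer(n_swaps %||% (10L * nrow(net$edges)))
  if (n_swaps < 0L) stop("`n_swaps` must be >= 0")
  ne <- nrow(net$edges)
  if (n_swaps == 0L || ne < 2L) return(net)
  with_seed(seed, {
    E1 <- net$edges[, 1L]
    E2 <- net$edges[, 2L]
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_len(ne)) assign(edge_key(E1[k], E2[k]), TRUE, envir = seen)
    for (it in seq_len(n_swaps)) {
      idx <- sample.int(ne, 2L)
      a <- E1[idx[1L]]; b <- E2[idx[1L]]
      c_ <- E1[idx[2L]]; d <- E2[idx[2L]]
      if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      # proposal: (a,d) and (c_,b)
      if (a == d || c_ == b) next
      k1 <- edge_key(a, d); k2 <- edge_key(c_, b)
      if (k1 == k2) next
      if (exists(k1, envir = seen, inherits = FALSE) ||
          exists(k2, envir = seen, inherits = FALSE)) next
      rm(list = c(edge_key(a, b), edge_key(c_, d)), envir = seen)
      assign(k1, TRUE, envir = seen)
      assign(k2, TRUE, envir = seen)
      E1[idx[1L]] <- min(a, d); E2[idx[1L]] <- max(a, d)
      E1[idx[2L]] <- min(c_, b); E2[idx[2L]] <- max(c_, b)
    }
    ppi_network(cbind(E1, E2), genes = net$genes)
  })
}
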