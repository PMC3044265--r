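#' Phenotype similarity profile
#'
#' An m x m symmetric matrix of similarity scores between disease
#' phenotypes, with entries in \[0, 1\] and unit diagonal (self-similarity).
#' Row d is the phenotype similarity vector y_d used as the regression
#' response when disease d is the query.
#'
#' @param S square numeric matrix of similarities; dimnames give disease
#'   identifiers (overridden by `diseases` if supplied)
#' @param diseases optional character vector of disease identifiers
#' @return an object of class `phenotype_profile` with elements
#'   `diseases`, `S` and `m`
#' @export
phenotype_profile <- function(S, diseases = NULL) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("`S` must be a square matrix")
  if (!is.numeric(S)) stop("`S` must be numeric")
  diseases <- as.character(diseases %||% rownames(S) %||% seq_len(nrow(S)))
  if (length(diseases) != nrow(S)) stop("disease labels do not match matrix size")
  if (anyDuplicated(diseases)) stop("duplicate disease identifiers")
  if (max(abs(S - t(S))) > 1e-6) stop("similarity matrix is asymmetric beyond 1e-6")
  S <- (S + t(S)) / 2
  if (min(S) < 0 || max(S) > 1) stop("similarity entries must lie in [0, 1]")
  if (any(abs(diag(S) - 1) > 1e-12)) {
    warning("diagonal of the similarity matrix forced to 1")
    diag(S) <- 1
  }
  dimnames(S) <- list(diseases, diseases)
  structure(list(diseases = diseases, S = S, m = nrow(S)),
            class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf("phenotype_profile: %d diseases\n", x$m))
  invisible(x)
}

#' Read a phenotype similarity profile from TSV
#'
#' Expects a header row and a first column both carrying disease
#' identifiers, and a square numeric body.
#'
#' @param path TSV file
#' @return a [phenotype_profile()]
#' @export
load_phenotype_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  diseases <- as.character(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(body)) stop(sprintf("non-numeric similarity entries in %s", path))
  if (nrow(body) != ncol(body)) stop(sprintf("similarity matrix in %s is not square", path))
  if (!identical(colnames(body), diseases)) {
    stop(sprintf("row and column disease labels differ in %s", path))
  }
  phenotype_profile(body, diseases = diseases)
}

#' Write a phenotype profile as TSV
#' @param profile a [phenotype_profile()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_phenotype_profile <- function(profile, path) {
  df <- data.frame(disease = profile$diseases,
                   profile$S, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Disease-gene association set
#'
#' Holds the known associations as a set of (disease, gene) pairs together
#' with the map G(d) from each disease to its associated gene set.
#'
#' @param disease,gene character vectors of equal length (one association
#'   per element); duplicates are dropped
#' @return an object of class `association_set` with elements `pairs`
#'   (data frame, sorted) and `G` (named list of character vectors)
#' @export
association_set <- function(disease, gene) {
  disease <- as.character(disease)
  gene <- as.character(gene)
  if (length(disease) != length(gene)) stop("`disease` and `gene` lengths differ")
  key <- paste(disease, gene, sep = "\t")
  keep <- !duplicated(key)
  disease <- disease[keep]; gene <- gene[keep]
  ord <- order(disease, gene, method = "radix")
  pairs <- data.frame(disease = disease[ord], gene = gene[ord],
                      stringsAsFactors = FALSE)
  G <- split(pairs$gene, pairs$disease)
  structure(list(pairs = pairs, G = G), class = "association_set")
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("association_set: %d associations, %d diseases, %d genes\n",
              nrow(x$pairs), length(x$G), length(unique(x$pairs$gene))))
  invisible(x)
}

#' Genes associated with a disease
#' @param assoc an [association_set()]
#' @param disease a disease identifier
#' @return character vector (empty if the disease has no known genes)
#' @export
disease_genes <- function(assoc, disease) {
  assoc$G[[disease]] %||% character(0)
}

# Remove a single (disease, gene) pair; used to hold associations out
# during cross-validation so they cannot leak into any proximity vector.
drop_association <- function(assoc, disease, gene) {
  keep <- !(assoc$pairs$disease == disease & assoc$pairs$gene == gene)
  association_set(assoc$pairs$disease[keep], assoc$pairs$gene[keep])
}

#' Read disease-gene associations from a two-column TSV
#'
#' Pairs whose disease is absent from `profile` are dropped with a
#' warning. Genes need not appear in any network: candidates missing from
#' a network are scored through the zero-proximity convention.
#'
#' @param path two-column text file (disease, gene); `#` comments ignored
#' @param profile optional [phenotype_profile()] used to filter diseases
#' @param networks optional list of [ppi_network()]s, used only to report
#'   how many associated genes no network covers
#' @return an [association_set()]
#' @export
load_associations <- function(path, profile = NULL, networks = NULL) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("disease", "gene"),
                          colClasses = "character")
  if (nrow(df) == 0L) stop(sprintf("no associations in %s", path))
  if (!is.null(profile)) {
    known <- df$disease %in% profile$diseases
    if (any(!known)) {
      warning(sprintf("dropped %d association(s) with diseases absent from the profile",
                      sum(!known)))
    }
    df <- df[known, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no associations left after filtering against the profile")
  assoc <- association_set(df$disease, df$gene)
  if (!is.null(networks)) {
    covered <- unique(unlist(lapply(networks, function(x) x$genes), use.names = FALSE))
    n_out <- sum(!(unique(assoc$pairs$gene) %in% covered))
    if (n_out > 0L) {
      message(sprintf("%d associated gene(s) are absent from every supplied network", n_out))
    }
  }
  assoc
}

#' Write associations as a two-column TSV
#' @param assoc an [association_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_associations <- function(assoc, path) {
  utils::write.table(assoc$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Proximity between a gene and a disease
#'
#' The gene-disease proximity is the sum of kernel proximities between
#' gene `g` and every gene in `genes_d` (typically G(d), the genes known
#' to be associated with a disease). An empty set gives 0, as do genes
#' absent from the kernel's network.
#'
#' @param kernel a [diffusion_kernel()] (or other proximity matrix)
#' @param g gene identifier
#' @param genes_d character vector of genes
#' @return a single nonnegative number
#' @export
gene_disease_proximity <- function(kernel, g, genes_d) {
  if (length(genes_d) == 0L) return(0)
  i <- match(g, kernel$genes)
  if (is.na(i)) return(0)
  j <- match(genes_d, kernel$genes)
  j <- j[!is.na(j)]
  if (length(j) == 0L) return(0)
  sum(kernel$Z[i, j])
}

#' Gene proximity vector over all diseases
#'
#' Builds x_g: for each disease d in the profile (in profile order), the
#' summed proximity between gene `g` and the disease's gene set G(d).
#' Diseases with no known genes contribute a structural zero. An
#' `override` replaces G(d) for selected diseases — this is how a query
#' disease's gene set is replaced by the model genes when scoring a
#' candidate.
#'
#' @param kernel a [diffusion_kernel()] (or other proximity matrix)
#' @param g gene identifier
#' @param profile a [phenotype_profile()]
#' @param assoc an [association_set()]
#' @param override optional named list mapping disease identifiers to the
#'   gene sets to use in place of G(d)
#' @return numeric vector of length `profile$m`, named by disease
#' @export
gene_proximity_vector <- function(kernel, g, profile, assoc, override = NULL) {
  sets <- assoc$G[profile$diseases]
  names(sets) <- profile$diseases
  sets[vapply(sets, is.null, TRUE)] <- list(character(0))
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override)))) {
      stop("`override` must be a named list of disease -> gene sets")
    }
    for (d in names(override)) {
      if (!d %in% profile$diseases) stop(sprintf("override disease '%s' not in profile", d))
      sets[[d]] <- as.character(override[[d]])
    }
  }
  x <- numeric(profile$m)
  names(x) <- profile$diseases
  gi <- match(g, kernel$genes)
  if (is.na(gi)) return(x)
  lens <- lengths(sets)
  if (sum(lens) == 0L) return(x)
  all_genes <- unlist(sets, use.names = FALSE)
  pos <- match(all_genes, kernel$genes)
  zrow <- kernel$Z[gi, ]
  vals <- ifelse(is.na(pos), 0, zrow[ifelse(is.na(pos), 1L, pos)])
  grp <- rep.int(seq_along(sets), lens)
  sums <- rowsum(vals, grp)
  x[as.integer(rownames(sums))] <- sums[, 1L]
  x
}
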