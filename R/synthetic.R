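#' Random network generator
#'
#' Builds a simple undirected network from either an Erdos-Renyi model
#' (each gene pair is an edge independently with probability
#' `density_param`) or a preferential-attachment model (start from a
#' clique on `density_param + 1` nodes; each new node attaches
#' `density_param` edges to distinct existing nodes with probability
#' proportional to degree, giving the heavy-tailed degree distribution
#' typical of PPI networks). The preferential-attachment edge count is
#' exactly `choose(m + 1, 2) + m * (n - m - 1)` with `m = density_param`.
#'
#' @param n_genes number of genes (>= 2)
#' @param model `"erdos_renyi"` or `"preferential_attachment"`
#' @param density_param edge probability (ER) or edges per new node (PA)
#' @param seed integer seed; the global RNG state is restored afterwards
#' @param gene_prefix prefix for generated gene identifiers
#' @return a [ppi_network()]
#' @export
make_network <- function(n_genes, model = c("erdos_renyi", "preferential_attachment"),
                         density_param, seed = NULL, gene_prefix = "g") {
  model <- match.arg(model)
  n_genes <- as.integer(n_genes)
  if (n_genes < 2L) stop("`n_genes` must be >= 2")
  width <- max(4L, nchar(as.character(n_genes)))
  genes <- sprintf(paste0(gene_prefix, "%0", width, "d"), seq_len(n_genes))
  with_seed(seed, {
    if (model == "erdos_renyi") {
      p <- density_param
      if (p < 0 || p > 1) stop("Erdos-Renyi `density_param` must be in [0, 1]")
      npairs <- n_genes * (n_genes - 1L) / 2
      if (p * npairs < 1) warning("expected edge count below 1; network may be empty")
      i <- rep.int(seq_len(n_genes - 1L), (n_genes - 1L):1L)
      j <- sequence((n_genes - 1L):1L) + i
      hit <- stats::runif(npairs) < p
      ppi_network(cbind(genes[i[hit]], genes[j[hit]]), genes = genes)
    } else {
      m <- as.integer(density_param)
      if (m < 1L || m + 1L > n_genes) stop("preferential-attachment `density_param` must satisfy 1 <= m < n_genes")
      deg <- integer(n_genes)
      e1 <- integer(0); e2 <- integer(0)
      core <- utils::combn(m + 1L, 2L)
      e1 <- core[1L, ]; e2 <- core[2L, ]
      deg[seq_len(m + 1L)] <- m
      for (v in (m + 2L):n_genes) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing])
        e1 <- c(e1, rep.int(v, m)); e2 <- c(e2, targets)
        deg[v] <- m
        deg[targets] <- deg[targets] + 1L
      }
      ppi_network(cbind(genes[e1], genes[e2]), genes = genes)
    }
  })
}

#' Default parameters for a synthetic scenario
#'
#' The defaults define the standard benchmark conditions: 500 genes, 120
#' diseases with 1-3 associated genes each, three networks (the full
#' "truth" network plus two corrupted partial copies sharing 60% of the
#' genes), a planted linear phenotype-similarity signal with unit
#' coefficient and Gaussian noise of standard deviation 0.1, and a
#' 5-chromosome synthetic genome for linkage-interval controls.
#'
#' @param n_genes number of genes
#' @param n_diseases number of diseases
#' @param n_networks number of networks q (the first is the uncorrupted
#'   truth network)
#' @param overlap fraction of the truth genes each additional network
#'   covers
#' @param genes_per_disease integer range `c(min, max)` of associated
#'   genes per disease
#' @param n_modules number of disease modules — network neighbourhoods
#'   that act as disease families, so that several diseases draw their
#'   genes from the same functionally related gene group (`NULL`:
#'   `n_diseases / 4`)
#' @param module_size number of genes per module (the module seed gene
#'   plus its nearest kernel neighbours)
#' @param signal_a baseline similarity added to every disease pair
#' @param signal_b coefficient of the planted linear signal
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   similarities
#' @param network_model,density_param truth-network generator (see
#'   [make_network()]); `density_param = NULL` picks an Erdos-Renyi
#'   probability giving mean degree 6
#' @param corruption fraction of edges targeted by degree-preserving
#'   rewiring in each non-truth network copy
#' @param gamma diffusion magnitude of the truth kernel the signal is
#'   planted with
#' @param n_chromosomes,chrom_length_bp synthetic genome layout for the
#'   coordinate table
#' @param seed integer seed; regeneration with identical parameters and
#'   seed is bitwise reproducible
#' @return a named list of parameters
#' @export
scenario_params <- function(n_genes = 500L, n_diseases = 120L, n_networks = 3L,
                            overlap = 0.6, genes_per_disease = c(1L, 3L),
                            n_modules = NULL, module_size = 5L,
                            signal_a = 0.2, signal_b = 1, noise_sd = 0.1,
                            network_model = "erdos_renyi", density_param = NULL,
                            corruption = 0.1, gamma = 0.2,
                            n_chromosomes = 5L, chrom_length_bp = 5e7,
                            seed = 1L) {
  list(n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
       n_networks = as.integer(n_networks), overlap = overlap,
       genes_per_disease = as.integer(genes_per_disease),
       n_modules = if (!is.null(n_modules)) as.integer(n_modules),
       module_size = as.integer(module_size),
       signal_a = signal_a, signal_b = signal_b, noise_sd = noise_sd,
       network_model = network_model, density_param = density_param,
       corruption = corruption, gamma = gamma,
       n_chromosomes = as.integer(n_chromosomes),
       chrom_length_bp = chrom_length_bp, seed = as.integer(seed))
}

#' Generate a synthetic prioritization scenario
#'
#' Emulates the four inputs of a disease-gene prioritization study with a
#' planted linear signal — the structure the method assumes: (1) a truth
#' PPI network plus `n_networks - 1` partially overlapping,
#' degree-preservingly corrupted copies; (2) each disease assigned a
#' small set of associated genes; (3) a phenotype similarity matrix built
#' as `signal_a + signal_b * (summed truth-kernel cross-proximity of the
#' two diseases' gene sets) + N(0, noise_sd)`, symmetrized, diagonal set
#' to 1, clipped to \[0, 1\]; (4) uniform gene coordinates on synthetic
#' chromosomes. The planted associations are recorded as `truth`.
#'
#' @param params a [scenario_params()] list
#' @return an object of class `synthetic_scenario` with elements
#'   `networks` (list of [ppi_network()]; the first is the truth
#'   network), `profile`, `assoc`, `coords`, `truth` (data frame of
#'   planted pairs) and `params`
#' @export
make_scenario <- function(params = scenario_params()) {
  p <- params
  if (max(p$genes_per_disease) > p$n_genes) {
    stop("`genes_per_disease` exceeds the number of genes")
  }
  dens <- p$density_param %||%
    (if (p$network_model == "erdos_renyi") 6 / (p$n_genes - 1) else 3L)
  with_seed(p$seed, {
    truth_net <- make_network(p$n_genes, model = p$network_model,
                              density_param = dens)
    genes <- truth_net$genes
    networks <- vector("list", p$n_networks)
    # networks carry edge-endpoint genes only, so they round-trip through
    # plain edge-list files; the master gene list keeps isolated genes for
    # associations and coordinates
    networks[[1L]] <- ppi_network(truth_net$edges)
    if (p$n_networks > 1L) {
      for (j in 2:p$n_networks) {
        sub_genes <- sort(sample(genes, round(p$overlap * p$n_genes)))
        keep <- truth_net$edges[, 1L] %in% sub_genes &
          truth_net$edges[, 2L] %in% sub_genes
        sub <- ppi_network(truth_net$edges[keep, , drop = FALSE])
        networks[[j]] <- degree_preserving_rewire(
          sub, n_swaps = round(p$corruption * nrow(sub$edges)))
      }
    }
    dwidth <- max(4L, nchar(as.character(p$n_diseases)))
    diseases <- sprintf(paste0("d%0", dwidth, "d"), seq_len(p$n_diseases))
    kern <- diffusion_kernel(truth_net, p$gamma)

    # Disease modules: each is a seed gene plus its nearest kernel
    # neighbours; diseases in the same module draw their genes from that
    # shared neighbourhood, so phenotypically similar diseases carry
    # network-proximal genes — the structure the method assumes.
    n_modules <- p$n_modules %||% max(1L, round(p$n_diseases / 4))
    seed_pool <- networks[[1L]]$genes  # non-isolated genes
    seeds <- sample(seed_pool, min(n_modules, length(seed_pool)))
    modules <- lapply(seeds, function(s) {
      i <- match(s, kern$genes)
      nb <- order(kern$Z[i, ], decreasing = TRUE)
      kern$genes[nb[seq_len(min(p$module_size, length(nb)))]]
    })
    sizes <- sample(seq(p$genes_per_disease[[1L]], p$genes_per_disease[[2L]]),
                    p$n_diseases, replace = TRUE)
    memb <- sample.int(length(modules), p$n_diseases, replace = TRUE)
    gsets <- lapply(seq_len(p$n_diseases), function(d) {
      pool <- modules[[memb[[d]]]]
      sort(sample(pool, min(sizes[[d]], length(pool))))
    })
    sizes <- lengths(gsets)
    assoc <- association_set(rep(diseases, sizes), unlist(gsets))
    Mind <- matrix(0, p$n_genes, p$n_diseases)
    for (d in seq_len(p$n_diseases)) {
      Mind[match(gsets[[d]], genes), d] <- 1
    }
    S0 <- crossprod(Mind, kern$Z %*% Mind)
    noise <- matrix(0, p$n_diseases, p$n_diseases)
    up <- upper.tri(noise)
    noise[up] <- stats::rnorm(sum(up), 0, p$noise_sd)
    noise <- noise + t(noise)
    S <- p$signal_a + p$signal_b * S0 + noise
    S <- (S + t(S)) / 2
    S[S < 0] <- 0
    S[S > 1] <- 1
    diag(S) <- 1
    profile <- phenotype_profile(S, diseases = diseases)

    coords <- data.frame(
      chrom = paste0("chr", sample.int(p$n_chromosomes, p$n_genes, replace = TRUE)),
      start = sample.int(p$chrom_length_bp, p$n_genes, replace = TRUE),
      gene = genes,
      stringsAsFactors = FALSE
    )
    coords$end <- coords$start + 1L
    coords <- coords[, c("chrom", "start", "end", "gene")]

    structure(
      list(networks = networks, profile = profile, assoc = assoc,
           coords = coords, truth = assoc$pairs, params = p),
      class = "synthetic_scenario"
    )
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("synthetic_scenario: %d genes, %d diseases, %d networks, %d planted associations\n",
              x$params$n_genes, x$params$n_diseases, length(x$networks),
              nrow(x$truth)))
  invisible(x)
}

#' Write a scenario to a directory of plain-text files
#'
#' Emits `network_<i>.tsv` edge lists, `profile.tsv`, `associations.tsv`,
#' `coords.bed`, `truth.tsv` and `params.json`.
#'
#' @param scenario a [make_scenario()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(scenario$networks)) {
    write_network(scenario$networks[[i]],
                  file.path(dir, sprintf("network_%d.tsv", i)))
  }
  write_phenotype_profile(scenario$profile, file.path(dir, "profile.tsv"))
  write_associations(scenario$assoc, file.path(dir, "associations.tsv"))
  utils::write.table(scenario$coords, file.path(dir, "coords.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(scenario$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(scenario$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a scenario directory written by [write_scenario()]
#' @param dir scenario directory
#' @return a `synthetic_scenario` (with `truth` read back from file)
#' @export
read_scenario <- function(dir) {
  nets <- list()
  i <- 1L
  repeat {
    path <- file.path(dir, sprintf("network_%d.tsv", i))
    if (!file.exists(path)) break
    nets[[i]] <- load_network(path)
    i <- i + 1L
  }
  if (length(nets) == 0L) stop(sprintf("no network files in %s", dir))
  profile <- load_phenotype_profile(file.path(dir, "profile.tsv"))
  assoc <- load_associations(file.path(dir, "associations.tsv"), profile = profile)
  coords <- load_gene_coords(file.path(dir, "coords.bed"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("disease", "gene"), colClasses = "character")
  } else NULL
  params_path <- file.path(dir, "params.json")
  params <- if (file.exists(params_path)) jsonlite::read_json(params_path, simplifyVector = TRUE) else NULL
  structure(
    list(networks = nets, profile = profile, assoc = assoc, coords = coords,
         truth = truth, params = params),
    class = "synthetic_scenario"
  )
}
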