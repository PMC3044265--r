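# Shared fixtures built in code.

path_graph <- function(genes = c("a", "b", "c", "d")) {
  ppi_network(cbind(genes[-length(genes)], genes[-1]))
}

triangle_graph <- function() ppi_network(cbind(c("a", "b", "c"), c("b", "c", "a")))

# Small random simple graph, deterministic given seed.
random_graph <- function(n, p = 0.1, seed = 1) {
  net <- suppressWarnings(
    make_network(n, model = "erdos_renyi", density_param = p, seed = seed))
  if (nrow(net$edges) == 0L) {
    net <- ppi_network(rbind(net$edges, net$genes[1:2]), genes = net$genes)
  }
  net
}

# A tiny handmade prioritization problem: 4-gene path graph, 5 diseases.
toy_problem <- function() {
  net <- path_graph()
  kern <- diffusion_kernel(net, 0.2)
  S <- matrix(c(1.0, 0.6, 0.2, 0.1, 0.4,
                0.6, 1.0, 0.3, 0.2, 0.1,
                0.2, 0.3, 1.0, 0.5, 0.3,
                0.1, 0.2, 0.5, 1.0, 0.2,
                0.4, 0.1, 0.3, 0.2, 1.0), 5, 5,
              dimnames = rep(list(paste0("d", 1:5)), 2))
  profile <- phenotype_profile(S)
  assoc <- association_set(c("d1", "d1", "d2", "d3", "d4"),
                           c("a", "b", "b", "d", "c"))
  list(net = net, kern = kern, profile = profile, assoc = assoc)
}

# Reduced-scale planted scenario for fast end-to-end tests.
small_scenario <- function(seed = 1, ...) {
  make_scenario(scenario_params(n_genes = 150L, n_diseases = 40L,
                                seed = seed, ...))
}

scenario_universe <- function(scn) {
  unique(unlist(lapply(scn$networks, function(x) x$genes), use.names = FALSE))
}

# Scorer that knows the truth: ranks the held-out gene first. The held-out
# gene is recoverable as a candidate that the full truth lists for the
# disease but the (held-out) association set no longer does.
oracle_scorer <- function(truth_assoc) {
  function(disease, candidates, assoc) {
    known_now <- disease_genes(assoc, disease)
    truth <- disease_genes(truth_assoc, disease)
    as.numeric(candidates %in% setdiff(truth, known_now))
  }
}
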