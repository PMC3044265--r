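new_validation_result <- function(records, control_rank_ratios, protocol, seed,
                                  n_skipped = 0L, n_missing_coords = 0L) {
  mrr <- mean(records$rank_ratio)
  roc <- roc_auc(records$rank_ratio, control_rank_ratios)
  structure(
    list(records = records,
         control_rank_ratios = control_rank_ratios,
         mean_rank_ratio = mrr,
         auc = roc$auc,
         roc_points = roc$points,
         protocol = protocol,
         seed = seed,
         n_skipped = n_skipped,
         n_missing_coords = n_missing_coords),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation_result (%s): %d associations, mean rank ratio %.4f, AUC %.4f\n",
              x$protocol, nrow(x$records), x$mean_rank_ratio, x$auc))
  if (x$n_skipped > 0L) cat(sprintf("  %d association(s) skipped\n", x$n_skipped))
  invisible(x)
}

#' ROC curve and AUC from rank ratios
#'
#' Sweeps a threshold over the pooled rank ratios (lower = better).
#' Sensitivity is the fraction of disease genes at or below the
#' threshold; specificity is the fraction of control genes above it. AUC
#' is the trapezoid area under the resulting curve, which equals the
#' Mann-Whitney statistic with ties counted 1/2.
#'
#' @param positive_rank_ratios rank ratios of the held-out disease genes
#' @param control_rank_ratios rank ratios of the control genes
#' @return list with `auc` and `points` (data frame with columns `fpr` =
#'   1 - specificity and `tpr` = sensitivity)
#' @export
roc_auc <- function(positive_rank_ratios, control_rank_ratios) {
  pos <- as.numeric(positive_rank_ratios)
  ctl <- as.numeric(control_rank_ratios)
  if (length(pos) == 0L || length(ctl) == 0L) {
    stop("both positive and control rank-ratio lists must be nonempty")
  }
  thr <- sort(unique(c(pos, ctl)))
  tpr <- c(0, vapply(thr, function(t) mean(pos <= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(ctl <= t), numeric(1)))
  if (utils::tail(fpr, 1L) < 1 || utils::tail(tpr, 1L) < 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Leave-one-out cross-validation against random controls
#'
#' For every known (disease, gene) association: the association is
#' removed from the association set (so it cannot leak into any proximity
#' vector), `n_controls` control genes are drawn without replacement from
#' `universe` minus the disease's known genes, the held-out gene is
#' ranked among the controls under the supplied scorer, and its rank
#' ratio is recorded. The aggregate mean rank ratio and ROC/AUC (held-out
#' genes versus controls) summarize performance.
#'
#' @param profile a [phenotype_profile()]
#' @param assoc an [association_set()]
#' @param scorer a scorer function (see [bf_scorer()])
#' @param universe character vector of genes controls are drawn from
#'   (typically the union of genes in the supplied networks)
#' @param n_controls number of random controls per association (default
#'   99, so each ranking list has 100 candidates)
#' @param seed integer seed; results are bitwise reproducible given it
#' @param n_repeats number of independent repetitions of the whole
#'   protocol (control sets redrawn with per-repeat seeds `seed`,
#'   `seed + 1`, ...); records are pooled before aggregation
#' @return a `validation_result`
#' @export
loocv_random_controls <- function(profile, assoc, scorer, universe,
                                  n_controls = 99L, seed = 1L,
                                  n_repeats = 1L) {
  n_repeats <- as.integer(n_repeats)
  if (n_repeats > 1L) {
    runs <- lapply(seq_len(n_repeats) - 1L, function(r) {
      loocv_random_controls(profile, assoc, scorer, universe,
                            n_controls = n_controls, seed = seed + r)
    })
    return(new_validation_result(
      do.call(rbind, lapply(runs, `[[`, "records")),
      unlist(lapply(runs, `[[`, "control_rank_ratios")),
      protocol = "random_controls", seed = seed))
  }
  universe <- unique(as.character(universe))
  n_controls <- as.integer(n_controls)
  pairs <- assoc$pairs
  with_seed(seed, {
    recs <- vector("list", nrow(pairs))
    ctl_rr <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      d <- pairs$disease[[i]]; g <- pairs$gene[[i]]
      pool <- setdiff(universe, disease_genes(assoc, d))
      if (length(pool) < n_controls) {
        stop(sprintf("control pool for disease '%s' has %d genes; %d needed",
                     d, length(pool), n_controls))
      }
      controls <- sample(pool, n_controls)
      held_out <- drop_association(assoc, d, g)
      rl <- rank_candidates(d, c(g, controls), scorer, held_out)
      rr <- rl$rank_ratio[match(c(g, controls), rl$gene)]
      recs[[i]] <- data.frame(disease = d, gene = g,
                              n_candidates = n_controls + 1L,
                              rank = rl$rank[match(g, rl$gene)],
                              rank_ratio = rr[[1L]],
                              stringsAsFactors = FALSE)
      ctl_rr[[i]] <- rr[-1L]
    }
    new_validation_result(do.call(rbind, recs), unlist(ctl_rr),
                          protocol = "random_controls", seed = seed)
  })
}

#' Read gene coordinates from a BED-like file
#'
#' Four whitespace-separated columns: chromosome, start, end, gene
#' (0-based half-open intervals); `#` comments ignored.
#'
#' @param path input file
#' @return data frame with columns `chrom`, `start`, `end`, `gene`
#' @export
load_gene_coords <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene"))
  if (nrow(df) == 0L) stop(sprintf("no coordinates in %s", path))
  df$chrom <- as.character(df$chrom)
  df$gene <- as.character(df$gene)
  df
}

#' Leave-one-out cross-validation against simulated linkage intervals
#'
#' Mimics positional cloning: the held-out gene is ranked against the
#' genes lying within `window_bp` upstream or downstream of it on the
#' same chromosome (anchored at gene starts), excluding the disease's
#' known genes. Associations whose gene lacks coordinates, or whose
#' interval contains no control genes, are skipped and counted.
#'
#' @inheritParams loocv_random_controls
#' @param coords data frame of gene coordinates (see
#'   [load_gene_coords()])
#' @param window_bp half-width of the linkage interval in base pairs
#'   (default 10 Mbp each side)
#' @return a `validation_result`
#' @export
loocv_linkage_interval <- function(profile, assoc, scorer, coords,
                                   window_bp = 10000000) {
  if (is.null(coords) || nrow(coords) == 0L) stop("`coords` is empty")
  pairs <- assoc$pairs
  pos <- stats::setNames(coords$start, coords$gene)
  chrom <- stats::setNames(coords$chrom, coords$gene)
  recs <- list(); ctl_rr <- list()
  n_skipped <- 0L; n_missing <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$disease[[i]]; g <- pairs$gene[[i]]
    if (!g %in% coords$gene) {
      n_missing <- n_missing + 1L
      n_skipped <- n_skipped + 1L
      next
    }
    same <- coords$gene[coords$chrom == chrom[[g]] &
                          abs(coords$start - pos[[g]]) <= window_bp]
    controls <- setdiff(same, c(g, disease_genes(assoc, d)))
    if (length(controls) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    held_out <- drop_association(assoc, d, g)
    rl <- rank_candidates(d, c(g, controls), scorer, held_out)
    rr <- rl$rank_ratio[match(c(g, controls), rl$gene)]
    recs[[length(recs) + 1L]] <-
      data.frame(disease = d, gene = g,
                 n_candidates = length(controls) + 1L,
                 rank = rl$rank[match(g, rl$gene)],
                 rank_ratio = rr[[1L]],
                 stringsAsFactors = FALSE)
    ctl_rr[[length(ctl_rr) + 1L]] <- rr[-1L]
  }
  if (length(recs) == 0L) stop("every association was skipped (no controls in any interval)")
  res <- new_validation_result(do.call(rbind, recs), unlist(ctl_rr),
                               protocol = "linkage_interval", seed = NA_integer_,
                               n_skipped = n_skipped, n_missing_coords = n_missing)
  res
}

permutation_modes <- c("original", "permute_pps", "permute_assoc",
                       "random_seed_genes", "permute_ppi")

#' Permutation null suite for the linearity assumption
#'
#' Computes the scheme-1 Bayes factor of every known (disease, gene)
#' association under the original data and under permutations that break,
#' respectively, disease-disease structure (`permute_pps`: one random
#' relabeling applied jointly to rows and columns of the similarity
#' matrix, which keeps it a valid symmetric profile), disease-gene
#' structure (`permute_assoc`: shuffle the gene column of the association
#' table; `random_seed_genes`: replace each associated gene by a uniform
#' draw from the network's genes), and gene-gene structure
#' (`permute_ppi`: degree-preserving rewiring of the network followed by
#' kernel recomputation). If the original data carry the assumed linear
#' signal, original Bayes factors should stochastically exceed 1 and
#' every permuted mode's.
#'
#' @param profile a [phenotype_profile()]
#' @param assoc an [association_set()]
#' @param net a [ppi_network()]
#' @param gamma diffusion magnitude for the kernel
#' @param modes subset of `c("original", "permute_pps", "permute_assoc",
#'   "random_seed_genes", "permute_ppi")`
#' @param n_perm permutation replicates per non-original mode (`0` keeps
#'   only the original mode)
#' @param seed integer seed
#' @param holdout remove each association from the association set before
#'   scoring it (under scheme 1 this does not change the score of the
#'   pair itself, because the query disease's gene set is overridden by
#'   the candidate; the flag is provided for protocol symmetry)
#' @param prior a [regression_prior()]
#' @return list with `samples` (named list of log-BF vectors per mode),
#'   `median_bf` (named vector of per-mode median Bayes factors),
#'   `wilcoxon` (one-sided signed-rank test of the original log BFs
#'   against 0; exact for n <= 25), `seed`
#' @export
permutation_suite <- function(profile, assoc, net, gamma = 0.2,
                              modes = permutation_modes, n_perm = 1L,
                              seed = 1L, holdout = FALSE,
                              prior = regression_prior()) {
  bad <- setdiff(modes, permutation_modes)
  if (length(bad) > 0L) stop(sprintf("unknown permutation mode(s): %s",
                                     paste(bad, collapse = ", ")))
  n_perm <- as.integer(n_perm)
  if (n_perm == 0L) modes <- intersect(modes, "original")
  kern0 <- diffusion_kernel(net, gamma)

  score_all <- function(kern, prof, asc) {
    vapply(seq_len(nrow(asc$pairs)), function(i) {
      d <- asc$pairs$disease[[i]]; g <- asc$pairs$gene[[i]]
      asc_i <- if (holdout) drop_association(asc, d, g) else asc
      score_candidate_bf(d, g, kern, prof, asc_i, scheme = 1L, prior = prior)
    }, numeric(1))
  }

  with_seed(seed, {
    samples <- list()
    for (mode in modes) {
      if (mode == "original") {
        samples[[mode]] <- score_all(kern0, profile, assoc)
        next
      }
      reps <- lapply(seq_len(n_perm), function(r) {
        switch(mode,
          permute_pps = {
            perm <- sample.int(profile$m)
            Sp <- profile$S[perm, perm, drop = FALSE]
            prof_p <- phenotype_profile(Sp, diseases = profile$diseases)
            score_all(kern0, prof_p, assoc)
          },
          permute_assoc = {
            asc_p <- association_set(assoc$pairs$disease,
                                     sample(assoc$pairs$gene))
            score_all(kern0, profile, asc_p)
          },
          random_seed_genes = {
            asc_p <- association_set(
              assoc$pairs$disease,
              sample(net$genes, nrow(assoc$pairs), replace = TRUE))
            score_all(kern0, profile, asc_p)
          },
          permute_ppi = {
            net_p <- degree_preserving_rewire(net)
            score_all(diffusion_kernel(net_p, gamma), profile, assoc)
          })
      })
      samples[[mode]] <- unlist(reps)
    }
    x <- samples[["original"]]
    wil <- if (!is.null(x)) {
      stats::wilcox.test(x, mu = 0, alternative = "greater",
                         exact = length(x) <= 25L, correct = TRUE)
    } else NULL
    list(samples = samples,
         median_bf = vapply(samples, function(s) exp(stats::median(s)), numeric(1)),
         wilcoxon = wil,
         seed = seed)
  })
}
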