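test_that("roc_auc handles separation, ties, and a hand-counted mixture", {
  expect_equal(roc_auc(rep(0.01, 5), rep(0.99, 7))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 4), rep(0.5, 6))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4), c(0.2, 0.3))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
})

test_that("roc_auc equals exhaustive Mann-Whitney pair counting", {
  withr::with_seed(31, {
    for (rep in 1:200) {
      n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
      # discretized ratios so ties occur often
      pos <- sample(1:10, n1, replace = TRUE) / 10
      ctl <- sample(1:10, n2, replace = TRUE) / 10
      expect_equal(roc_auc(pos, ctl)$auc, pair_count_auc(pos, ctl),
                   tolerance = 1e-12)
    }
  })
})

test_that("an always-first oracle achieves mean rank ratio 1/(n_controls+1) and AUC 1", {
  scn <- small_scenario()
  res <- loocv_random_controls(scn$profile, scn$assoc, oracle_scorer(scn$assoc),
                               scenario_universe(scn), n_controls = 99, seed = 4)
  expect_equal(res$mean_rank_ratio, 1 / 100)
  expect_equal(res$auc, 1)
  expect_true(all(res$records$rank == 1))
})

test_that("a random scorer is calibrated near the uniform-rank expectation", {
  scn <- small_scenario()
  res <- loocv_random_controls(scn$profile, scn$assoc, random_scorer(),
                               scenario_universe(scn), n_controls = 99,
                               seed = 5, n_repeats = 4)
  n <- nrow(res$records)
  se <- sqrt((100^2 - 1) / 12) / 100 / sqrt(n)
  expect_lt(abs(res$mean_rank_ratio - 0.505), 3 * se)
  expect_lt(abs(res$auc - 0.5), 0.05)
})

test_that("LOOCV results are reproducible for a fixed seed", {
  scn <- small_scenario()
  sc <- oracle_scorer(scn$assoc)
  r1 <- loocv_random_controls(scn$profile, scn$assoc, sc, scenario_universe(scn),
                              n_controls = 20, seed = 9)
  r2 <- loocv_random_controls(scn$profile, scn$assoc, sc, scenario_universe(scn),
                              n_controls = 20, seed = 9)
  expect_identical(r1$records, r2$records)
  expect_error(
    loocv_random_controls(scn$profile, scn$assoc, sc, letters[1:10],
                          n_controls = 99, seed = 1),
    "control pool")
})

test_that("the held-out association never leaks into the scorer's view", {
  scn <- small_scenario()
  seen <- new.env()
  spy <- function(disease, candidates, assoc) {
    pairs <- assoc$pairs
    held <- scn$assoc$pairs
    for (i in seq_len(nrow(pairs))) {
      if (pairs$disease[i] == disease) {
        # the candidate being tested must not be annotated to the disease
        assign("checked", TRUE, envir = seen)
        expect_false(candidates[1] %in% disease_genes(assoc, disease))
      }
    }
    seq_along(candidates)
  }
  loocv_random_controls(scn$profile, scn$assoc, spy, scenario_universe(scn),
                        n_controls = 5, seed = 2)
  expect_true(get("checked", envir = seen))
})

test_that("linkage-interval controls come from the +/- window on the same chromosome", {
  # toy genome: 7 genes on one chromosome, 1 on another
  coords <- data.frame(
    chrom = c(rep("chr1", 7), "chr2"),
    start = c(0, 1e6, 2e6, 3e6, 4e6, 5e6, 30e6, 1e6),
    end = c(0, 1e6, 2e6, 3e6, 4e6, 5e6, 30e6, 1e6) + 1,
    gene = paste0("g", 1:8), stringsAsFactors = FALSE
  )
  prof <- phenotype_profile(diag(2), diseases = c("d1", "d2"))
  assoc <- association_set(c("d1", "d2"), c("g1", "g8"))
  sc <- oracle_scorer(assoc)
  res <- loocv_linkage_interval(prof, assoc, sc, coords, window_bp = 1e7)
  # g1's interval holds g2..g6 (5 controls); g8 is alone on chr2 -> skipped
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$n_candidates, 6L)
  expect_equal(res$records$rank_ratio, 1 / 6)
  expect_equal(res$n_skipped, 1L)
  # zero window leaves no controls anywhere
  expect_error(loocv_linkage_interval(prof, assoc, sc, coords, window_bp = 0),
               "skipped")
  expect_error(loocv_linkage_interval(prof, assoc, sc, coords[0, ]), "empty")
})

test_that("linkage-interval validation with a random scorer is near 0.5", {
  scn <- small_scenario()
  res <- withr::with_seed(77,
    loocv_linkage_interval(scn$profile, scn$assoc, random_scorer(), scn$coords))
  expect_gt(nrow(res$records), 30)
  expect_lt(abs(res$mean_rank_ratio - 0.5), 0.1)
})

test_that("identity relabeling of the similarity profile reproduces original Bayes factors", {
  toy <- toy_problem()
  perm_prof <- phenotype_profile(toy$profile$S[1:5, 1:5],
                                 diseases = toy$profile$diseases)
  orig <- vapply(seq_len(nrow(toy$assoc$pairs)), function(i)
    score_candidate_bf(toy$assoc$pairs$disease[i], toy$assoc$pairs$gene[i],
                       toy$kern, toy$profile, toy$assoc), numeric(1))
  relab <- vapply(seq_len(nrow(toy$assoc$pairs)), function(i)
    score_candidate_bf(toy$assoc$pairs$disease[i], toy$assoc$pairs$gene[i],
                       toy$kern, perm_prof, toy$assoc), numeric(1))
  expect_equal(relab, orig)
})

test_that("permutation suite runs all modes deterministically and flags unknown modes", {
  scn <- small_scenario()
  res <- permutation_suite(scn$profile, scn$assoc, scn$networks[[1]],
                           seed = 3, n_perm = 1)
  expect_setequal(names(res$samples),
                  c("original", "permute_pps", "permute_assoc",
                    "random_seed_genes", "permute_ppi"))
  # relabeling/rewiring modes keep the association set intact; shuffled
  # gene columns may collapse onto duplicate pairs, which are dropped
  expect_true(all(lengths(res$samples[c("original", "permute_pps", "permute_ppi")]) ==
                    nrow(scn$assoc$pairs)))
  expect_true(all(lengths(res$samples) <= nrow(scn$assoc$pairs)))
  res2 <- permutation_suite(scn$profile, scn$assoc, scn$networks[[1]],
                            seed = 3, n_perm = 1)
  expect_identical(res$samples, res2$samples)
  # n_perm = 0 keeps only the original mode
  res0 <- permutation_suite(scn$profile, scn$assoc, scn$networks[[1]],
                            seed = 3, n_perm = 0)
  expect_identical(names(res0$samples), "original")
  expect_error(permutation_suite(scn$profile, scn$assoc, scn$networks[[1]],
                                 modes = "bogus"), "unknown permutation mode")
})
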