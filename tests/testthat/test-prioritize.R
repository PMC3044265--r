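test_that("design matrices have pq + 1 columns in kernel-major order", {
  toy <- toy_problem()
  d1 <- build_design("d2", "c", toy$kern, toy$profile, toy$assoc, scheme = 1)
  expect_equal(dim(d1$X), c(5L, 2L))  # p = 1, q = 1
  expect_true(all(d1$X[, 1] == 1))
  expect_equal(d1$y, unname(toy$profile$S["d2", ]))

  kerns <- list(toy$kern, diffusion_kernel(toy$net, 0.3))
  d2 <- build_design("d1", "c", kerns, toy$profile, toy$assoc, scheme = 2)
  expect_equal(ncol(d2$X), 1L + 3L * 2L)  # p = 3 model genes, q = 2
  # scheme-1 columns use the override G(query) = {candidate}
  x_expected <- gene_proximity_vector(toy$kern, "c", toy$profile, toy$assoc,
                                      override = list(d2 = "c"))
  expect_equal(unname(d1$X[, 2]), unname(x_expected))
})

test_that("single-network scoring equals integration with q = 1 and zero networks are inert", {
  toy <- toy_problem()
  s_single <- score_candidate_bf("d1", "c", toy$kern, toy$profile, toy$assoc)
  s_list <- score_candidate_bf("d1", "c", list(toy$kern), toy$profile, toy$assoc)
  expect_identical(s_single, s_list)

  # a network covering none of the involved genes adds all-zero columns
  alien <- diffusion_kernel(ppi_network(cbind("zz1", "zz2")), 0.2)
  s_aug <- score_candidate_bf("d1", "c", list(toy$kern, alien), toy$profile, toy$assoc)
  expect_equal(s_aug, s_single, tolerance = 1e-12)
})

test_that("candidates absent from every network score log BF = 0", {
  toy <- toy_problem()
  expect_identical(score_candidate_bf("d1", "ghost", toy$kern, toy$profile, toy$assoc), 0)
  kerns <- list(toy$kern, diffusion_kernel(toy$net, 0.4))
  expect_identical(score_candidate_bf("d1", "ghost", kerns, toy$profile, toy$assoc), 0)
})

test_that("ranking orders by score with average-rank ties", {
  rl <- rank_candidates("d", c("g1", "g2", "g3"), c(3, 2, 1))
  expect_equal(rl$rank, c(1, 2, 3))
  expect_equal(rl$rank_ratio, c(1, 2, 3) / 3)

  tied <- rank_candidates("d", paste0("g", 1:4), rep(5, 4))
  expect_true(all(tied$rank == 2.5))
  expect_true(all(tied$rank_ratio == 2.5 / 4))
  # display order deterministic by identifier within ties
  expect_equal(tied$gene, paste0("g", 1:4))

  big <- rank_candidates("d", paste0("g", 1:100), c(10, rnorm(99)))
  expect_equal(big$rank_ratio[big$gene == "g1"], 0.01)
  expect_error(rank_candidates("d", c("a", "a"), c(1, 2)), "duplicate")
})

test_that("cipher proximity applies a Gaussian kernel to shortest paths", {
  net <- path_graph()  # a - b - c - d
  W <- cipher_proximity(net)
  expect_equal(W$Z["a", "a"], 1)
  expect_equal(W$Z["a", "b"], exp(-1))
  expect_equal(W$Z["a", "c"], exp(-4))
  expect_equal(W$Z["a", "d"], exp(-9))
  # disconnected pairs get zero proximity
  net2 <- ppi_network(rbind(c("a", "b"), c("x", "y")))
  expect_equal(cipher_proximity(net2)$Z["a", "x"], 0)
  # bandwidth rescales the exponent
  expect_equal(cipher_proximity(net, bandwidth = 4)$Z["a", "c"], exp(-1))
})

test_that("cipher score is the Pearson correlation of y_d and x_g", {
  toy <- toy_problem()
  s <- cipher_score("d1", "b", toy$net, toy$profile, toy$assoc)
  W <- cipher_proximity(toy$net)
  x <- gene_proximity_vector(W, "b", toy$profile, toy$assoc,
                             override = list(d1 = "b"))
  # direct formula oracle
  y <- toy$profile$S["d1", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(s, r_hand, tolerance = 1e-12)

  # perfect linear dependence gives 1; all-zero proximity warns and gives 0
  prof <- toy$profile
  prof$S["d1", ] <- prof$S[, "d1"] <- c(1, 0.5, 0.25, 0.4, 0.3)
  diag(prof$S) <- 1
  expect_warning(s0 <- cipher_score("d1", "ghost", toy$net, prof, toy$assoc), "zero variance")
  expect_equal(s0, 0)

  # diffusion-kernel variant
  sd1 <- cipher_score("d1", "b", toy$net, toy$profile, toy$assoc, sp_kernel = FALSE)
  xd <- gene_proximity_vector(toy$kern, "b", toy$profile, toy$assoc,
                              override = list(d1 = "b"))
  expect_equal(sd1, cor(xd, toy$profile$S["d1", ]), tolerance = 1e-12)
})

test_that("ols R^2 matches the normal-equations oracle and handles edge cases", {
  toy <- toy_problem()
  r2 <- ols_r2_score("d1", "b", toy$kern, toy$profile, toy$assoc)
  d <- build_design("d1", "b", toy$kern, toy$profile, toy$assoc, scheme = 1)
  beta <- solve(crossprod(d$X), crossprod(d$X, d$y))
  sse <- sum((d$y - d$X %*% beta)^2)
  sst <- sum((d$y - mean(d$y))^2)
  expect_equal(r2, 1 - sse / sst, tolerance = 1e-10)

  # exact linear response gives R^2 = 1; absent candidate gives 0
  expect_equal(ols_r2_score("d1", "ghost", toy$kern, toy$profile, toy$assoc), 0)
  m <- 6
  yx <- withr::with_seed(1, rnorm(m))
  prof <- phenotype_profile(diag(m), diseases = paste0("p", 1:m))
  # direct check of the fitting path on a synthetic exact-fit design
  X <- cbind(1, yx)
  fit <- qr(X)
  expect_equal(sum(qr.resid(fit, 2 * yx + 3)^2), 0, tolerance = 1e-20)
})

test_that("scorer factories agree with their single-candidate functions", {
  toy <- toy_problem()
  cands <- c("a", "c", "ghost")
  sc_bf <- bf_scorer(toy$kern, toy$profile)
  expect_equal(sc_bf("d2", cands, toy$assoc),
               vapply(cands, function(g)
                 score_candidate_bf("d2", g, toy$kern, toy$profile, toy$assoc),
                 numeric(1), USE.NAMES = FALSE))
  sc_ci <- cipher_scorer(toy$net, toy$profile)
  expect_equal(sc_ci("d2", cands, toy$assoc)[1:2],
               vapply(cands[1:2], function(g)
                 cipher_score("d2", g, toy$net, toy$profile, toy$assoc),
                 numeric(1), USE.NAMES = FALSE))
  sc_ols <- ols_scorer(toy$kern, toy$profile)
  expect_equal(sc_ols("d2", cands, toy$assoc),
               vapply(cands, function(g)
                 ols_r2_score("d2", g, toy$kern, toy$profile, toy$assoc),
                 numeric(1), USE.NAMES = FALSE))
})
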