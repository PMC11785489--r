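test_that("canonical correlations at lambda 0 match classical CCA", {
  set.seed(31)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- X[, 1:3] %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(n * 3), n, 3)
  fit <- fit_rcca(X, Y)
  expect_equal(fit$cor[1:3], cancor(X, Y)$cor, tolerance = 1e-8)
  # self-correlation
  expect_equal(fit_rcca(X, X)$cor[1], 1, tolerance = 1e-8)
  # correlations are non-increasing
  expect_true(all(diff(fit$cor) <= 1e-8))
  # contract errors
  expect_error(fit_rcca(X, Y[-1, ]), "same number of rows")
  expect_error(fit_rcca(X, Y, lambda_x = -1), ">= 0")
})

test_that("regularized singular values agree with the reference rCCA solver", {
  skip_if_not_installed("mixOmics")
  set.seed(32)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- X[, 1:3] + matrix(rnorm(n * 3), n, 3)
  ref <- mixOmics::rcc(X, Y, method = "ridge", lambda1 = 0.4, lambda2 = 0.2)
  fit <- fit_rcca(X, Y, lambda_x = 0.4, lambda_y = 0.2)
  expect_equal(fit$d[seq_along(ref$cor)], unname(ref$cor), tolerance = 1e-6)
})

test_that("a planted shared factor with population correlation 0.6 is recovered", {
  set.seed(33)
  n <- 5000; rho <- 0.6
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[, 1] <- rho * X[, 1] + sqrt(1 - rho^2) * rnorm(n)
  fit <- fit_rcca(X, Y, 0.01, 0.01)
  # Monte-Carlo error of r at n=5000 is ~ (1-rho^2)/sqrt(n) ~ 0.009;
  # allow 3 sd plus overfitting bias of order (p+q)/n
  expect_lt(abs(fit$cor[1] - rho), 0.03)
  # sign convention: the dominant x weight is positive
  expect_gt(fit$xcoef[which.max(abs(fit$xcoef[, 1])), 1], 0)
  # user-directed sign flips negate scores
  flip <- fit_rcca(X, Y, 0.01, 0.01, flip = 1)
  expect_equal(flip$xcoef[, 1], -fit$xcoef[, 1])
  expect_equal(flip$cor[1], fit$cor[1])
})

test_that("penalty tuning prefers regularization when p approaches n", {
  set.seed(34)
  n <- 60; p <- 40
  Z <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p) + Z
  Y <- matrix(rnorm(n * p), n, p) + Z
  sel <- tune_rcca(X, Y, lambda_grid = c(0, 0.1, 1), folds = 5, seed = 2)
  expect_gt(sel$lambda_x, 0)
  expect_gt(sel$lambda_y, 0)
  # single grid point is returned as-is, reproducibly
  one <- tune_rcca(X, Y, lambda_grid = 0.5, folds = 3, seed = 7)
  expect_equal(one$lambda_x, 0.5)
  expect_identical(tune_rcca(X, Y, c(0, 0.1, 1), seed = 2)$lambda_x,
                   sel$lambda_x)
  expect_error(tune_rcca(X, Y, numeric(0)), "non-empty")
})

test_that("permutation p values hit the floor for strong signal and validate input", {
  set.seed(35)
  n <- 400
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 1] <- 0.6 * X[, 1] + 0.8 * rnorm(n)
  pt <- rcca_permutation_test(X, Y, 0.05, 0.05, n_perm = 99, seed = 4)
  expect_equal(pt$p_train[1], 1 / 100)
  expect_true(all(pt$p_train >= 1 / 100 & pt$p_train <= 1))
  expect_error(rcca_permutation_test(X, Y, n_perm = 0), "at least 1")
  # held-out evaluation returns test-set p values too
  hold <- rep(c(FALSE, TRUE), length.out = n)
  pt2 <- rcca_permutation_test(X, Y, 0.05, 0.05, n_perm = 49, seed = 4,
                               holdout = hold)
  expect_equal(pt2$p_test[1], 1 / 50)
})

test_that("scorer recovers a planted sparse truth and standardizes scores", {
  cfg <- sim_config(n_donors = 6L, cells_per_donor = 700L)
  sim <- simulate_repertoire(cfg, seed = 41)
  one <- sample_one_per_clone(sim$cells, seed = 42)
  tc <- sim$tcrs[match(one$cell_id, sim$tcrs$cell_id), ]
  fe <- featurize_tcrs(tc, cfg$gene_table, cfg$registry)
  m <- train_scorer(fe, one$state, seed = 43)
  s <- predict(m, fe)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(sd(s), 1, tolerance = 1e-10)
  top10 <- order(abs(m$weights), decreasing = TRUE)[1:10]
  hits <- intersect(top10, sim$truth$true_idx)
  expect_gte(length(hits), 6L)  # modest n here; full-scale check elsewhere
  expect_true(all(sign(m$weights[hits]) ==
                    sign(sim$truth$weights[hits])))
  # serialization reproduces identical scores
  path <- tempfile(fileext = ".json")
  write_scorer(m, path)
  m2 <- read_scorer(path)
  expect_equal(predict(m2, fe), s, tolerance = 1e-12)
  # registry mismatch is refused
  fe0 <- featurize_tcrs(tc[1:5, ], cfg$gene_table,
                        build_registry(interactions = FALSE))
  expect_error(predict(m, fe0), "registry")
  expect_error(train_scorer(fe, rep(1, nrow(fe$x))), "both classes")
})

test_that("an extreme ridge penalty flattens the scorer", {
  cfg <- quick_config()
  sim <- simulate_repertoire(cfg, seed = 44)
  fe <- featurize_tcrs(sim$tcrs[1:200, ], cfg$gene_table, cfg$registry)
  y <- sim$cells$state[1:200]
  m <- train_scorer(fe, y, lambda = 1e6)
  expect_lt(max(abs(m$weights)), 1e-4)
  expect_lt(m$score_sd, 0.01)
})

test_that("score is linear and monotone in a positively weighted feature", {
  cfg <- quick_config()
  sim <- simulate_repertoire(cfg, seed = 45)
  fe <- featurize_tcrs(sim$tcrs[1:200, ], cfg$gene_table, cfg$registry)
  m <- train_scorer(fe, sim$cells$state[1:200], seed = 1)
  j <- which.max(m$weights)  # positive weight, unmasked somewhere
  row <- which(!fe$mask[, j])[1]
  fe_hi <- fe
  fe_hi$x[row, j] <- fe$x[row, j] + 1
  expect_gt(predict(m, fe_hi)[row], predict(m, fe)[row])
})

test_that("single-chain scorers ignore the other chain entirely", {
  cfg <- quick_config()
  sim <- simulate_repertoire(cfg, seed = 46)
  tc <- sim$tcrs[1:200, ]
  fe <- featurize_tcrs(tc, cfg$gene_table, cfg$registry)
  m_a <- train_scorer(fe, sim$cells$state[1:200], chain_mask = "alpha_only",
                      seed = 2)
  beta_loops <- c("CDR1b", "CDR2b", "CDR3b")
  expect_true(all(m_a$weights[cfg$registry$features$loop %in% beta_loops] == 0))
  # scramble all beta-chain sequences across cells: scores unchanged
  scr <- tc
  perm <- sample(nrow(scr))
  scr[c("vb", "jb", "cdr3b")] <- scr[perm, c("vb", "jb", "cdr3b")]
  fe_scr <- featurize_tcrs(scr, cfg$gene_table, cfg$registry)
  expect_equal(predict(m_a, fe_scr), predict(m_a, fe), tolerance = 1e-12)
})

test_that("CDR contribution shares are a normalized partition attribution", {
  cfg <- quick_config()
  sim <- simulate_repertoire(cfg, seed = 47)
  fe <- featurize_tcrs(sim$tcrs[1:150, ], cfg$gene_table, cfg$registry)
  m <- train_scorer(fe, sim$cells$state[1:150], seed = 3)
  imp <- cdr_contribution(m, fe)
  expect_equal(sum(imp$share), 1, tolerance = 1e-12)
  expect_true(all(imp$share >= 0))
  # a model whose weights live only in CDR3b attributes everything there
  m3 <- m
  keep <- cfg$registry$features$loop == "CDR3b"
  m3$weights[!keep] <- 0
  imp3 <- cdr_contribution(m3, fe)
  expect_equal(imp3$share[imp3$group == "CDR3b"], 1)
  expect_true(all(imp3$share[imp3$group != "CDR3b"] == 0))
  # groups must partition the registry
  expect_error(cdr_contribution(m, fe, groups = list(a = 1:10)), "partition")
})
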