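test_that("single-donor mixed model reduces to plain logistic regression", {
  set.seed(51)
  n <- 400
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.4 * s - 0.5))
  a <- mixed_logit(y, s, rep("d1", n))
  ref <- glm(y ~ s, family = binomial())
  expect_equal(a$beta, unname(coef(ref)["s"]), tolerance = 1e-6)
  expect_equal(a$se, unname(summary(ref)$coefficients["s", 2]),
               tolerance = 1e-6)
  expect_match(a$model, "single donor")
  expect_error(mixed_logit(rep(1, 10), rnorm(10), rep("d", 10)),
               "single class")
})

test_that("donor random-intercept model recovers a known effect", {
  set.seed(52)
  nd <- 30; nc <- 200
  donor <- rep(sprintf("d%02d", 1:nd), each = nc)
  u <- rnorm(nd, 0, 0.5)[rep(1:nd, each = nc)]
  s <- rnorm(nd * nc)
  y <- rbinom(nd * nc, 1, plogis(0.3 * s - 0.5 + u))
  a <- mixed_logit(y, s, donor)
  expect_lt(abs(a$beta - 0.3), 2 * a$se)
  expect_true(a$converged)
  expect_equal(a$ci, c(a$beta - 1.96 * a$se, a$beta + 1.96 * a$se))
  # invariance to donor relabeling and row order
  perm <- sample(length(y))
  relab <- setNames(sprintf("z%02d", sample(nd)), unique(donor))
  a2 <- mixed_logit(y[perm], s[perm], unname(relab[donor[perm]]))
  expect_equal(a2$beta, a$beta, tolerance = 1e-6)
  # one-tailed option halves the two-sided p for a positive effect
  a3 <- mixed_logit(y, s, donor, one_tailed = TRUE)
  expect_equal(a3$p, a$p / 2, tolerance = 1e-10)
})

test_that("per-donor effects respect the eligibility rules", {
  set.seed(53)
  mk <- function(donor, n, npos) {
    data.frame(donor = donor, s = rnorm(n),
               y = sample(rep(c(1L, 0L), c(npos, n - npos))))
  }
  df <- rbind(mk("small", 99, 50),   # < 100 cells
              mk("fewpos", 120, 9),  # < 10 matched
              mk("fewneg", 120, 111),# < 10 unmatched
              mk("ok", 150, 60))
  out <- per_individual_betas(df$y, df$s, df$donor)
  expect_equal(out$estimates$donor, "ok")
  expect_setequal(out$excluded$donor, c("small", "fewpos", "fewneg"))
  ref <- glm(y ~ s, family = binomial(), data = df[df$donor == "ok", ])
  expect_equal(out$estimates$beta, unname(coef(ref)["s"]), tolerance = 1e-10)
})

test_that("random-effects meta-analysis handles degenerate and equal studies", {
  one <- random_effects_meta(0.4, 0.1)
  expect_equal(one$mu, 0.4)
  expect_equal(one$tau2, 0)
  two <- random_effects_meta(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(two$mu, 0.3, tolerance = 1e-8)
  expect_equal(two$tau2, 0, tolerance = 1e-8)
  expect_equal(two$I2, 0)
  expect_error(random_effects_meta(numeric(0), numeric(0)), "no studies")
  expect_error(random_effects_meta(c(1, 2), c(0.1, -1)), "positive")
})

test_that("meta-analysis recovers simulated heterogeneity and the lfsr closed form", {
  set.seed(54)
  k <- 50; mu <- 0.2; tau <- 0.1
  ses <- runif(k, 0.03, 0.08)
  betas <- rnorm(k, mu, tau) + rnorm(k, 0, ses)
  m <- random_effects_meta(betas, ses)
  expect_lt(abs(m$mu - mu), 3 * m$mu_se)
  expect_lt(abs(sqrt(m$tau2) - tau), 0.05)
  expect_equal(m$lfsr, pnorm(-m$mu / sqrt(m$tau2)))
  expect_equal(m$H2, m$Q / m$df)
  expect_equal(m$I2, max(0, (m$Q - m$df) / m$Q) * 100)
})

test_that("twin null probability follows the pair-sampling closed form", {
  expect_equal(twin_pnull(c(2))$p_null, 1)
  expect_equal(twin_pnull(c(1, 1))$p_null, 0)
  # [3,1]: 3 concordant of the 6 possible pairs
  expect_equal(twin_pnull(c(3, 1))$p_null, 0.5)
  expect_error(twin_pnull(c(1, 0)), "at least 2")
  expect_error(twin_pnull(c(-1, 3)), "non-negative")
})

test_that("twin null matches Monte-Carlo pair resampling", {
  set.seed(55)
  for (i in 1:20) {
    counts <- rpois(sample(2:8, 1), 4) + 1
    pn <- twin_pnull(counts)$p_null
    N <- sum(counts)
    lab <- rep(seq_along(counts), counts)
    B <- 2e5
    i1 <- sample.int(N, B, replace = TRUE)
    i2 <- sample.int(N - 1, B, replace = TRUE)
    i2 <- ifelse(i2 >= i1, i2 + 1L, i2)
    phat <- mean(lab[i1] == lab[i2])
    expect_lt(abs(phat - pn), 3 * sqrt(pn * (1 - pn) / B) + 1e-12)
  }
})

test_that("exact binomial tail matches closed forms and the reference algorithm", {
  expect_equal(twin_binomial_test(2, 2, 0.5)$p_value, 0.25)
  expect_equal(twin_binomial_test(10, 10, 0.5)$p_value, 2^-10)
  expect_equal(twin_binomial_test(5, 0, 0.3)$p_value, 1)
  expect_error(twin_binomial_test(10, 5, 1.2), "between 0 and 1")
  expect_error(twin_binomial_test(10, 11, 0.5), "n_pairs")
  # deep tails: agree with pbinom (incomplete-beta algorithm) to 3 sig digits
  cases <- list(c(115, 80, 0.215), c(115, 115, 0.215), c(200, 150, 0.2),
                c(115, 80, 0.5), c(50, 50, 0.25))
  for (cs in cases) {
    ours <- twin_binomial_test(cs[1], cs[2], cs[3])$p_value
    ref <- pbinom(cs[2] - 1, cs[1], cs[3], lower.tail = FALSE)
    expect_lt(abs(ours / ref - 1), 5e-4)
  }
  # the headline-sized tail is far below 1e-20 and still finite in log space
  deep <- twin_binomial_test(115, 115, 0.1)
  expect_lt(deep$log10_p, -100)
  expect_true(is.finite(deep$log10_p))
})

test_that("null twin cohorts are calibrated against the expected concordance", {
  cfg <- sim_config(n_donors = 8L, cells_per_donor = 150L, public_rate = 0.05,
                    concordance_boost = 0)
  conc <- integer(0); expected <- numeric(0)
  for (seed in 1:8) {
    tw <- simulate_twin_cohort(cfg, seed = seed)
    pairs <- find_twins(tw$cells)
    if (nrow(pairs) == 0) next
    member_states <- c(pairs$state_a, pairs$state_b)
    pn <- twin_pnull(as.integer(table(member_states)))$p_null
    conc <- c(conc, sum(pairs$concordant))
    expected <- c(expected, nrow(pairs) * pn)
  }
  # aggregate concordance should match the null expectation within CLT error
  expect_lt(abs(sum(conc) - sum(expected)), 3 * sqrt(sum(expected)) + 3)
})

test_that("boosted twin cohorts reject the concordance null", {
  cfg <- sim_config(n_donors = 8L, cells_per_donor = 200L, public_rate = 0.15,
                    concordance_boost = 0.6)
  tw <- simulate_twin_cohort(cfg, seed = 77)
  pairs <- find_twins(tw$cells)
  expect_gt(nrow(pairs), 10)
  states <- c(pairs$state_a, pairs$state_b)
  pn <- twin_pnull(as.integer(table(states)))
  res <- twin_binomial_test(nrow(pairs), sum(pairs$concordant), pn)
  expect_lt(res$p_value, 0.001)
})

test_that("down-sampling is deterministic and the identity at full size", {
  set.seed(56)
  cells <- data.frame(y = rbinom(300, 1, 0.4), s = rnorm(300),
                      donor = rep(c("a", "b", "c"), each = 100))
  test_fun <- function(d) mixed_logit(d$y, d$s, d$donor)
  full <- downsample_match(cells, nrow(cells), seed = 1, test = test_fun)
  ref <- test_fun(cells)
  expect_equal(full$beta, ref$beta)
  sub1 <- downsample_match(cells, 150, seed = 9, test = test_fun)
  sub2 <- downsample_match(cells, 150, seed = 9, test = test_fun)
  expect_identical(attr(sub1, "rows"), attr(sub2, "rows"))
  expect_error(downsample_match(cells, 301, 1, test_fun), "exceeds")
})
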