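#' Mixed-effects logistic association between a TCR score and a cell state
#'
#' Fits `logit P(state_i = 1) = beta_score * score_i + beta_0 + b_donor(i)`
#' with a Gaussian random intercept per donor, via `lme4::glmer` using the
#' Laplace approximation to the integral over random effects. With a single
#' donor the random intercept is dropped and the model reduces to plain
#' logistic regression. Inference on `beta_score` is a Wald test; the 95%
#' confidence interval is `beta +/- 1.96 se`. Scores are expected to be
#' standardized (one unit = one training sd), so `beta` is the log odds
#' ratio per sd of TCR score. Callers should pass one cell per clone.
#'
#' @param states Binary outcome vector.
#' @param scores Numeric TCR scores.
#' @param donor_ids Donor identifier per cell.
#' @param covariates Optional data frame of additional fixed effects.
#' @param one_tailed Report the upper-tailed p value for `beta > 0`.
#' @return Object of class `tcr_assoc`: `beta`, `se`, `ci` (length 2), `p`,
#'   `z`, `n`, `n_donors`, `model`, `converged`, `one_tailed`.
#' @export
mixed_logit <- function(states, scores, donor_ids, covariates = NULL,
                        one_tailed = FALSE) {
  states <- as.integer(as.logical(states))
  n <- length(states)
  if (length(scores) != n || length(donor_ids) != n)
    .stopf("states, scores and donor_ids must have equal length")
  if (length(unique(states)) < 2L)
    .stopf("outcome has a single class; association is inestimable")
  df <- data.frame(state = states, score = as.numeric(scores),
                   donor = factor(donor_ids))
  form_fixed <- "state ~ score"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    form_fixed <- paste(form_fixed, "+",
                        paste(names(covariates), collapse = " + "))
  }
  n_donors <- nlevels(df$donor)
  converged <- TRUE
  if (n_donors >= 2L) {
    fit <- withCallingHandlers(
      lme4::glmer(stats::as.formula(paste(form_fixed, "+ (1 | donor)")),
                  data = df, family = stats::binomial(), nAGQ = 1L),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    model <- "glmer (Laplace, random donor intercept)"
  } else {
    fit <- stats::glm(stats::as.formula(form_fixed), data = df,
                      family = stats::binomial())
    converged <- fit$converged
    co <- summary(fit)$coefficients
    model <- "glm (single donor)"
  }
  beta <- co["score", 1]; se <- co["score", 2]
  z <- beta / se
  p <- if (one_tailed) stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  structure(list(beta = beta, se = se,
                 ci = c(beta - 1.96 * se, beta + 1.96 * se),
                 p = p, z = z, n = n, n_donors = n_donors, model = model,
                 converged = converged, one_tailed = one_tailed),
            class = "tcr_assoc")
}

#' @export
print.tcr_assoc <- function(x, ...) {
  cat("TCR score association (", x$model, ")\n", sep = "")
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$beta, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  %s Wald p = %.3g, n = %d cells, %d donor(s)%s\n",
              if (x$one_tailed) "one-tailed" else "two-sided",
              x$p, x$n, x$n_donors,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' Per-donor association effects
#'
#' Plain logistic regression of state on score within each eligible donor.
#' Donors are eligible if they contribute at least `min_cells` cells, of
#' which at least `min_pos` match the target state and at least `min_neg`
#' do not.
#'
#' @inheritParams mixed_logit
#' @param min_cells,min_pos,min_neg Eligibility thresholds.
#' @return List with `estimates` (data frame: donor, beta, se, n, n_pos)
#'   and `excluded` (data frame: donor, reason).
#' @export
per_individual_betas <- function(states, scores, donor_ids,
                                 min_cells = 100L, min_pos = 10L,
                                 min_neg = 10L) {
  states <- as.integer(as.logical(states))
  donors <- sort(unique(as.character(donor_ids)))
  est <- list(); excl <- list()
  for (d in donors) {
    i <- donor_ids == d
    n <- sum(i); npos <- sum(states[i]); nneg <- n - npos
    reason <- if (n < min_cells) sprintf("fewer than %d cells", min_cells)
      else if (npos < min_pos) sprintf("fewer than %d state-matched cells", min_pos)
      else if (nneg < min_neg) sprintf("fewer than %d non-matched cells", min_neg)
      else NA_character_
    if (!is.na(reason)) {
      excl[[d]] <- data.frame(donor = d, reason = reason,
                              stringsAsFactors = FALSE)
      next
    }
    fit <- stats::glm(states[i] ~ scores[i], family = stats::binomial())
    co <- summary(fit)$coefficients
    est[[d]] <- data.frame(donor = d, beta = co[2, 1], se = co[2, 2],
                           n = n, n_pos = npos, stringsAsFactors = FALSE)
  }
  empty_est <- data.frame(donor = character(), beta = numeric(),
                          se = numeric(), n = integer(), n_pos = integer())
  empty_exc <- data.frame(donor = character(), reason = character())
  list(estimates = if (length(est)) do.call(rbind, c(est, make.row.names = FALSE)) else empty_est,
       excluded = if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE)) else empty_exc)
}

#' Random-effects meta-analysis of per-unit effects
#'
#' Pools per-donor (or per-antigen) log odds ratios under a normal
#' random-effects model, estimating the between-unit variance `tau^2` by
#' maximum likelihood (`metafor::rma`, `method = "ML"`). Heterogeneity is
#' summarised from Cochran's Q as `I^2 = max(0, (Q - df)/Q) * 100` and
#' `H^2 = Q/df`. The local false sign rate -- the model-implied fraction of
#' units whose true effect has the opposite (non-positive) sign of the
#' pooled mean -- is `pnorm(-mu/tau)` for `tau > 0` and the indicator
#' `mu <= 0` otherwise.
#'
#' @param betas Effect estimates.
#' @param ses Their standard errors (all positive).
#' @return Object of class `tcr_meta`: `mu`, `mu_se`, `mu_p`, `tau2`, `Q`,
#'   `Q_p`, `df`, `I2` (percent), `H2`, `lfsr`, `k`.
#' @export
random_effects_meta <- function(betas, ses) {
  k <- length(betas)
  if (k == 0L) .stopf("no studies to pool")
  if (length(ses) != k || any(ses <= 0))
    .stopf("'ses' must be positive and match 'betas'")
  if (k == 1L) {
    mu <- betas[1]; mu_se <- ses[1]; tau2 <- 0
    Q <- 0; df <- 0L; Qp <- NA_real_; I2 <- 0; H2 <- NA_real_
    mu_p <- 2 * stats::pnorm(-abs(mu / mu_se))
  } else {
    fit <- metafor::rma(yi = betas, sei = ses, method = "ML")
    mu <- as.numeric(fit$b); mu_se <- fit$se; mu_p <- fit$pval
    tau2 <- fit$tau2
    Q <- fit$QE; Qp <- fit$QEp; df <- k - 1L
    I2 <- max(0, (Q - df) / Q) * 100
    H2 <- Q / df
  }
  lfsr <- if (tau2 > 0) stats::pnorm(-mu / sqrt(tau2)) else as.numeric(mu <= 0)
  structure(list(mu = mu, mu_se = mu_se, mu_p = mu_p, tau2 = tau2,
                 Q = Q, Q_p = Qp, df = df, I2 = I2, H2 = H2,
                 lfsr = lfsr, k = k),
            class = "tcr_meta")
}

#' @export
print.tcr_meta <- function(x, ...) {
  cat("Random-effects meta-analysis (ML), k =", x$k, "\n")
  cat(sprintf("  mu = %.4f (se %.4f), p = %.3g; tau^2 = %.5f\n",
              x$mu, x$mu_se, x$mu_p, x$tau2))
  cat(sprintf("  Q = %.2f (df %d, p = %.3g), I2 = %.1f%%, H2 = %s\n",
              x$Q, x$df, x$Q_p, x$I2,
              if (is.na(x$H2)) "NA" else sprintf("%.2f", x$H2)))
  cat(sprintf("  local false sign rate = %.3g\n", x$lfsr))
  invisible(x)
}

#' Null concordance probability for TCR twins
#'
#' Probability that two cells drawn at random (without replacement) from the
#' pooled twin-member cells share a cluster: with `n_j` of the `N` cells in
#' cluster `j`, `P_j = n_j (n_j - 1) / (N (N - 1))` and
#' `P_null = sum_j P_j`.
#'
#' @param cluster_counts Non-negative integer vector of per-cluster counts
#'   (`N = sum >= 2`).
#' @return Object of class `twin_null` with `$p_j` and `$p_null`.
#' @export
twin_pnull <- function(cluster_counts) {
  if (any(cluster_counts < 0) || any(cluster_counts != round(cluster_counts)))
    .stopf("'cluster_counts' must be non-negative integers")
  N <- sum(cluster_counts)
  if (N < 2) .stopf("need at least 2 cells in total")
  p_j <- cluster_counts * (cluster_counts - 1) / (N * (N - 1))
  structure(list(counts = cluster_counts, p_j = p_j, p_null = sum(p_j), N = N),
            class = "twin_null")
}

#' @export
print.twin_null <- function(x, ...) {
  cat(sprintf("Twin null concordance: P_null = %.4f over %d cells in %d clusters\n",
              x$p_null, x$N, length(x$counts)))
  invisible(x)
}

#' Exact upper-tail binomial test for twin concordance
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p_null)` by direct summation of
#' the tail terms in log space (log-gamma binomial coefficients combined by
#' log-sum-exp), which stays accurate for tail probabilities far below
#' 1e-30.
#'
#' @param n_pairs Number of twin pairs (trials).
#' @param n_concordant Observed concordant pairs.
#' @param p_null Null concordance probability, strictly inside (0, 1); a
#'   `twin_null` object is also accepted.
#' @return Object of class `twin_test` with `p_value`, `log10_p`, and the
#'   expected concordant count under the null.
#' @export
twin_binomial_test <- function(n_pairs, n_concordant, p_null) {
  if (inherits(p_null, "twin_null")) p_null <- p_null$p_null
  if (!is.numeric(p_null) || p_null <= 0 || p_null >= 1)
    .stopf("'p_null' must lie strictly between 0 and 1")
  if (n_concordant < 0 || n_concordant > n_pairs)
    .stopf("'n_concordant' must lie in [0, n_pairs]")
  ks <- seq.int(n_concordant, n_pairs)
  logterms <- lgamma(n_pairs + 1) - lgamma(ks + 1) - lgamma(n_pairs - ks + 1) +
    ks * log(p_null) + (n_pairs - ks) * log1p(-p_null)
  logp <- min(.logsumexp(logterms), 0)
  structure(list(n_pairs = n_pairs, n_concordant = n_concordant,
                 p_null = p_null, p_value = exp(logp),
                 log10_p = logp / log(10),
                 expected = n_pairs * p_null),
            class = "twin_test")
}

#' @export
print.twin_test <- function(x, ...) {
  cat(sprintf("Exact binomial twin test: %d concordant of %d pairs (expected %.1f)\n",
              x$n_concordant, x$n_pairs, x$expected))
  cat(sprintf("  upper-tail p = %.3g (log10 p = %.2f)\n", x$p_value, x$log10_p))
  invisible(x)
}

#' Down-sample cells and repeat an association test
#'
#' Draws a uniform subsample without replacement (deterministic per seed)
#' and reruns the supplied test on it; used as a power-matched control, e.g.
#' matching productive-TCR sample sizes to the nonproductive set.
#'
#' @param cells A data frame of cells (rows are sampling units).
#' @param n_target Subsample size, at most `nrow(cells)`.
#' @param seed Integer seed.
#' @param test A function taking the subsampled data frame and returning the
#'   association result.
#' @return The value of `test` on the subsample, with the selected row
#'   indices attached as attribute `"rows"`.
#' @export
downsample_match <- function(cells, n_target, seed, test) {
  if (n_target > nrow(cells))
    .stopf("n_target (%d) exceeds available cells (%d)", n_target, nrow(cells))
  rows <- .with_seed(seed, sort(sample.int(nrow(cells), n_target)))
  out <- test(cells[rows, , drop = FALSE])
  attr(out, "rows") <- rows
  out
}
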