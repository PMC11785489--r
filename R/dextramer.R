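#' Assemble a multiplexed Dextramer panel
#'
#' Bundles the cells x dextramers UMI count matrix with the identities of
#' the negative-control dextramers and the per-cell technical covariates
#' used for background correction: TCR expression (log counts-per-10k of
#' CDR3 UMIs, alpha + beta summed), CLR-normalized CD3 and CD8 surface
#' expression, and donor.
#'
#' @param counts Non-negative integer matrix, cells x dextramers, with
#'   column names.
#' @param controls Character vector of negative-control column names
#'   (at least one).
#' @param covariates Data frame with columns `tcr_exp`, `cd3_exp`,
#'   `cd8_exp`, `donor_id`, one row per cell.
#' @return Object of class `dextramer_panel`.
#' @export
dextramer_panel <- function(counts, controls, covariates) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) .stopf("'counts' needs column names")
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("'counts' must be non-negative integers")
  if (length(controls) < 1L || !all(controls %in% colnames(counts)))
    .stopf("'controls' must name at least one counts column")
  need <- c("tcr_exp", "cd3_exp", "cd8_exp", "donor_id")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    .stopf("covariates are missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(covariates) != nrow(counts))
    .stopf("covariates must have one row per cell")
  structure(list(counts = counts, controls = controls,
                 covariates = as.data.frame(covariates)),
            class = "dextramer_panel")
}

#' @export
print.dextramer_panel <- function(x, ...) {
  cat("Dextramer panel:", nrow(x$counts), "cells x", ncol(x$counts),
      "dextramers (", length(x$controls), "negative controls )\n")
  invisible(x)
}

#' Fit the negative-binomial background model for one dextramer
#'
#' Regresses the target dextramer's UMI counts on the negative-control UMI
#' counts and the technical covariates (TCR, CD3, CD8 expression) plus donor
#' indicators (reference-level dummy coding, lexicographically first donor
#' as reference; donor terms only when the panel spans several donors),
#' with a log link and dispersion estimated by maximum likelihood
#' (`MASS::glm.nb`). The fitted mean is the technically expected count used
#' by [normalize_stain()].
#'
#' @param panel A [dextramer_panel()].
#' @param dex_id Target dextramer column name (not a negative control).
#' @return Object of class `dex_background` wrapping the fit, with
#'   `$converged` flagged rather than failing on shaky fits.
#' @export
fit_background <- function(panel, dex_id) {
  stopifnot(inherits(panel, "dextramer_panel"))
  if (!dex_id %in% colnames(panel$counts))
    .stopf("unknown dextramer '%s'", dex_id)
  if (dex_id %in% panel$controls)
    .stopf("'%s' is a negative control; fit a non-control dextramer", dex_id)
  y <- panel$counts[, dex_id]
  if (all(y == 0)) .stopf("all-zero counts for '%s'; background fit is degenerate", dex_id)
  nc <- panel$counts[, panel$controls, drop = FALSE]
  colnames(nc) <- paste0("nc_", seq_len(ncol(nc)))
  df <- data.frame(y = y, nc, tcr_exp = panel$covariates$tcr_exp,
                   cd3_exp = panel$covariates$cd3_exp,
                   cd8_exp = panel$covariates$cd8_exp)
  donor <- factor(panel$covariates$donor_id,
                  levels = sort(unique(as.character(panel$covariates$donor_id))))
  if (nlevels(donor) > 1L) df$donor <- donor
  converged <- TRUE
  fit <- withCallingHandlers(
    MASS::glm.nb(y ~ ., data = df),
    warning = function(w) {
      if (grepl("iteration limit|converge", conditionMessage(w),
                ignore.case = TRUE)) converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!isTRUE(fit$converged)) converged <- FALSE
  structure(list(fit = fit, dex_id = dex_id, theta = fit$theta,
                 coefficients = stats::coef(fit), converged = converged),
            class = "dex_background")
}

#' @export
print.dex_background <- function(x, ...) {
  cat("Negative-binomial background fit for '", x$dex_id, "'",
      if (!x$converged) "  [did not converge]", "\n", sep = "")
  cat(sprintf("  dispersion theta = %.3f, %d coefficients\n",
              x$theta, length(x$coefficients)))
  invisible(x)
}

#' Normalize Dextramer staining against the fitted background
#'
#' Replaces each cell's raw UMI count with
#' `Dnorm_i = log(observed_i / expected_i + 1)`, where `expected_i` is the
#' negative-binomial fitted mean from the technical covariates. `Dnorm` is
#' zero for zero observed counts, strictly increasing in the observed count
#' for fixed expected count, and non-negative.
#'
#' @param fit A [fit_background()] result.
#' @param panel The panel the fit came from.
#' @param dex_id Dextramer column (defaults to the fitted one).
#' @return Object of class `dex_stain`: data frame with `observed`,
#'   `expected`, `dnorm` plus the dextramer id.
#' @export
normalize_stain <- function(fit, panel, dex_id = fit$dex_id) {
  stopifnot(inherits(fit, "dex_background"), inherits(panel, "dextramer_panel"))
  if (!fit$converged)
    warning("background fit did not converge; Dnorm values may be unstable")
  observed <- panel$counts[, dex_id]
  expected <- stats::fitted(fit$fit)
  stopifnot(all(expected > 0))  # guaranteed by the log link
  out <- data.frame(observed = observed, expected = expected,
                    dnorm = log(observed / expected + 1))
  structure(list(values = out, dex_id = dex_id), class = "dex_stain")
}

#' @export
print.dex_stain <- function(x, ...) {
  cat("Normalized Dextramer staining for '", x$dex_id, "': ",
      nrow(x$values), " cells, Dnorm range [",
      sprintf("%.3f, %.3f", min(x$values$dnorm), max(x$values$dnorm)),
      "]\n", sep = "")
  invisible(x)
}

#' Call antigen binders from normalized staining
#'
#' A cell is a binder when its `Dnorm` meets or exceeds the dextramer's
#' threshold. Thresholds are analysis configuration (set per dextramer,
#' conventionally at the antimode of the bimodal `Dnorm` distribution; see
#' [find_antimode()] for an automatic convenience).
#'
#' @param stain A [normalize_stain()] result.
#' @param threshold Numeric threshold for this dextramer.
#' @return Logical vector of binder calls.
#' @export
call_binders <- function(stain, threshold) {
  stopifnot(inherits(stain, "dex_stain"))
  if (missing(threshold) || is.null(threshold) || is.na(threshold))
    .stopf("no threshold configured for dextramer '%s'", stain$dex_id)
  stain$values$dnorm >= threshold
}

#' Flag cells called as binders of multiple dextramers
#'
#' @param calls Named list of logical binder-call vectors (one per
#'   dextramer, aligned cells).
#' @return Integer vector: per cell, the number of dextramers bound.
#' @export
multi_binders <- function(calls) {
  m <- do.call(cbind, calls)
  rowSums(m)
}

#' Kernel-density antimode between the two main modes
#'
#' Convenience extension beyond manually chosen thresholds: locates the
#' minimum of a kernel density estimate between its two highest local
#' maxima, the natural binder/background cut for a bimodal `Dnorm`
#' distribution.
#'
#' @param x Numeric values (e.g. `Dnorm`).
#' @param adjust Bandwidth multiplier; the default oversmooths deliberately
#'   so that count-discreteness wiggles near zero do not masquerade as
#'   modes.
#' @param ... Passed to [stats::density()].
#' @return The antimode location, or `NA` if the density is unimodal.
#' @export
find_antimode <- function(x, adjust = 3, ...) {
  d <- stats::density(x, adjust = adjust, ...)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(loc_max) < 2L) return(NA_real_)
  top2 <- sort(loc_max[order(y[loc_max], decreasing = TRUE)][1:2])
  between <- seq.int(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' TCR-mem association within one antigen-specific population
#'
#' Logistic regression of memory state on the TCR-mem score, adjusting for
#' normalized Dextramer staining (`Dnorm`, a proxy for TCR-pMHC affinity)
#' and donor indicators when the population spans several donors:
#' `logit P(memory_i) = beta_mem * TCRmem_i + beta_D * Dnorm_i +
#' donor terms + beta_0`. The population must contain at least `min_clones`
#' distinct clones (one cell per clone, the caller's duty); single-class
#' outcomes are flagged inestimable rather than fitted.
#'
#' @param memory Binary memory-state vector.
#' @param scores TCR-mem scores.
#' @param dnorm Normalized staining values.
#' @param donor_ids Donor per cell.
#' @param antigen Antigen/dextramer label (bookkeeping).
#' @param min_clones Eligibility threshold on distinct clones.
#' @param one_tailed Report the upper-tailed p value.
#' @return Object of class `antigen_assoc`: `beta`, `se`, `p`, `n_clones`,
#'   `n_donors`, `eligible`, `estimable`.
#' @export
antigen_assoc <- function(memory, scores, dnorm, donor_ids,
                          antigen = "antigen", min_clones = 10L,
                          one_tailed = FALSE) {
  memory <- as.integer(as.logical(memory))
  n <- length(memory)
  eligible <- n >= min_clones
  estimable <- length(unique(memory)) == 2L
  beta <- se <- p <- NA_real_
  n_donors <- length(unique(donor_ids))
  if (eligible && estimable) {
    df <- data.frame(memory = memory, score = scores, dnorm = dnorm)
    if (n_donors > 1L)
      df$donor <- factor(donor_ids,
                         levels = sort(unique(as.character(donor_ids))))
    fit <- stats::glm(memory ~ ., data = df, family = stats::binomial())
    co <- summary(fit)$coefficients
    beta <- co["score", 1]; se <- co["score", 2]
    z <- beta / se
    p <- if (one_tailed) stats::pnorm(z, lower.tail = FALSE)
         else 2 * stats::pnorm(-abs(z))
  }
  structure(list(antigen = antigen, beta = beta, se = se, p = p,
                 n_clones = n, n_donors = n_donors,
                 eligible = eligible, estimable = estimable),
            class = "antigen_assoc")
}

#' @export
print.antigen_assoc <- function(x, ...) {
  cat("Antigen-specific TCR-mem association ('", x$antigen, "')\n", sep = "")
  if (!x$eligible)
    cat("  ineligible:", x$n_clones, "clones (need >= 10)\n")
  else if (!x$estimable)
    cat("  inestimable: single-class memory outcome\n")
  else
    cat(sprintf("  beta = %.4f (se %.4f), p = %.3g, %d clones, %d donor(s)\n",
                x$beta, x$se, x$p, x$n_clones, x$n_donors))
  invisible(x)
}

#' Meta-analysis of TCR-mem effects across antigen-specific populations
#'
#' Pools eligible, estimable per-antigen effects with
#' [random_effects_meta()] (ML heterogeneity).
#'
#' @param results List of [antigen_assoc()] results.
#' @return A `tcr_meta` object.
#' @export
across_antigen_meta <- function(results) {
  ok <- vapply(results, function(r)
    inherits(r, "antigen_assoc") && r$eligible && r$estimable, logical(1))
  if (sum(ok) < 2L)
    .stopf("need at least 2 eligible antigen-specific results (got %d)", sum(ok))
  betas <- vapply(results[ok], `[[`, numeric(1), "beta")
  ses <- vapply(results[ok], `[[`, numeric(1), "se")
  random_effects_meta(betas, ses)
}
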