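#' Train a TCR scoring function
#'
#' Fits a ridge-penalized logistic regression of a binary T cell state on
#' the full TCR feature vector: `logit P(state_i = 1) = sum_j beta_j
#' feature_{j,i} + beta_0`. The penalty is selected by k-fold
#' cross-validation minimising held-out binomial deviance (via
#' `glmnet::cv.glmnet`, `alpha = 0`). Feature scaling statistics are fit on
#' the included training rows and frozen into the model, as are the training
#' mean and standard deviation of the raw score, so that a score of 1 in any
#' dataset means one training-set standard deviation. Rows in `exclude`
#' (e.g. innate-like cells for the CD8/Treg/memory contrasts) contribute
#' neither to fitting nor to standardization. Callers are expected to pass
#' one cell per clone ([sample_one_per_clone()]).
#'
#' Single-chain variants (`chain_mask = "alpha_only"` / `"beta_only"`) fit
#' only the chosen chain's features; the other chain's weights are exactly
#' zero, so scores are invariant to its sequence content.
#'
#' @param features Raw (unscaled) [featurize_tcrs()] matrix of the training
#'   cells.
#' @param labels Binary vector (0/1 or logical), one per row.
#' @param target Name of the target state (bookkeeping only).
#' @param folds Number of CV folds.
#' @param exclude Optional logical vector of rows to drop entirely.
#' @param chain_mask `"both"`, `"alpha_only"`, or `"beta_only"`.
#' @param lambda Optional fixed penalty; skips CV when supplied.
#' @param nlambda Length of the automatic penalty path.
#' @param seed Seed for the CV fold assignment.
#' @return An object of class `tcr_scorer` holding the weight vector,
#'   intercept, selected penalty, frozen scaling, score standardization
#'   constants, chain mask, and registry hash.
#' @export
train_scorer <- function(features, labels, target = "state", folds = 5L,
                         exclude = NULL, chain_mask = c("both", "alpha_only",
                                                        "beta_only"),
                         lambda = NULL, nlambda = 30L, seed = 1L) {
  stopifnot(inherits(features, "tcr_features"))
  chain_mask <- match.arg(chain_mask)
  n <- nrow(features$x)
  labels <- as.integer(as.logical(labels))
  if (length(labels) != n) .stopf("'labels' must have one entry per cell")
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  keep <- !exclude
  if (length(unique(labels[keep])) < 2L)
    .stopf("labels must contain both classes after exclusions")

  train <- subset_features(features, keep)
  scaling <- fit_scaling(train)
  Xs <- apply_scaling(train, scaling)$x
  y <- labels[keep]

  cols <- .chain_columns(features$registry, chain_mask)
  Xfit <- Xs[, cols, drop = FALSE]

  foldid <- .with_seed(seed, sample(rep(seq_len(folds), length.out = sum(keep))))
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(Xfit, y, family = "binomial", alpha = 0,
                            foldid = foldid, nlambda = nlambda,
                            type.measure = "deviance", standardize = FALSE)
    lambda <- cv$lambda.min
    cv_table <- data.frame(lambda = cv$lambda, deviance = cv$cvm)
  } else {
    cv_table <- NULL
  }
  fit <- glmnet::glmnet(Xfit, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta_sub <- as.numeric(fit$beta)
  w <- numeric(ncol(Xs))
  w[cols] <- beta_sub
  names(w) <- features$registry$features$name
  b0 <- as.numeric(fit$a0)

  raw <- as.vector(Xs %*% w) + b0
  model <- structure(list(
    target = target, weights = w, intercept = b0, lambda = lambda,
    chain_mask = chain_mask, scaling = scaling,
    score_mean = mean(raw), score_sd = stats::sd(raw),
    registry_hash = features$registry$hash, n_train = sum(keep),
    cv = cv_table), class = "tcr_scorer")
  model
}

# registry columns belonging to the alpha/beta chain (all for "both")
.chain_columns <- function(registry, chain_mask) {
  if (chain_mask == "both") return(seq_len(nrow(registry$features)))
  want <- if (chain_mask == "alpha_only") c("CDR1a", "CDR2a", "CDR3a")
          else c("CDR1b", "CDR2b", "CDR3b")
  which(registry$features$loop %in% want)
}

#' @export
print.tcr_scorer <- function(x, ...) {
  cat("TCR scoring function '", x$target, "' (chain: ", x$chain_mask, ")\n",
      sep = "")
  cat(sprintf("  ridge lambda %.4g, %d training cells, %d nonzero weights\n",
              x$lambda, x$n_train, sum(x$weights != 0)))
  cat(sprintf("  train raw score mean %.4f, sd %.4f\n",
              x$score_mean, x$score_sd))
  invisible(x)
}

#' @export
coef.tcr_scorer <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
summary.tcr_scorer <- function(object, n_top = 10L, ...) {
  ord <- order(abs(object$weights), decreasing = TRUE)[seq_len(n_top)]
  top <- data.frame(feature = names(object$weights)[ord],
                    weight = unname(object$weights[ord]))
  out <- list(target = object$target, lambda = object$lambda,
              chain_mask = object$chain_mask, top = top)
  class(out) <- "summary.tcr_scorer"
  out
}

#' @export
print.summary.tcr_scorer <- function(x, ...) {
  cat("TCR scoring function '", x$target, "', top features by |weight|:\n",
      sep = "")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Score TCRs with a trained scoring function
#'
#' Applies the model's frozen train-set feature scaling, computes the linear
#' score `beta . x + beta_0`, and standardizes by the training score mean
#' and standard deviation. Refuses feature matrices built under a different
#' registry.
#'
#' @param object A `tcr_scorer`.
#' @param features Raw (unscaled) `tcr_features` for the cells to score.
#' @param type `"score"` (standardized, default), `"link"` (raw linear
#'   predictor), or `"response"` (fitted probability).
#' @param ... Unused.
#' @return Numeric vector, one value per cell.
#' @export
predict.tcr_scorer <- function(object, features, type = c("score", "link",
                                                          "response"), ...) {
  stopifnot(inherits(features, "tcr_features"))
  type <- match.arg(type)
  if (!identical(object$registry_hash, features$registry$hash))
    .stopf("feature registry mismatch: model %s vs data %s",
           object$registry_hash, features$registry$hash)
  Xs <- apply_scaling(features, object$scaling)$x
  raw <- as.vector(Xs %*% object$weights) + object$intercept
  switch(type,
         score = (raw - object$score_mean) / object$score_sd,
         link = raw,
         response = stats::plogis(raw))
}

#' Grouped CDR contribution shares of a scoring function
#'
#' Estimates how much each CDR loop contributes to the score by masking each
#' loop's feature group to zero (post-scaling) and measuring the mean
#' absolute change in score across the supplied cells (conventionally the
#' positive-class cells). Shares are normalized to sum to 1. This is a
#' partition-masking simplification of Shapley-style feature attribution:
#' groups are removed one at a time rather than over all coalitions.
#'
#' @param model A `tcr_scorer`.
#' @param features Raw `tcr_features` for the cells to attribute over.
#' @param groups Optional named list of feature-index groups forming a
#'   partition of the registry; defaults to the six CDR loops.
#' @return Data frame (class `tcr_importance`) with `group`, `contribution`
#'   (mean |delta score|), and `share`.
#' @export
cdr_contribution <- function(model, features, groups = NULL) {
  stopifnot(inherits(model, "tcr_scorer"), inherits(features, "tcr_features"))
  if (!identical(model$registry_hash, features$registry$hash))
    .stopf("feature registry mismatch")
  p <- length(model$weights)
  if (is.null(groups))
    groups <- split(seq_len(p), features$registry$features$loop)
  idx <- sort(unlist(groups, use.names = FALSE))
  if (!identical(idx, seq_len(p)))
    .stopf("'groups' must partition the %d registry features", p)

  Xs <- apply_scaling(features, model$scaling)$x
  full <- as.vector(Xs %*% model$weights)
  contrib <- vapply(groups, function(g) {
    part <- as.vector(Xs[, g, drop = FALSE] %*% model$weights[g])
    mean(abs(part)) / model$score_sd  # |full - masked| = |group part|
  }, numeric(1))
  tot <- sum(contrib)
  if (tot <= 0) .stopf("model has no nonzero weights; contributions undefined")
  out <- data.frame(group = names(groups), contribution = unname(contrib),
                    share = unname(contrib) / tot, stringsAsFactors = FALSE)
  class(out) <- c("tcr_importance", "data.frame")
  out
}

#' Serialize or restore a scoring function
#'
#' The JSON document embeds the registry hash, weights, intercept, penalty,
#' scaling statistics, score standardization constants, and chain mask; a
#' restored model reproduces identical scores.
#'
#' @param model A `tcr_scorer`.
#' @param path JSON path.
#' @export
write_scorer <- function(model, path) {
  stopifnot(inherits(model, "tcr_scorer"))
  jsonlite::write_json(list(
    schema = "tcr_scorer/1",
    target = model$target, chain_mask = model$chain_mask,
    weights = as.list(model$weights), intercept = model$intercept,
    lambda = model$lambda, score_mean = model$score_mean,
    score_sd = model$score_sd, registry_hash = model$registry_hash,
    n_train = model$n_train,
    scaling = list(mean = model$scaling$mean, sd = model$scaling$sd,
                   zero_var = model$scaling$zero_var,
                   registry_hash = model$scaling$registry_hash,
                   n = model$scaling$n)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "tcr_scorer/1"))
    .stopf("unrecognized scorer schema '%s'", doc$schema)
  scaling <- structure(list(mean = doc$scaling$mean, sd = doc$scaling$sd,
                            zero_var = as.logical(doc$scaling$zero_var),
                            registry_hash = doc$scaling$registry_hash,
                            n = doc$scaling$n), class = "tcr_scaling")
  structure(list(target = doc$target, weights = unlist(doc$weights),
                 intercept = doc$intercept, lambda = doc$lambda,
                 chain_mask = doc$chain_mask, scaling = scaling,
                 score_mean = doc$score_mean, score_sd = doc$score_sd,
                 registry_hash = doc$registry_hash, n_train = doc$n_train,
                 cv = NULL), class = "tcr_scorer")
}
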