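#' Regularized canonical correlation analysis
#'
#' Finds paired linear combinations of two views (TCR sequence features and
#' cell-state features, e.g. expression PCs) with maximal correlation,
#' stabilised for collinear or high-dimensional inputs by adding ridge
#' penalties to each view's covariance matrix. The solution whitens each
#' view by `(Cov + lambda I)^(-1/2)` and takes the top singular triplets of
#' the whitened cross-covariance; at `lambda = 0` this reduces to classical
#' CCA. Canonical correlations are reported as empirical correlations of the
#' canonical scores on the input data. Weight columns are sign-fixed so the
#' largest-magnitude x-weight is positive; `flip` allows user-directed sign
#' reversals of selected variates.
#'
#' @param X,Y Numeric matrices with aligned rows (one cell per clone).
#' @param lambda_x,lambda_y Non-negative ridge penalties.
#' @param K Number of canonical variates (default `min(ncol(X), ncol(Y))`).
#' @param flip Optional integer vector of variates whose signs to reverse.
#' @return An object of class `tcr_rcca` with `$xcoef`, `$ycoef`, `$cor`
#'   (empirical canonical correlations), `$d` (regularized singular values),
#'   the penalties, and column centers for projection.
#' @export
fit_rcca <- function(X, Y, lambda_x = 0, lambda_y = 0,
                     K = min(ncol(X), ncol(Y)), flip = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    .stopf("X and Y must have the same number of rows (%d vs %d)",
           nrow(X), nrow(Y))
  if (lambda_x < 0 || lambda_y < 0) .stopf("ridge penalties must be >= 0")
  n <- nrow(X)
  if (n < 3L) .stopf("need at least 3 observations")
  K <- min(K, ncol(X), ncol(Y))

  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  Cx <- crossprod(Xc) / (n - 1) + diag(lambda_x, ncol(X))
  Cy <- crossprod(Yc) / (n - 1) + diag(lambda_y, ncol(Y))
  Cxy <- crossprod(Xc, Yc) / (n - 1)

  Wx <- .inv_sqrt(Cx); Wy <- .inv_sqrt(Cy)
  sv <- svd(Wx %*% Cxy %*% Wy, nu = K, nv = K)
  A <- Wx %*% sv$u[, seq_len(K), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(K), drop = FALSE]

  for (k in seq_len(K)) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) { A[, k] <- -A[, k]; B[, k] <- -B[, k] }
  }
  if (!is.null(flip)) {
    flip <- intersect(as.integer(flip), seq_len(K))
    A[, flip] <- -A[, flip]; B[, flip] <- -B[, flip]
  }
  r <- vapply(seq_len(K), function(k)
    stats::cor(Xc %*% A[, k], Yc %*% B[, k])[1, 1], numeric(1))

  structure(list(xcoef = A, ycoef = B, cor = r, d = sv$d[seq_len(K)],
                 lambda_x = lambda_x, lambda_y = lambda_y,
                 xcenter = cx, ycenter = cy, K = K, n = n),
            class = "tcr_rcca")
}

# symmetric inverse square root via eigendecomposition
.inv_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps * max(abs(e$values), 1))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' @export
print.tcr_rcca <- function(x, ...) {
  cat("Regularized CCA (lambda_x = ", format(x$lambda_x),
      ", lambda_y = ", format(x$lambda_y), ", n = ", x$n, ")\n", sep = "")
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$cor), collapse = " "), "\n")
  invisible(x)
}

#' Project data onto fitted canonical variates
#'
#' @param object A `tcr_rcca` model.
#' @param newx,newy Matrices with the training column layout; either may be
#'   `NULL`.
#' @param ... Unused.
#' @return List with `x_scores` and/or `y_scores`.
#' @export
predict.tcr_rcca <- function(object, newx = NULL, newy = NULL, ...) {
  out <- list()
  if (!is.null(newx))
    out$x_scores <- sweep(as.matrix(newx), 2, object$xcenter) %*% object$xcoef
  if (!is.null(newy))
    out$y_scores <- sweep(as.matrix(newy), 2, object$ycenter) %*% object$ycoef
  out
}

#' Tune rCCA ridge penalties by cross-validation
#'
#' Selects the `(lambda_x, lambda_y)` pair maximising the mean held-out
#' correlation of the first canonical variate across folds. Fold assignment
#' is seeded, so the selection is reproducible; ties favour the largest
#' penalty pair (the more conservative model).
#'
#' @param X,Y Row-aligned matrices.
#' @param lambda_grid Numeric vector of candidate penalties (used for both
#'   views; all pairs are evaluated).
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @return List with `lambda_x`, `lambda_y`, and the CV table `cv`.
#' @export
tune_rcca <- function(X, Y, lambda_grid, folds = 5L, seed = 1L) {
  if (length(lambda_grid) == 0L) .stopf("'lambda_grid' must be non-empty")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold <- .with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  grid <- expand.grid(lambda_x = lambda_grid, lambda_y = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_cor <- NA_real_
  for (g in seq_len(nrow(grid))) {
    rs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- fit_rcca(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      grid$lambda_x[g], grid$lambda_y[g], K = 1L)
      sc <- predict(fit, newx = X[!tr, , drop = FALSE],
                    newy = Y[!tr, , drop = FALSE])
      stats::cor(sc$x_scores[, 1], sc$y_scores[, 1])
    }, numeric(1))
    grid$cv_cor[g] <- mean(rs, na.rm = TRUE)
  }
  best <- which(grid$cv_cor == max(grid$cv_cor))
  best <- best[length(best)]  # ties -> largest penalties (grid is ascending)
  list(lambda_x = grid$lambda_x[best], lambda_y = grid$lambda_y[best],
       cv = grid)
}

#' Permutation significance test for canonical correlations
#'
#' Breaks the row alignment between the two views by permuting Y, refits the
#' rCCA, and records the null canonical correlations. Empirical p values are
#' `(1 + #(null >= observed)) / (n_perm + 1)`, bounded below by
#' `1/(n_perm+1)`. With a held-out set, weights are learned on the training
#' rows each permutation and correlations are evaluated on both subsets.
#'
#' @param X,Y Row-aligned matrices.
#' @param lambda_x,lambda_y Ridge penalties.
#' @param K Number of variates to test.
#' @param n_perm Number of permutations (must be >= 1).
#' @param seed RNG seed.
#' @param holdout Optional logical vector marking held-out rows.
#' @return An object of class `tcr_rcca_perm` with observed correlations,
#'   p values (`$p_train`, and `$p_test` when a holdout is given), the null
#'   distribution matrix, and `n_perm`.
#' @export
rcca_permutation_test <- function(X, Y, lambda_x = 0, lambda_y = 0,
                                  K = min(ncol(X), ncol(Y)), n_perm = 1000L,
                                  seed = 1L, holdout = NULL) {
  if (n_perm < 1L) .stopf("'n_perm' must be at least 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(holdout)) holdout <- rep(FALSE, n)
  if (length(holdout) != n) .stopf("'holdout' must have one entry per row")
  tr <- !holdout
  K <- min(K, ncol(X), ncol(Y))

  eval_fit <- function(Yall) {
    fit <- fit_rcca(X[tr, , drop = FALSE], Yall[tr, , drop = FALSE],
                    lambda_x, lambda_y, K = K)
    r_tr <- fit$cor
    r_te <- if (any(holdout)) {
      sc <- predict(fit, newx = X[holdout, , drop = FALSE],
                    newy = Yall[holdout, , drop = FALSE])
      vapply(seq_len(K), function(k)
        stats::cor(sc$x_scores[, k], sc$y_scores[, k]), numeric(1))
    } else NULL
    list(train = r_tr, test = r_te)
  }

  obs <- eval_fit(Y)
  nulls <- .with_seed(seed, {
    lapply(seq_len(n_perm), function(i) eval_fit(Y[sample.int(n), , drop = FALSE]))
  })
  null_train <- do.call(rbind, lapply(nulls, `[[`, "train"))
  p_train <- vapply(seq_len(K), function(k)
    (1 + sum(null_train[, k] >= obs$train[k])) / (n_perm + 1), numeric(1))
  out <- list(cor_train = obs$train, p_train = p_train,
              null_train = null_train, n_perm = n_perm, K = K)
  if (any(holdout)) {
    null_test <- do.call(rbind, lapply(nulls, `[[`, "test"))
    out$cor_test <- obs$test
    out$p_test <- vapply(seq_len(K), function(k)
      (1 + sum(null_test[, k] >= obs$test[k])) / (n_perm + 1), numeric(1))
    out$null_test <- null_test
  }
  structure(out, class = "tcr_rcca_perm")
}

#' @export
print.tcr_rcca_perm <- function(x, ...) {
  cat("rCCA permutation test (", x$n_perm, " permutations)\n", sep = "")
  for (k in seq_len(x$K))
    cat(sprintf("  CV%d: r = %.3f, p = %.4g\n", k, x$cor_train[k], x$p_train[k]))
  invisible(x)
}
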