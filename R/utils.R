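# shared internal helpers

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# strip IMGT allele suffixes ("TRAV1-2*01" -> "TRAV1-2")
.strip_allele <- function(x) sub("\\*.*$", "", x)

# rank-based area under the ROC curve (Mann-Whitney statistic)
.auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
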