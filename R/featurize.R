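#' Featurize paired TCR sequences
#'
#' Converts each paired receptor into the registry's fixed-length biophysical
#' feature vector. CDR1/CDR2 loop sequences come from the V-gene table;
#' CDR3 loops are the junction interiors (the invariant C and F/W anchors
#' are dropped). Loops are placed onto slots by middle-out gap alignment
#' ([gap_align()]); slots left empty by short loops are recorded in the gap
#' mask and carry the value 0 (positional and interaction features only --
#' composition and length features are never masked). Composition features
#' are percentages of the true loop length; interaction features are
#' products of the Atchley factors of adjacent occupied slots.
#'
#' @param tcrs Paired-TCR data frame (post-[pair_and_qc()]).
#' @param gene_table V-gene reference from [read_gene_table()].
#' @param registry A [build_registry()] object.
#' @return An object of class `tcr_features`: list with the raw numeric
#'   matrix `$x` (cells x features), logical gap mask `$mask`, `$registry`,
#'   `$cell_ids`, and `$scaled = FALSE`.
#' @export
featurize_tcrs <- function(tcrs, gene_table, registry = build_registry()) {
  .check_paired(tcrs)
  stopifnot(inherits(registry, "tcr_registry"))
  n <- nrow(tcrs)
  loops <- names(registry$slots)
  slots <- registry$slots

  gta <- gene_table[gene_table$locus == "alpha", , drop = FALSE]
  gtb <- gene_table[gene_table$locus == "beta", , drop = FALSE]
  ia <- match(.strip_allele(tcrs$va), gta$v_gene)
  ib <- match(.strip_allele(tcrs$vb), gtb$v_gene)
  if (anyNA(ia))
    .stopf("V gene '%s' not found in gene table (alpha)",
           tcrs$va[which(is.na(ia))[1]])
  if (anyNA(ib))
    .stopf("V gene '%s' not found in gene table (beta)",
           tcrs$vb[which(is.na(ib))[1]])

  seqs <- list(
    CDR1a = gta$cdr1_aa[ia], CDR2a = gta$cdr2_aa[ia],
    CDR3a = substr(tcrs$cdr3a, 2L, nchar(tcrs$cdr3a) - 1L),
    CDR1b = gtb$cdr1_aa[ib], CDR2b = gtb$cdr2_aa[ib],
    CDR3b = substr(tcrs$cdr3b, 2L, nchar(tcrs$cdr3b) - 1L)
  )
  for (lp in loops) {
    too_long <- nchar(seqs[[lp]]) > slots[lp]
    if (any(too_long))
      .stopf("%s sequence '%s' exceeds its %d slots", lp,
             seqs[[lp]][which(too_long)[1]], slots[lp])
    if (any(!nzchar(seqs[[lp]])))
      .stopf("empty %s loop sequence", lp)
  }

  # residue index matrix: cells x total slots, NA marks a gap slot
  total <- sum(slots)
  offs <- c(0L, cumsum(slots))[seq_along(slots)]
  names(offs) <- loops
  ridx <- matrix(NA_integer_, n, total)
  for (lp in loops) {
    s <- seqs[[lp]]
    for (L in unique(nchar(s))) {
      rows <- which(nchar(s) == L)
      chars <- matrix(unlist(strsplit(s[rows], ""), use.names = FALSE),
                      nrow = length(rows), ncol = L, byrow = TRUE)
      code <- matrix(match(chars, .aa_letters), nrow = length(rows))
      if (anyNA(code))
        .stopf("non-standard amino-acid letter in %s", lp)
      ridx[rows, offs[lp] + .occupied_slots(L, slots[lp])] <- code
    }
  }

  feats <- registry$features
  X <- matrix(0, n, nrow(feats))
  M <- matrix(FALSE, n, nrow(feats))
  colnames(X) <- feats$name

  # positional block: Atchley factor of the residue occupying each slot
  ip <- which(feats$kind == "position_atchley")
  slot_abs <- offs[feats$loop[ip]] + feats$slot[ip]
  for (j in seq_along(ip)) {
    code <- ridx[, slot_abs[j]]
    gap <- is.na(code)
    v <- .atchley[code, feats$factor[ip[j]]]
    v[gap] <- 0
    X[, ip[j]] <- v
    M[, ip[j]] <- gap
  }

  # composition: 100 * count(letter) / loop length
  looplen <- sapply(loops, function(lp) nchar(seqs[[lp]]))
  if (n == 1L) looplen <- matrix(looplen, nrow = 1, dimnames = list(NULL, loops))
  ic <- which(feats$kind == "composition")
  for (j in ic) {
    lp <- feats$loop[j]
    cols <- offs[lp] + seq_len(slots[lp])
    cnt <- rowSums(ridx[, cols, drop = FALSE] == match(feats$letter[j], .aa_letters),
                   na.rm = TRUE)
    X[, j] <- 100 * cnt / looplen[, lp]
  }

  il <- which(feats$kind == "length")
  for (j in il) X[, j] <- looplen[, feats$loop[j]]

  # adjacency interactions: products of factors of neighbouring slots
  ii <- which(feats$kind == "adjacency_interaction")
  if (length(ii)) {
    c1 <- ridx[, offs[feats$loop[ii]] + feats$slot[ii], drop = FALSE]
    for (j in seq_along(ii)) {
      k <- ii[j]
      codeA <- ridx[, offs[feats$loop[k]] + feats$slot[k]]
      codeB <- ridx[, offs[feats$loop[k]] + feats$slot2[k]]
      gap <- is.na(codeA) | is.na(codeB)
      v <- .atchley[codeA, feats$factor[k]] * .atchley[codeB, feats$factor2[k]]
      v[gap] <- 0
      X[, k] <- v
      M[, k] <- gap
    }
  }

  structure(list(x = X, mask = M, registry = registry,
                 cell_ids = tcrs$cell_id, scaled = FALSE),
            class = "tcr_features")
}

#' @export
print.tcr_features <- function(x, ...) {
  cat("TCR feature matrix: ", nrow(x$x), " cells x ", ncol(x$x),
      " features (", if (x$scaled) "scaled" else "raw", ")\n", sep = "")
  cat("  gap entries:", sum(x$mask), "\n")
  invisible(x)
}

#' Subset a feature matrix by rows
#'
#' @param feats A `tcr_features` object.
#' @param rows Integer or logical row index.
#' @return The row-subset `tcr_features`.
#' @export
subset_features <- function(feats, rows) {
  stopifnot(inherits(feats, "tcr_features"))
  feats$x <- feats$x[rows, , drop = FALSE]
  feats$mask <- feats$mask[rows, , drop = FALSE]
  feats$cell_ids <- feats$cell_ids[rows]
  feats
}

#' Train-set feature scaling
#'
#' `fit_scaling()` estimates each feature's mean and standard deviation over
#' the non-gap entries of a (training) feature matrix. `apply_scaling()`
#' standardizes a matrix with frozen statistics: non-gap entries become
#' `(x - mean) / sd`, gap entries become exactly 0, and zero-variance
#' features map to 0. Applying train-set statistics to external data leaves
#' the statistics untouched, so one scaled unit always means one training
#' standard deviation.
#'
#' @param feats A raw `tcr_features` matrix.
#' @return `fit_scaling()`: an object of class `tcr_scaling` (per-feature
#'   `mean`, `sd`, `zero_var` flag, registry hash). `apply_scaling()`: the
#'   scaled `tcr_features`.
#' @export
fit_scaling <- function(feats) {
  stopifnot(inherits(feats, "tcr_features"))
  if (feats$scaled) .stopf("feature matrix is already scaled")
  w <- !feats$mask
  nobs <- colSums(w)
  sx <- colSums(feats$x * w)
  sxx <- colSums(feats$x^2 * w)
  mu <- ifelse(nobs > 0, sx / nobs, 0)
  vr <- ifelse(nobs > 1, (sxx - nobs * mu^2) / (nobs - 1), 0)
  vr[vr < 0] <- 0
  sd <- sqrt(vr)
  structure(list(mean = mu, sd = sd, zero_var = sd == 0 | nobs < 2,
                 registry_hash = feats$registry$hash, n = nrow(feats$x)),
            class = "tcr_scaling")
}

#' @rdname fit_scaling
#' @param stats A `tcr_scaling` object (typically from the training set).
#' @export
apply_scaling <- function(feats, stats) {
  stopifnot(inherits(feats, "tcr_features"), inherits(stats, "tcr_scaling"))
  if (!identical(stats$registry_hash, feats$registry$hash))
    .stopf("scaling stats were fit under a different registry (hash %s vs %s)",
           stats$registry_hash, feats$registry$hash)
  sd <- stats$sd
  sd[stats$zero_var] <- 1  # value forced to 0 below anyway
  xs <- sweep(sweep(feats$x, 2, stats$mean, "-"), 2, sd, "/")
  xs[, stats$zero_var] <- 0
  xs[feats$mask] <- 0
  feats$x <- xs
  feats$scaled <- TRUE
  feats
}

#' Write or read a feature matrix as TSV with a sidecar gap-mask TSV
#'
#' `<prefix>.features.tsv` holds the cells x features values (cell ids in
#' the first column); `<prefix>.mask.tsv` holds the gap mask as 0/1.
#'
#' @param feats A `tcr_features` object.
#' @param prefix Output path prefix.
#' @param registry Registry to attach on read (must match the written
#'   column set).
#' @return `write_features()` returns the two paths invisibly;
#'   `read_features()` the restored `tcr_features`.
#' @export
write_features <- function(feats, prefix) {
  stopifnot(inherits(feats, "tcr_features"))
  fp <- paste0(prefix, ".features.tsv")
  mp <- paste0(prefix, ".mask.tsv")
  xdf <- data.frame(cell_id = feats$cell_ids, feats$x, check.names = FALSE)
  utils::write.table(xdf, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  mdf <- data.frame(cell_id = feats$cell_ids, feats$mask + 0L,
                    check.names = FALSE)
  utils::write.table(mdf, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fp, mp))
}

#' @rdname write_features
#' @export
read_features <- function(prefix, registry) {
  stopifnot(inherits(registry, "tcr_registry"))
  xdf <- utils::read.delim(paste0(prefix, ".features.tsv"),
                           check.names = FALSE)
  mdf <- utils::read.delim(paste0(prefix, ".mask.tsv"), check.names = FALSE)
  if (!identical(names(xdf)[-1], registry$features$name))
    .stopf("feature columns do not match the registry")
  structure(list(x = as.matrix(xdf[, -1, drop = FALSE]),
                 mask = as.matrix(mdf[, -1, drop = FALSE]) > 0,
                 registry = registry, cell_ids = xdf$cell_id,
                 scaled = FALSE),
            class = "tcr_features")
}

#' Serialize or restore scaling statistics
#'
#' @param stats A `tcr_scaling` object.
#' @param path JSON path.
#' @export
write_scaling <- function(stats, path) {
  stopifnot(inherits(stats, "tcr_scaling"))
  jsonlite::write_json(
    list(mean = stats$mean, sd = stats$sd, zero_var = stats$zero_var,
         registry_hash = stats$registry_hash, n = stats$n),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = doc$mean, sd = doc$sd,
                 zero_var = as.logical(doc$zero_var),
                 registry_hash = doc$registry_hash[[1]], n = doc$n[[1]]),
            class = "tcr_scaling")
}
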