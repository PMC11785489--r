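#' Middle-out gap alignment of a loop sequence onto fixed slots
#'
#' Places the first `ceiling(L/2)` residues in the leftmost slots and the
#' remaining `floor(L/2)` residues in the rightmost slots, leaving gap
#' characters in the middle. Loops of variable length thereby keep their
#' termini anchored to fixed slot positions, mirroring IMGT-style numbering
#' where insertions and deletions accumulate at the loop apex.
#'
#' @param seq Amino-acid string, `0 < nchar(seq) <= n_slots`.
#' @param n_slots Number of slots for the loop.
#' @return A string of length `n_slots` with `-` marking gap slots.
#' @examples
#' gap_align("CASSF", 6)   # "CAS-SF"
#' @export
gap_align <- function(seq, n_slots) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    .stopf("'seq' must be a single non-empty string")
  L <- nchar(seq)
  if (L > n_slots)
    .stopf("sequence length %d exceeds %d slots", L, n_slots)
  res <- strsplit(seq, "")[[1]]
  out <- rep("-", n_slots)
  nl <- ceiling(L / 2)
  out[seq_len(nl)] <- res[seq_len(nl)]
  if (L > nl)
    out[(n_slots - (L - nl) + 1L):n_slots] <- res[(nl + 1L):L]
  paste(out, collapse = "")
}

# slot indices occupied by a loop of length L within n_slots (middle-out)
.occupied_slots <- function(L, n_slots) {
  nl <- ceiling(L / 2)
  nr <- L - nl
  c(seq_len(nl), if (nr > 0) (n_slots - nr + 1L):n_slots)
}

.default_slots <- c(CDR1a = 7L, CDR2a = 8L, CDR3a = 15L,
                    CDR1b = 6L, CDR2b = 6L, CDR3b = 16L)

#' Build the TCR feature registry
#'
#' The registry is the ordered catalogue of biophysical features extracted
#' from a paired TCR. With the default slot allocation (58 residue slots:
#' CDR1a=7, CDR2a=8, CDR3a=15, CDR1b=6, CDR2b=6, CDR3b=16, the CDR3 slots
#' covering the junction interior after dropping the invariant C/F-W
#' anchors) it contains:
#' \itemize{
#'   \item 290 positional features (5 Atchley factors per slot);
#'   \item 114 composition features (percentage of each loop occupied by 19
#'     amino acids, glycine excluded as the reference);
#'   \item 6 loop-length features;
#'   \item 25 interaction features per adjacent within-loop slot pair
#'     (pairwise products of the Atchley factors of neighbouring residues).
#' }
#'
#' @param slots Named integer vector of per-loop slot counts; names must be
#'   `CDR1a, CDR2a, CDR3a, CDR1b, CDR2b, CDR3b`.
#' @param interactions Include adjacent-residue interaction features.
#' @return An object of class `tcr_registry`: a list with the feature
#'   descriptor table (`$features`), `$slots`, `$n_features`, and a
#'   structural `$hash` embedded in trained models so that scoring can
#'   refuse registry mismatches.
#' @export
build_registry <- function(slots = .default_slots, interactions = TRUE) {
  loops <- c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b", "CDR3b")
  if (!identical(sort(names(slots)), sort(loops)))
    .stopf("'slots' must be named %s", paste(loops, collapse = ", "))
  slots <- as.integer(slots[loops])
  names(slots) <- loops
  if (any(is.na(slots)) || any(slots <= 0L))
    .stopf("slot counts must be positive integers")

  pos <- do.call(rbind, lapply(loops, function(lp) {
    expand.grid(slot = seq_len(slots[lp]), factor = 1:5,
                KEEP.OUT.ATTRS = FALSE)[, 2:1][, 2:1, drop = FALSE]
  }))
  pos <- data.frame(
    kind = "position_atchley",
    loop = rep(loops, times = 5L * slots),
    slot = unlist(lapply(slots, function(s) rep(seq_len(s), each = 5L))),
    slot2 = NA_integer_,
    factor = unlist(lapply(slots, function(s) rep(1:5, times = s))),
    factor2 = NA_integer_, letter = NA_character_,
    stringsAsFactors = FALSE
  )
  comp_letters <- setdiff(.aa_letters, "G")
  comp <- data.frame(
    kind = "composition",
    loop = rep(loops, each = length(comp_letters)),
    slot = NA_integer_, slot2 = NA_integer_,
    factor = NA_integer_, factor2 = NA_integer_,
    letter = rep(comp_letters, times = length(loops)),
    stringsAsFactors = FALSE
  )
  len <- data.frame(kind = "length", loop = loops, slot = NA_integer_,
                    slot2 = NA_integer_, factor = NA_integer_,
                    factor2 = NA_integer_, letter = NA_character_,
                    stringsAsFactors = FALSE)
  feats <- rbind(pos, comp, len)
  if (interactions) {
    ints <- do.call(rbind, lapply(loops, function(lp) {
      np <- slots[lp] - 1L
      if (np < 1L) return(NULL)
      data.frame(
        kind = "adjacency_interaction", loop = lp,
        slot = rep(seq_len(np), each = 25L),
        slot2 = rep(seq_len(np) + 1L, each = 25L),
        factor = rep(rep(1:5, each = 5L), times = np),
        factor2 = rep(rep(1:5, times = 5L), times = np),
        letter = NA_character_, stringsAsFactors = FALSE
      )
    }))
    feats <- rbind(feats, ints)
  }
  feats$name <- with(feats, ifelse(
    kind == "position_atchley", sprintf("pos_%s_s%d_f%d", loop, slot, factor),
    ifelse(kind == "composition", sprintf("comp_%s_%s", loop, letter),
    ifelse(kind == "length", sprintf("len_%s", loop),
           sprintf("int_%s_s%d.%d_f%dx%d", loop, slot, slot2, factor, factor2)))))
  rownames(feats) <- NULL
  reg <- structure(list(slots = slots, features = feats,
                        n_features = nrow(feats),
                        interactions = interactions, version = "1"),
                   class = "tcr_registry")
  reg$hash <- registry_hash(reg)
  reg
}

#' @rdname build_registry
#' @param registry A `tcr_registry`.
#' @export
registry_hash <- function(registry) {
  stopifnot(inherits(registry, "tcr_registry"))
  canon <- paste(c(registry$version,
                   paste(names(registry$slots), registry$slots, sep = "="),
                   registry$features$name), collapse = "\n")
  v <- utf8ToInt(canon)
  h <- sum(as.numeric(v) * (seq_along(v) %% 97 + 1)) %% 2147483647
  sprintf("reg1-%d-%.0f", nrow(registry$features), h)
}

#' @export
print.tcr_registry <- function(x, ...) {
  counts <- table(x$features$kind)
  cat("TCR feature registry (", x$n_features, " features, ",
      sum(x$slots), " residue slots)\n", sep = "")
  cat("  slots:", paste(names(x$slots), x$slots, sep = "=", collapse = " "), "\n")
  for (k in names(counts)) cat(sprintf("  %-22s %d\n", k, counts[[k]]))
  cat("  hash:", x$hash, "\n")
  invisible(x)
}

#' Serialize or restore a feature registry
#'
#' @param registry A `tcr_registry`.
#' @param path JSON path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   the restored registry (hash recomputed and verified).
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "tcr_registry"))
  jsonlite::write_json(
    list(version = registry$version,
         slots = as.list(registry$slots),
         interactions = registry$interactions,
         hash = registry$hash),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- build_registry(slots = unlist(doc$slots),
                        interactions = isTRUE(doc$interactions))
  if (!identical(reg$hash, doc$hash))
    .stopf("registry hash mismatch: file %s vs rebuilt %s", doc$hash, reg$hash)
  reg
}
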