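#' Pair TCR chains and apply sequence quality control
#'
#' Collapses per-contig chain records into paired alpha/beta receptors and
#' applies the standard repertoire QC in a fixed order, attributing each
#' removed cell to the first failing rule:
#' \enumerate{
#'   \item \strong{multiplet} -- not exactly one productive alpha and one
#'     productive beta chain (nonproductive contigs are dropped first when
#'     `require_productive = TRUE`; dual-alpha and dual-beta cells are
#'     excluded);
#'   \item \strong{unresolved_genes} -- missing/unresolved V or J call,
#'     invalid CDR3 amino-acid string, or a V gene absent from the gene
#'     table;
#'   \item \strong{pseudogene} -- V gene flagged as a pseudogene;
#'   \item \strong{cdr3_length} -- CDR3 length outside the admissible
#'     windows (junction-inclusive strings, alpha 10-17, beta 11-18 by
#'     default).
#' }
#'
#' @param chains Chain data frame from [read_contigs()].
#' @param gene_table V-gene reference from [read_gene_table()].
#' @param min_len_a,max_len_a,min_len_b,max_len_b CDR3 length windows
#'   (amino acids, anchors included).
#' @param donor_ids Optional named character vector mapping `cell_id` to a
#'   donor identifier; unmapped cells get `NA`.
#' @param require_productive Drop nonproductive contigs before pairing.
#'   Set `FALSE` when analysing nonproductive rearrangements.
#' @return A paired-TCR data frame with columns `cell_id`, `donor_id`, `va`,
#'   `ja`, `cdr3a`, `vb`, `jb`, `cdr3b`, with a `"qc_report"` attribute (see
#'   [qc_report()]) counting removals per rule. Empty input yields an empty
#'   frame with a zeroed report.
#' @export
pair_and_qc <- function(chains, gene_table,
                        min_len_a = 10L, max_len_a = 17L,
                        min_len_b = 11L, max_len_b = 18L,
                        donor_ids = NULL, require_productive = TRUE) {
  need <- c("cell_id", "locus", "v_gene", "j_gene", "cdr3_aa", "productive")
  miss <- setdiff(need, names(chains))
  if (length(miss))
    .stopf("chains are missing column(s): %s", paste(miss, collapse = ", "))

  report <- c(multiplet = 0L, unresolved_genes = 0L,
              pseudogene = 0L, cdr3_length = 0L)
  empty <- data.frame(cell_id = character(), donor_id = character(),
                      va = character(), ja = character(), cdr3a = character(),
                      vb = character(), jb = character(), cdr3b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(chains) == 0L) {
    attr(empty, "qc_report") <- list(input_cells = 0L, kept = 0L,
                                     removed = report)
    return(empty)
  }

  all_cells <- unique(chains$cell_id)
  if (require_productive)
    chains <- chains[chains$productive, , drop = FALSE]

  # rule 1: exactly one alpha and one beta among (productive) chains
  na <- table(factor(chains$cell_id[chains$locus == "alpha"], levels = all_cells))
  nb <- table(factor(chains$cell_id[chains$locus == "beta"], levels = all_cells))
  ok1 <- all_cells[na == 1L & nb == 1L]
  report["multiplet"] <- length(all_cells) - length(ok1)

  a <- chains[chains$locus == "alpha" & chains$cell_id %in% ok1, , drop = FALSE]
  b <- chains[chains$locus == "beta" & chains$cell_id %in% ok1, , drop = FALSE]
  a <- a[match(ok1, a$cell_id), , drop = FALSE]
  b <- b[match(ok1, b$cell_id), , drop = FALSE]

  tcrs <- data.frame(
    cell_id = ok1,
    donor_id = if (is.null(donor_ids)) rep(NA_character_, length(ok1))
               else unname(donor_ids[ok1]),
    va = .strip_allele(a$v_gene), ja = .strip_allele(a$j_gene),
    cdr3a = a$cdr3_aa,
    vb = .strip_allele(b$v_gene), jb = .strip_allele(b$j_gene),
    cdr3b = b$cdr3_aa,
    stringsAsFactors = FALSE
  )

  gta <- gene_table[gene_table$locus == "alpha", , drop = FALSE]
  gtb <- gene_table[gene_table$locus == "beta", , drop = FALSE]

  resolved_call <- function(x) !is.na(x) & nzchar(x) & !(x %in% c("None", "NA"))
  ok2 <- resolved_call(tcrs$va) & resolved_call(tcrs$ja) &
    resolved_call(tcrs$vb) & resolved_call(tcrs$jb) &
    .valid_aa(tcrs$cdr3a) & .valid_aa(tcrs$cdr3b) &
    tcrs$va %in% gta$v_gene & tcrs$vb %in% gtb$v_gene
  report["unresolved_genes"] <- sum(!ok2)
  tcrs <- tcrs[ok2, , drop = FALSE]

  pseudo_a <- gta$v_gene[gta$pseudogene]
  pseudo_b <- gtb$v_gene[gtb$pseudogene]
  ok3 <- !(tcrs$va %in% pseudo_a) & !(tcrs$vb %in% pseudo_b)
  report["pseudogene"] <- sum(!ok3)
  tcrs <- tcrs[ok3, , drop = FALSE]

  la <- nchar(tcrs$cdr3a); lb <- nchar(tcrs$cdr3b)
  ok4 <- la >= min_len_a & la <= max_len_a & lb >= min_len_b & lb <= max_len_b
  report["cdr3_length"] <- sum(!ok4)
  tcrs <- tcrs[ok4, , drop = FALSE]

  rownames(tcrs) <- NULL
  attr(tcrs, "qc_report") <- list(input_cells = length(all_cells),
                                  kept = nrow(tcrs), removed = report)
  tcrs
}

#' @rdname pair_and_qc
#' @param tcrs A paired-TCR data frame returned by `pair_and_qc()`.
#' @export
qc_report <- function(tcrs) attr(tcrs, "qc_report")

.check_paired <- function(tcrs) {
  need <- c("cell_id", "va", "ja", "cdr3a", "vb", "jb", "cdr3b")
  miss <- setdiff(need, names(tcrs))
  if (length(miss))
    .stopf("paired TCRs are missing column(s): %s", paste(miss, collapse = ", "))
  invisible(tcrs)
}

#' Expand paired TCRs back into per-contig chain rows
#'
#' Inverse of the pairing step; useful for QC round trips and for writing
#' AIRR output.
#'
#' @param tcrs A paired-TCR data frame.
#' @return A chain data frame as produced by [read_contigs()].
#' @export
tcrs_to_chains <- function(tcrs) {
  .check_paired(tcrs)
  data.frame(
    cell_id = rep(tcrs$cell_id, 2L),
    locus = rep(c("alpha", "beta"), each = nrow(tcrs)),
    v_gene = c(tcrs$va, tcrs$vb),
    j_gene = c(tcrs$ja, tcrs$jb),
    cdr3_aa = c(tcrs$cdr3a, tcrs$cdr3b),
    productive = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Clonotype key of a paired TCR
#'
#' Concatenates the (allele-stripped) Valpha, Jalpha, Vbeta, Jbeta gene names
#' with the CDR3alpha and CDR3beta amino-acid sequences. Two receptors share
#' a key if and only if all six components match exactly; within a donor a
#' shared key marks an expanded clone, across donors a public clonotype.
#'
#' @param tcrs A paired-TCR data frame (vectorized).
#' @return Character vector of keys.
#' @export
clonotype_key <- function(tcrs) {
  .check_paired(tcrs)
  comp <- tcrs[c("va", "ja", "vb", "jb", "cdr3a", "cdr3b")]
  for (nm in names(comp))
    if (any(is.na(comp[[nm]]) | !nzchar(comp[[nm]])))
      .stopf("clonotype_key: empty component '%s'", nm)
  paste(.strip_allele(tcrs$va), .strip_allele(tcrs$ja),
        .strip_allele(tcrs$vb), .strip_allele(tcrs$jb),
        tcrs$cdr3a, tcrs$cdr3b, sep = "|")
}

#' Select one cell at random per expanded clone
#'
#' Clones are `(donor_id, clonotype_key)` groups; one representative cell is
#' drawn uniformly per clone. Deterministic for a fixed seed; the caller's
#' RNG state is untouched.
#'
#' @param cells Data frame with columns `donor_id` and `clonotype_key`.
#' @param seed Integer seed.
#' @return The subset of `cells` with exactly one row per clone, in input
#'   order.
#' @export
sample_one_per_clone <- function(cells, seed) {
  if (!all(c("donor_id", "clonotype_key") %in% names(cells)))
    .stopf("cells need columns 'donor_id' and 'clonotype_key'")
  if (nrow(cells) == 0L) return(cells)
  grp <- paste(cells$donor_id, cells$clonotype_key, sep = "\r")
  idx <- split(seq_len(nrow(cells)), grp)  # split() orders groups by key
  pick <- .with_seed(seed, {
    vapply(idx, function(i) if (length(i) == 1L) i else i[sample.int(length(i), 1L)],
           integer(1))
  })
  cells[sort(unname(pick)), , drop = FALSE]
}

#' Identify cross-donor TCR twins
#'
#' A TCR twin is a clonotype observed in exactly two distinct donors: the
#' same paired amino-acid receptor arising independently in two people.
#' Clonotypes private to one donor, or shared by three or more donors, are
#' excluded. Each twin member (all cells of the clonotype within one donor)
#' is assigned a transcriptional state with [assign_twin_state()].
#'
#' @param cells Data frame with columns `donor_id`, `clonotype_key`, and
#'   `state_label`.
#' @return Data frame with one row per twin pair: `clonotype_key`,
#'   `donor_a`, `donor_b` (lexicographic order), `state_a`, `state_b`,
#'   `concordant`.
#' @export
find_twins <- function(cells) {
  need <- c("donor_id", "clonotype_key", "state_label")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    .stopf("cells are missing column(s): %s", paste(miss, collapse = ", "))
  ndon <- tapply(cells$donor_id, cells$clonotype_key,
                 function(d) length(unique(d)))
  twin_keys <- names(ndon)[ndon == 2L]
  if (length(twin_keys) == 0L)
    return(data.frame(clonotype_key = character(), donor_a = character(),
                      donor_b = character(), state_a = character(),
                      state_b = character(), concordant = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(twin_keys, function(k) {
    sub <- cells[cells$clonotype_key == k, , drop = FALSE]
    donors <- sort(unique(sub$donor_id))
    sa <- assign_twin_state(sub$state_label[sub$donor_id == donors[1]])
    sb <- assign_twin_state(sub$state_label[sub$donor_id == donors[2]])
    data.frame(clonotype_key = k, donor_a = donors[1], donor_b = donors[2],
               state_a = sa, state_b = sb, concordant = identical(sa, sb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a transcriptional state to a twin member
#'
#' A singleton cell contributes its own cluster; an expanded member takes the
#' cluster containing the greatest number of its constituent cells. Ties are
#' broken deterministically in favour of the lexicographically smallest
#' label (reported via a message).
#'
#' @param state_labels Character vector of cluster labels for all cells of
#'   one `(donor, clonotype)` member.
#' @return A single cluster label.
#' @export
assign_twin_state <- function(state_labels) {
  if (length(state_labels) == 0L)
    .stopf("assign_twin_state: empty member set")
  tab <- table(state_labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1L)
    message("assign_twin_state: tie broken lexicographically (",
            paste(winners, collapse = ", "), " -> ", min(winners), ")")
  min(winners)
}
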