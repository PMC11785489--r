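#' Read single-cell TCR contigs
#'
#' Parses per-contig TCR chain records from either the 10x Genomics
#' `filtered_contig_annotations.csv` dialect or an AIRR Rearrangement TSV.
#' Loci other than TRA/TRB (for example TRG/TRD) are dropped with a message
#' reporting the count.
#'
#' @param path Path to the contig file.
#' @param dialect `"tenx"` (CSV with columns `barcode`, `chain`, `v_gene`,
#'   `j_gene`, `cdr3`, `productive`) or `"airr"` (TSV with columns `cell_id`,
#'   `locus`, `v_call`, `j_call`, `junction_aa`, `productive`).
#' @return A data frame of chains with columns `cell_id`, `locus`
#'   (`"alpha"`/`"beta"`), `v_gene`, `j_gene`, `cdr3_aa`, `productive`
#'   (logical). The number of dropped out-of-scope contigs is attached as
#'   attribute `"dropped_loci"`.
#' @seealso [pair_and_qc()], [write_airr()]
#' @export
read_contigs <- function(path, dialect = c("tenx", "airr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("cannot read contig file '%s'", path)
  if (dialect == "tenx") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "productive")
    miss <- setdiff(need, names(df))
    if (length(miss))
      .stopf("tenx contig file is missing mandatory column(s): %s",
             paste(miss, collapse = ", "))
    out <- data.frame(
      cell_id    = as.character(df$barcode),
      locus      = as.character(df$chain),
      v_gene     = as.character(df$v_gene),
      j_gene     = as.character(df$j_gene),
      cdr3_aa    = as.character(df$cdr3),
      productive = .parse_logical(df$productive),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("cell_id", "locus", "v_call", "j_call", "junction_aa", "productive")
    miss <- setdiff(need, names(df))
    if (length(miss))
      .stopf("AIRR contig file is missing mandatory column(s): %s",
             paste(miss, collapse = ", "))
    out <- data.frame(
      cell_id    = as.character(df$cell_id),
      locus      = as.character(df$locus),
      v_gene     = as.character(df$v_call),
      j_gene     = as.character(df$j_call),
      cdr3_aa    = as.character(df$junction_aa),
      productive = .parse_logical(df$productive),
      stringsAsFactors = FALSE
    )
  }
  keep <- out$locus %in% c("TRA", "TRB", "alpha", "beta")
  dropped <- sum(!keep)
  if (dropped > 0)
    message("read_contigs: dropped ", dropped, " contig(s) of out-of-scope loci")
  out <- out[keep, , drop = FALSE]
  out$locus <- ifelse(out$locus %in% c("TRA", "alpha"), "alpha", "beta")
  rownames(out) <- NULL
  attr(out, "dropped_loci") <- dropped
  out
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write paired TCRs as an AIRR Rearrangement TSV subset
#'
#' Emits two rows (alpha, beta) per cell with columns `cell_id`, `locus`,
#' `v_call`, `j_call`, `junction_aa`, `productive`, re-readable with
#' [read_contigs()] under the `"airr"` dialect.
#'
#' @param tcrs A paired-TCR data frame (see [pair_and_qc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(tcrs, path) {
  .check_paired(tcrs)
  rows <- data.frame(
    cell_id = rep(tcrs$cell_id, each = 2L),
    locus = rep(c("TRA", "TRB"), times = nrow(tcrs)),
    v_call = as.vector(rbind(tcrs$va, tcrs$vb)),
    j_call = as.vector(rbind(tcrs$ja, tcrs$jb)),
    junction_aa = as.vector(rbind(tcrs$cdr3a, tcrs$cdr3b)),
    productive = "true",
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell metadata
#'
#' CSV with header `cell_id,donor_id,state_label` and any further covariate
#' columns, one row per cell.
#'
#' @param path Path to the CSV.
#' @return A data frame; duplicate cell ids are an error.
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "donor_id", "state_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("cell metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    .stopf("duplicate cell_id in metadata: %s",
           df$cell_id[duplicated(df$cell_id)][1])
  df
}

#' Read a V-gene reference table
#'
#' CSV with columns `locus` (`alpha`/`beta`), `v_gene`, `cdr1_aa`, `cdr2_aa`,
#' `pseudogene` mapping IMGT V-gene names to their germline-encoded CDR1 and
#' CDR2 amino-acid sequences. Non-pseudogenes must have non-empty CDR1/CDR2;
#' gene names must be unique within each locus.
#'
#' @param path Path to the CSV. Defaults to the bundled synthetic mini-table
#'   used by the simulator and the test suite (fictional gene names; real
#'   analyses should supply a table translated from the IMGT reference).
#' @return A validated data frame.
#' @export
read_gene_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vgene_table_synthetic.csv",
                        package = "tcrfate", mustWork = TRUE)
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "v_gene", "cdr1_aa", "cdr2_aa", "pseudogene")
  miss <- setdiff(need, names(gt))
  if (length(miss))
    .stopf("gene table is missing column(s): %s", paste(miss, collapse = ", "))
  gt$pseudogene <- .parse_logical(gt$pseudogene)
  if (!all(gt$locus %in% c("alpha", "beta")))
    .stopf("gene table locus must be 'alpha' or 'beta'")
  dup <- duplicated(gt[c("locus", "v_gene")])
  if (any(dup))
    .stopf("duplicated v_gene within a locus: %s", gt$v_gene[dup][1])
  bad <- !gt$pseudogene & !(.valid_aa(gt$cdr1_aa) & .valid_aa(gt$cdr2_aa))
  if (any(bad))
    .stopf("non-pseudogene '%s' has an empty or invalid CDR1/CDR2 sequence",
           gt$v_gene[bad][1])
  gt
}
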