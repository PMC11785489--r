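# shared fixtures: everything is generated in code at test time

gt_fixture <- read_gene_table()

# a hand-built paired TCR table using genes from the bundled table
toy_tcrs <- function() {
  data.frame(
    cell_id = c("c1", "c2", "c3"),
    donor_id = c("dA", "dA", "dB"),
    va = c("TRAVS1", "TRAVS2", "TRAVS1"),
    ja = c("TRAJS1", "TRAJS2", "TRAJS1"),
    cdr3a = c("CAVRGGSQGNLIF", "CAVSDLEPNSSASKIIF", "CAVRGGSQGNLIF"),
    vb = c("TRBVS1", "TRBVS2", "TRBVS1"),
    jb = c("TRBJS1", "TRBJS2", "TRBJS1"),
    cdr3b = c("CASSIRSSYEQYF", "CASSLAPGATNEKLFF", "CASSIRSSYEQYF"),
    stringsAsFactors = FALSE
  )
}

# write a 10x-dialect contig CSV and return its path
write_tenx_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tenx_rows <- function(barcode, chain, v, j, cdr3, productive = "True") {
  data.frame(barcode = barcode, chain = chain, v_gene = v, j_gene = j,
             cdr3 = cdr3, productive = productive, stringsAsFactors = FALSE)
}

quick_config <- function(...) {
  sim_config(n_donors = 4L, cells_per_donor = 120L, ...)
}
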