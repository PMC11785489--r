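test_that("gap alignment splits middle-out and enforces slot capacity", {
  expect_equal(gap_align("CASSF", 6), "CAS-SF")
  expect_equal(gap_align("ABCDEF", 6), "ABCDEF")
  expect_equal(gap_align("AB", 5), "A---B")
  expect_equal(gap_align("ABC", 6), "AB---C")
  expect_error(gap_align("ABCDEFG", 6), "exceeds")
})

test_that("default registry reproduces the published feature accounting", {
  reg <- build_registry()
  kinds <- table(reg$features$kind)
  expect_equal(sum(reg$slots), 58L)
  expect_equal(unname(kinds["position_atchley"]), 290L)
  expect_equal(unname(kinds["composition"]), 114L)
  expect_equal(unname(kinds["length"]), 6L)
  # 25 interaction descriptors per adjacent within-loop slot pair
  ints <- reg$features[reg$features$kind == "adjacency_interaction", ]
  per_pair <- table(paste(ints$loop, ints$slot, ints$slot2))
  expect_true(all(per_pair == 25L))
  expect_equal(length(per_pair), sum(reg$slots - 1L))
  # composition excludes glycine
  comp <- reg$features[reg$features$kind == "composition", ]
  expect_false("G" %in% comp$letter)
  expect_equal(unname(table(comp$loop)["CDR3a"]), 19L)
  expect_error(build_registry(slots = c(CDR1a = 0L, CDR2a = 8L, CDR3a = 15L,
                                        CDR1b = 6L, CDR2b = 6L, CDR3b = 16L)),
               "positive")
})

test_that("bundled Atchley table is the published standardized factor set", {
  A <- atchley_factors()
  expect_equal(dim(A), c(20L, 5L))
  expect_true(all(is.finite(A)))
  # factors were standardized over the 20 residues
  expect_true(all(abs(colMeans(A)) < 0.005))
  expect_equal(unname(atchley_lookup("A")),
               c(-0.591, -1.302, -0.733, 1.570, -0.146))
  expect_error(atchley_lookup("*"), "not a standard")
  expect_error(atchley_lookup("B"), "not a standard")
})

test_that("featurization matches hand-computed values", {
  reg <- build_registry()
  tcrs <- toy_tcrs()[1, ]
  fe <- featurize_tcrs(tcrs, gt_fixture, reg)
  expect_equal(ncol(fe$x), reg$n_features)
  A <- atchley_factors()

  # positional: CDR3a interior "AVRGGSQGNLI" (11 aa), slot 1 holds 'A'
  j <- which(reg$features$name == "pos_CDR3a_s1_f1")
  expect_equal(unname(fe$x[1, j]), unname(A["A", 1]))
  # middle-out: slot 15 holds the last interior residue 'I'
  j2 <- which(reg$features$name == "pos_CDR3a_s15_f3")
  expect_equal(unname(fe$x[1, j2]), unname(A["I", 3]))
  # middle slots are gaps: 11 residues in 15 slots -> slots 7..10 empty
  gap_cols <- which(reg$features$kind == "position_atchley" &
                      reg$features$loop == "CDR3a" &
                      reg$features$slot %in% 7:10)
  expect_true(all(fe$mask[1, gap_cols]))
  expect_true(all(fe$x[1, gap_cols] == 0))

  # interaction = product of the neighbours' factors (slots 1-2: 'A','V')
  ji <- which(reg$features$name == "int_CDR3a_s1.2_f2x4")
  expect_equal(unname(fe$x[1, ji]), unname(A["A", 2] * A["V", 4]))
  # interactions across a gap boundary are masked
  jgap <- which(reg$features$kind == "adjacency_interaction" &
                  reg$features$loop == "CDR3a" &
                  reg$features$slot == 6L)
  expect_true(all(fe$mask[1, jgap]))

  # composition closes to 100 minus the glycine percentage per loop
  comp <- reg$features$kind == "composition"
  for (lp in names(reg$slots)) {
    cols <- which(comp & reg$features$loop == lp)
    seqs <- switch(lp,
                   CDR3a = substr(tcrs$cdr3a, 2, nchar(tcrs$cdr3a) - 1),
                   CDR3b = substr(tcrs$cdr3b, 2, nchar(tcrs$cdr3b) - 1),
                   CDR1a = gt_fixture$cdr1_aa[gt_fixture$v_gene == tcrs$va],
                   CDR2a = gt_fixture$cdr2_aa[gt_fixture$v_gene == tcrs$va],
                   CDR1b = gt_fixture$cdr1_aa[gt_fixture$v_gene == tcrs$vb],
                   CDR2b = gt_fixture$cdr2_aa[gt_fixture$v_gene == tcrs$vb])
    gly <- 100 * lengths(regmatches(seqs, gregexpr("G", seqs))) / nchar(seqs)
    expect_equal(sum(fe$x[1, cols]), 100 - gly, tolerance = 1e-12)
  }

  # length features equal the loop (interior) lengths
  jl <- which(reg$features$name == "len_CDR3a")
  expect_equal(unname(fe$x[1, jl]), nchar(tcrs$cdr3a) - 2)

  # a full-length CDR3a (17 aa junction -> 15 interior) has no CDR3a gaps
  full <- tcrs; full$cdr3a <- "CAVRGGSQGNLIAGKTF"
  fef <- featurize_tcrs(full, gt_fixture, reg)
  pos3a <- which(reg$features$kind == "position_atchley" &
                   reg$features$loop == "CDR3a")
  expect_false(any(fef$mask[1, pos3a]))

  # unknown V gene -> lookup error naming the gene
  bad <- tcrs; bad$va <- "TRAV404"
  expect_error(featurize_tcrs(bad, gt_fixture, reg), "TRAV404")
})

test_that("featurization is pure and row-order equivariant", {
  tcrs <- toy_tcrs()
  fe1 <- featurize_tcrs(tcrs, gt_fixture)
  fe2 <- featurize_tcrs(tcrs, gt_fixture)
  expect_identical(fe1$x, fe2$x)
  perm <- c(3L, 1L, 2L)
  fe3 <- featurize_tcrs(tcrs[perm, ], gt_fixture)
  expect_equal(fe3$x, fe1$x[perm, ], ignore_attr = TRUE)
  expect_equal(fe3$mask, fe1$mask[perm, ], ignore_attr = TRUE)
})

test_that("changing one residue perturbs exactly the features that see its slot", {
  reg <- build_registry()
  t1 <- toy_tcrs()[1, ]
  t2 <- t1
  # interior position 3 ('R' -> 'K') occupies CDR3a slot 3
  substr(t2$cdr3a, 4, 4) <- "K"
  f1 <- featurize_tcrs(t1, gt_fixture, reg)$x[1, ]
  f2 <- featurize_tcrs(t2, gt_fixture, reg)$x[1, ]
  changed <- which(f1 != f2)
  fe <- reg$features
  expected <- which(
    (fe$loop == "CDR3a" & fe$kind == "position_atchley" & fe$slot == 3L) |
    (fe$loop == "CDR3a" & fe$kind == "adjacency_interaction" &
       (fe$slot == 3L | fe$slot2 == 3L)) |
    (fe$loop == "CDR3a" & fe$kind == "composition" & fe$letter %in% c("R", "K")))
  expect_setequal(changed, expected)
})

test_that("scaling standardizes non-gap entries and freezes train statistics", {
  cfg <- quick_config()
  sim <- simulate_repertoire(cfg, seed = 21)
  fe <- featurize_tcrs(sim$tcrs[1:150, ], gt_fixture)
  st <- fit_scaling(fe)
  fs <- apply_scaling(fe, st)
  w <- !fe$mask
  mu <- colSums(fs$x * w) / colSums(w)
  ok <- !st$zero_var
  expect_true(max(abs(mu[ok])) < 1e-10)
  sds <- sqrt(colSums((fs$x * w)^2) / (colSums(w) - 1))
  expect_equal(unname(sds[ok]), rep(1, sum(ok)), tolerance = 1e-8)
  # masked entries are exactly zero after scaling
  expect_true(all(fs$x[fe$mask] == 0))
  # frozen stats: applying train stats to shifted data leaves stats unchanged
  fe2 <- featurize_tcrs(sim$tcrs[151:300, ], gt_fixture)
  fs2 <- apply_scaling(fe2, st)
  expect_false(isTRUE(all.equal(colMeans(fs2$x), rep(0, ncol(fs2$x)))))
  expect_identical(fit_scaling(fe)$mean, st$mean)
  # registry mismatch refused
  reg2 <- build_registry(interactions = FALSE)
  fe3 <- featurize_tcrs(sim$tcrs[1:5, ], gt_fixture, reg2)
  expect_error(apply_scaling(fe3, st), "registry")
})

test_that("feature matrices round-trip through TSV with their gap mask", {
  fe <- featurize_tcrs(toy_tcrs(), gt_fixture)
  prefix <- tempfile()
  write_features(fe, prefix)
  back <- read_features(prefix, fe$registry)
  expect_equal(back$x, fe$x, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(back$mask, fe$mask, ignore_attr = TRUE)
  expect_identical(back$cell_ids, fe$cell_ids)
  expect_error(read_features(prefix, build_registry(interactions = FALSE)),
               "registry")
})

test_that("cell metadata reader validates its header and ids", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,donor_id,state_label,age",
               "c1,d1,A1,30", "c2,d1,A2,30"), p)
  md <- read_cell_metadata(p)
  expect_equal(nrow(md), 2L)
  expect_equal(md$age, c(30L, 30L))
  writeLines(c("cell_id,donor_id", "c1,d1"), p)
  expect_error(read_cell_metadata(p), "state_label")
  writeLines(c("cell_id,donor_id,state_label", "c1,d1,A1", "c1,d1,A2"), p)
  expect_error(read_cell_metadata(p), "duplicate")
})

test_that("registry and scaling serialize through JSON losslessly", {
  reg <- build_registry()
  p1 <- tempfile(fileext = ".json")
  write_registry(reg, p1)
  reg2 <- read_registry(p1)
  expect_identical(reg2$hash, reg$hash)
  expect_identical(reg2$features$name, reg$features$name)

  fe <- featurize_tcrs(toy_tcrs(), gt_fixture, reg)
  st <- fit_scaling(fe)
  p2 <- tempfile(fileext = ".json")
  write_scaling(st, p2)
  st2 <- read_scaling(p2)
  expect_equal(st2$mean, st$mean, tolerance = 1e-12)
  expect_equal(st2$sd, st$sd, tolerance = 1e-12)
  expect_equal(apply_scaling(fe, st2)$x, apply_scaling(fe, st)$x,
               tolerance = 1e-9)
})
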