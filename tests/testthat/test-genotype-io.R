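test_that("pairs_csv parsing, normalization and error reporting", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,L1,L2",
               "S1,130/134,128/128",
               "S2,.,140/144"), tf)
  gm <- read_genotype_table(tf)
  expect_equal(dim(gm), c(2L, 2L))
  expect_equal(sum(is.na(gm$a1)), 1L)
  expect_equal(gm$a1[1, ], c(L1 = 130L, L2 = 128L))

  # reversed allele order is normalized to min-first
  writeLines(c("accession,L1", "S1,134/130"), tf)
  gm <- read_genotype_table(tf)
  expect_equal(unname(c(gm$a1[1, 1], gm$a2[1, 1])), c(130L, 134L))

  writeLines(c("accession,L1", "Syrah,130/134", "Syrah,130/134"), tf)
  expect_error(read_genotype_table(tf), "Syrah")

  writeLines(c("accession,L1", "S1,130/x"), tf)
  expect_error(read_genotype_table(tf), "non-integer")

  writeLines(c("accession,L1", "S1,130"), tf)
  expect_error(read_genotype_table(tf), "pair")
})

test_that("two_column_csv dialect and half-call detection", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,L1_1,L1_2,L2_1,L2_2",
               "S1,134,130,0,0",
               "S2,128,128,140,144"), tf)
  gm <- read_genotype_table(tf, dialect = "two_column_csv")
  expect_equal(gm$locus_ids, c("L1", "L2"))
  expect_true(is.na(gm$a1[1, 2]))
  expect_equal(unname(gm$a1[1, 1]), 130L)  # normalized

  writeLines(c("id,L1_1,L1_2", "S1,130,0"), tf)
  expect_error(read_genotype_table(tf, dialect = "two_column_csv"),
               "half-call")
})

test_that("genotype_matrix invariants are enforced", {
  expect_error(genotype_matrix(c("a", "a"), "L", c(1L, 1L), c(1L, 1L)),
               "duplicate accession")
  expect_error(genotype_matrix(c("a", "b"), c("L", "L"),
                               matrix(1L, 2, 2), matrix(1L, 2, 2)),
               "duplicate locus")
  expect_error(genotype_matrix("a", c("L1", "L2"), matrix(1L), matrix(1L)),
               "n_accessions x n_loci")
  expect_error(genotype_matrix(c("a", "b"), "L", c(130L, NA), c(NA, 134L)),
               "half-call")
  expect_error(genotype_matrix("a", "L", -5L, 130L), "non-positive")
})

test_that("parse -> serialize round trip is the identity", {
  for (seed in 1:3) {
    gm <- random_gm(8L, 4L, missing_rate = 0.15, seed = seed)
    tf <- withr::local_tempfile(fileext = ".csv")
    write_genotype_table(gm, tf)
    expect_true(isTRUE(all.equal(gm, read_genotype_table(tf))))
  }
})

test_that("STRUCTURE encoding round-trips and codes missing as -9", {
  gm <- gm_from_strings(list(c("130/134"), c(".")), "L1", c("a", "b"))
  enc <- write_structure_input(gm)
  # two data rows per accession; distinct integer codes for distinct alleles
  expect_length(enc$text, 1L + 4L)
  row_a1 <- strsplit(enc$text[2], "\t")[[1]]
  row_a2 <- strsplit(enc$text[3], "\t")[[1]]
  expect_false(row_a1[2] == row_a2[2])
  expect_equal(strsplit(enc$text[4], "\t")[[1]][2], "-9")
  expect_equal(strsplit(enc$text[5], "\t")[[1]][2], "-9")

  for (seed in 1:5) {
    gm <- random_gm(5L, 3L, missing_rate = 0.2, seed = seed)
    enc <- write_structure_input(gm)
    expect_true(isTRUE(all.equal(gm, decode_structure_input(enc$text,
                                                            enc$recoding))))
  }
})

test_that("standardize_alleles estimates per-locus modal offsets", {
  loci <- c("VVS2", "VVMD5")
  gm <- gm_from_strings(list(c("130/134", "228/230"),
                             c("130/130", "230/240")),
                        loci, c("Syrah", "Other"))
  panel <- reference_panel(
    "Syrah", loci,
    list(list(VVS2 = c(130L, 134L), VVMD5 = c(228L, 230L))))
  anchors <- c(Syrah = "Syrah")

  # already aligned: identity
  out <- standardize_alleles(gm, panel, anchors)
  expect_equal(unname(out$offsets), c(0L, 0L))
  expect_true(isTRUE(all.equal(gm, out$gm)))

  # shift every observed allele down 2 bp at both loci -> offset +2
  gm2 <- gm
  gm2$a1 <- gm$a1 - 2L
  gm2$a2 <- gm$a2 - 2L
  out2 <- standardize_alleles(gm2, panel, anchors)
  expect_equal(unname(out2$offsets), c(2L, 2L))
  expect_true(isTRUE(all.equal(gm, out2$gm)))

  # idempotence: re-standardizing yields all-zero offsets
  out3 <- standardize_alleles(out2$gm, panel, anchors)
  expect_equal(unname(out3$offsets), c(0L, 0L))

  # discordant anchors below the consistency threshold -> error
  panel2 <- reference_panel(
    c("Syrah", "Merlot"), "VVS2",
    list(list(VVS2 = c(132L, 136L)),   # implies +2, +2
         list(VVS2 = c(124L, 128L)))) # implies -6, -6
  gm3 <- gm_from_strings(list(c("130/134"), c("130/134")), "VVS2",
                         c("Syrah", "Merlot"))
  expect_error(standardize_alleles(gm3, panel2,
                                   c(Syrah = "Syrah", Merlot = "Merlot")),
               "agree with modal offset")

  # no anchors typed at a locus -> offset 0 with warning
  gm4 <- gm_from_strings(list(c(".", "228/230")), loci, "Syrah")
  expect_warning(out4 <- standardize_alleles(gm4, panel, anchors),
                 "no anchors typed")
  expect_equal(unname(out4$offsets[1]), 0L)
})
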