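test_that("profile keys are canonical and order-insensitive", {
  gm <- gm_from_strings(list(c("130/134", "200/204"),
                             c("130/134", "200/204"),
                             c("130/134", "200/206")),
                        c("L2", "L1"), c("a", "b", "c"))
  expect_identical(profile_key(gm, "a"), profile_key(gm, "b"))
  expect_false(profile_key(gm, "a") == profile_key(gm, "c"))
  # invariant to locus column order in the input
  gm_swapped <- gm[, c("L1", "L2")]
  expect_identical(profile_key(gm, "a"), profile_key(gm_swapped, "a"))
})

test_that("duplicate and synonym grouping by exact profile identity", {
  # same name + same profile -> one duplicate group, one unique genotype
  gm <- gm_from_strings(list(c("130/134", "200/204"),
                             c("130/134", "200/204")),
                        c("L1", "L2"), c("acc1", "acc2"))
  res <- find_duplicates_and_synonyms(
    gm, names = c(acc1 = "Niagara", acc2 = "Niagara"))
  expect_length(res$duplicate_groups, 1L)
  expect_length(res$synonym_groups, 0L)
  expect_equal(res$n_unique_genotypes, 1L)

  # identical profiles under different names -> synonym group
  res2 <- find_duplicates_and_synonyms(
    gm, names = c(acc1 = "Tinta Roriz", acc2 = "Tempranillo Tinto"))
  expect_length(res2$synonym_groups, 1L)
  expect_length(res2$duplicate_groups, 0L)

  # distinct random profiles -> no groups, n unique genotypes
  gm3 <- random_gm(10L, 5L, n_alleles = 10L, seed = 3)
  keys <- vapply(gm3$accession_ids, function(a) profile_key(gm3, a), "")
  stopifnot(!anyDuplicated(keys))  # generator sanity
  res3 <- find_duplicates_and_synonyms(gm3)
  expect_equal(res3$n_unique_genotypes, 10L)
  expect_length(res3$duplicate_groups, 0L)
  expect_length(res3$synonym_groups, 0L)

  # missing-vs-typed at a compared locus breaks identity (strict mode)
  gm4 <- gm_from_strings(list(c("130/134", "."),
                              c("130/134", "200/204")),
                         c("L1", "L2"), c("a", "b"))
  expect_warning(res4 <- find_duplicates_and_synonyms(gm4), "excluded")
  expect_equal(res4$excluded, "a")
  expect_equal(res4$n_unique_genotypes, 1L)
})

test_that("lenient mode matches on shared typed loci", {
  loci <- paste0("L", 1:7)
  prof <- c("100/102", "104/104", "110/112", "120/124", "130/130",
            "140/144", "150/152")
  rows <- list(prof,
               replace(prof, 7, "."),      # missing L7, matches on 6 shared
               replace(prof, 5, "132/132")) # genuinely different
  gm <- gm_from_strings(rows, loci, c("a", "b", "c"))
  # strict: b is excluded, a and c distinct
  expect_warning(strict <- find_duplicates_and_synonyms(gm), "excluded")
  expect_equal(strict$excluded, "b")
  # lenient: a and b form a synonym group over their 6 shared loci
  len <- find_duplicates_and_synonyms(gm, mode = "lenient")
  expect_length(len$synonym_groups, 1L)
  expect_setequal(len$synonym_groups[[1]], c("a", "b"))
  expect_equal(len$n_unique_genotypes, 2L)
})

test_that("grouping is an equivalence and relabeling never splits groups", {
  gm <- random_gm(12L, 4L, n_alleles = 3L, seed = 7)  # forces collisions
  res <- find_duplicates_and_synonyms(gm)
  n0 <- res$n_unique_genotypes
  # relabel every synonym-group member to the first member's name
  nm <- setNames(gm$accession_ids, gm$accession_ids)
  for (grp in res$synonym_groups) nm[grp] <- grp[1L]
  res2 <- find_duplicates_and_synonyms(gm, names = nm)
  expect_lte(res2$n_unique_genotypes, n0)
  expect_length(res2$synonym_groups, 0L)
})

test_that("reference matching classifies validated/misnamed/unknown/unreported", {
  loci <- c("VVS2", "VVMD5")
  panel <- reference_panel(
    c("Cabernet Franc", "Merlot Noir"), loci,
    list(list(VVS2 = c(137L, 151L), VVMD5 = c(230L, 240L)),
         list(VVS2 = c(137L, 139L), VVMD5 = c(226L, 236L))))
  gm <- gm_from_strings(
    list(c("137/151", "230/240"),   # profile of Cabernet Franc
         c("137/139", "226/236"),   # profile of Merlot Noir
         c("101/103", "200/202"),   # novel, name in panel
         c("105/107", "204/206")),  # novel, name absent
    loci, c("Merlot Noir", "A2", "A3", "A4"))
  declared <- c(`Merlot Noir` = "Merlot Noir", A2 = "Merlot Noir",
                A3 = "Cabernet Franc", A4 = "IAC 138-22")
  res <- match_to_references(gm, panel, declared)
  # name swap: accession declared Merlot but matching Cabernet Franc
  expect_equal(res$misnamed$accession, "Merlot Noir")
  expect_equal(res$misnamed$prime_name, "Cabernet Franc")
  expect_equal(res$validated$accession, "A2")
  expect_equal(res$unknown, "A3")
  expect_equal(res$unreported, "A4")
  # the four categories partition the accession set
  all_cat <- c(res$validated$accession, res$misnamed$accession,
               res$unknown, res$unreported, res$excluded)
  expect_setequal(all_cat, gm$accession_ids)

  # ambiguous panel (same profile under two prime names) -> error
  panel_bad <- reference_panel(
    c("X", "Y"), loci,
    list(list(VVS2 = c(137L, 151L), VVMD5 = c(230L, 240L)),
         list(VVS2 = c(137L, 151L), VVMD5 = c(230L, 240L))))
  expect_error(match_to_references(gm, panel_bad, declared),
               "panel inconsistency")
})

test_that("name normalization handles case, accents and spacing", {
  expect_equal(normalize_name("  Moscatel  de Alexandria "),
               "moscatel de alexandria")
  expect_equal(normalize_name("Niágara"), normalize_name("Niagara"))
  expect_false(normalize_name("Pedro Ximenez") ==
                 normalize_name("Pedro Gimenez"))
})
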