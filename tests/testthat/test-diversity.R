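test_that("allele frequencies use typed calls only", {
  gm <- gm_from_strings(list("130/134", "130/134"), "L")
  expect_equal(allele_frequencies(gm, "L")$freqs, c(`130` = 0.5, `134` = 0.5))

  gm <- gm_from_strings(list("130/130", "130/134"), "L")
  expect_equal(allele_frequencies(gm, "L")$freqs, c(`130` = 0.75, `134` = 0.25))

  gm <- gm_from_strings(list("130/134", "."), "L")
  af <- allele_frequencies(gm, "L")
  expect_equal(af$n_typed, 1L)
  expect_equal(unname(af$freqs), c(0.5, 0.5))

  gm <- gm_from_strings(list(".", "."), "L")
  af <- allele_frequencies(gm, "L")
  expect_equal(af$n_typed, 0L)
  expect_length(af$freqs, 0L)
})

test_that("locus summary matches hand-evaluated definitions", {
  # p = (0.5, 0.5), all calls heterozygous
  gm <- gm_from_strings(list("130/134", "130/134"), "L")
  s <- locus_summary(gm, "L")
  expect_equal(s$Na, 2)
  expect_equal(s$Ne, 2, tolerance = 1e-12)
  expect_equal(s$He, 0.5, tolerance = 1e-12)
  expect_equal(s$Ho, 1)
  expect_equal(s$F, -1, tolerance = 1e-12)

  # monomorphic: Na = Ne = 1, He = 0, F undefined (not an error)
  gm <- gm_from_strings(list("130/130", "130/130"), "L")
  s <- locus_summary(gm, "L")
  expect_equal(s[, c("Na", "Ne", "Ho", "He")],
               data.frame(Na = 1, Ne = 1, Ho = 0, He = 0),
               ignore_attr = TRUE)
  expect_true(is.na(s$F))

  # unbiased variant applies 2N/(2N-1)
  gm <- gm_from_strings(list("130/134", "130/134"), "L")
  expect_equal(locus_summary(gm, "L", unbiased = TRUE)$He, 0.5 * 4 / 3)
})

test_that("PIC matches the printed double-sum and its algebraic identity", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375, tolerance = 1e-12)
  # brute-force oracle for <= 4 alleles: explicit double loop
  pic_brute <- function(p) {
    out <- 1 - sum(p^2)
    for (i in seq_along(p)) for (j in seq_along(p)) if (j > i)
      out <- out - 2 * p[i]^2 * p[j]^2
    out
  }
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    expect_equal(pic(p), pic_brute(p), tolerance = 1e-12)
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)  # PIC <= He
  }
})

test_that("discriminating power matches hand-evaluated cases", {
  gm <- gm_from_strings(as.list(rep("130/130", 4)), "L")
  expect_equal(discriminating_power(pattern_frequencies(gm, "L")), 0)

  gm <- gm_from_strings(list("130/130", "130/130", "130/134", "130/134"), "L")
  expect_equal(discriminating_power(pattern_frequencies(gm, "L")), 2 / 3,
               tolerance = 1e-12)

  gm <- gm_from_strings(list("130/130", "130/134", "134/134", "130/136"), "L")
  expect_equal(discriminating_power(pattern_frequencies(gm, "L")), 1,
               tolerance = 1e-12)

  gm <- gm_from_strings(list("130/130"), "L")
  expect_error(discriminating_power(pattern_frequencies(gm, "L")), "N >= 2")
})

test_that("Dj converges to 1 - sum(p^2) over patterns as N grows", {
  # fixed pattern distribution, counts chosen exactly at N = 1e4
  counts <- c(5000, 3000, 1500, 500)
  N <- sum(counts)
  p <- counts / N
  pat <- list(locus_id = "L", pattern_freqs = p, N = N, I = length(p))
  expect_equal(discriminating_power(pat), 1 - sum(p^2), tolerance = 1e-3)
})

test_that("null-allele EM recovers the simulated truth", {
  # true r = 0 under HWE: estimate stays near zero
  gm <- hwe_locus_gm(500, rep(0.2, 5), r = 0, seed = 101)
  expect_lt(null_allele_frequency(gm, "LOC"), 0.02)

  # true r = 0.20: mean estimate over 20 seeds within +-0.05
  est <- vapply(1:20, function(s) {
    gm <- hwe_locus_gm(500, rep(0.2, 5), r = 0.20, seed = 200 + s,
                       extra_missing = 0.02)
    null_allele_frequency(gm, "LOC")
  }, 0)
  expect_lt(abs(mean(est) - 0.20), 0.05)

  # below the typed-call floor: NA with warning
  gm <- hwe_locus_gm(5, c(0.5, 0.5), seed = 1)
  expect_warning(r <- null_allele_frequency(gm, "LOC"), "undefined")
  expect_true(is.na(r))
})

test_that("private and rare alleles follow strict definitions", {
  gm <- gm_from_strings(list("100/102", "100/100", "102/104", "104/104"),
                        "L", ids = c("a", "b", "c", "d"))
  grouping <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  out <- private_and_rare_alleles(gm, grouping)
  # allele 100 only in g1, 104 only in g2, 102 shared
  expect_equal(out$private$g1$allele, 100)
  expect_equal(out$private$g2$allele, 104)

  # strict < threshold: 0.049 rare, 0.050 not
  freqs <- c(rep(105L, 19), 135L)  # 1/20 = 0.05
  gm2 <- genotype_matrix(sprintf("x%02d", 1:10), "L",
                         freqs[seq(1, 20, 2)], freqs[seq(2, 20, 2)])
  out2 <- private_and_rare_alleles(gm2, setNames(rep("g", 10),
                                                 gm2$accession_ids))
  expect_false(135 %in% out2$rare$allele)  # exactly 0.05 -> not rare
  expect_true(all(out2$rare$freq < 0.05))

  # identical group compositions -> no private alleles
  gm3 <- gm_from_strings(list("100/102", "100/102"), "L", c("a", "b"))
  out3 <- private_and_rare_alleles(gm3, c(a = "g1", b = "g2"))
  expect_equal(nrow(out3$private$g1), 0L)
  expect_equal(nrow(out3$private$g2), 0L)

  expect_error(private_and_rare_alleles(gm3, c(a = "g1", zz = "g2")),
               "unknown accession|unlabeled")
})

test_that("collection summary totals and means", {
  gm <- gm_from_strings(list("130/134", "130/134"), "L")
  cs <- collection_summary(gm, null_r = FALSE)
  expect_equal(unname(cs$total["Na"]), cs$table$Na[1])
  expect_equal(unname(cs$total["Ne"]), cs$table$Ne[1])

  tab <- data.frame(K = 1, Na = c(10, 24), Ne = c(2, 3), Ho = c(0.5, 0.7),
                    He = c(0.5, 0.7))
  cs2 <- collection_summary(tab)
  expect_equal(unname(cs2$mean["Na"]), 17)
  expect_equal(unname(cs2$total["Na"]), 34)
  expect_equal(unname(cs2$se["Na"]), sd(c(10, 24)) / sqrt(2))
})

test_that("diversity invariants hold on random matrices", {
  for (seed in 1:4) {
    gm <- random_gm(40L, 5L, n_alleles = 8L, missing_rate = 0.05,
                    seed = seed)
    tab <- diversity_table(gm, null_r = FALSE)
    expect_true(all(tab$Ne <= tab$Na + 1e-9))
    expect_true(all(tab$Ne >= 1))
    expect_true(all(tab$PIC <= tab$He + 1e-12))
    expect_true(all(tab$He >= 0 & tab$He < 1))
    expect_true(all(tab$Ho >= 0 & tab$Ho <= 1))
    expect_true(all(tab$Dj >= -1e-12 & tab$Dj <= 1 + 1e-12))
  }
  # Ne = Na iff equifrequent
  gm <- gm_from_strings(list("100/102", "100/102"), "L")
  s <- locus_summary(gm, "L")
  expect_equal(s$Ne, s$Na, tolerance = 1e-12)
})

test_that("Ho approaches He on HWE-simulated data", {
  gm <- hwe_locus_gm(1000, c(0.4, 0.3, 0.2, 0.1), r = 0, seed = 42)
  s <- locus_summary(gm, "LOC")
  expect_lt(abs(s$Ho - s$He), 0.02)
})
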