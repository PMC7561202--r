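test_that("Rogers distance matches hand-evaluated single-locus cases", {
  gm <- gm_from_strings(list("130/134", "130/134"), "L", c("a", "b"))
  expect_equal(rogers_distance(gm)["a", "b"], 0)

  gm <- gm_from_strings(list("130/130", "134/134"), "L", c("a", "b"))
  expect_equal(rogers_distance(gm)["a", "b"], 1, tolerance = 1e-12)

  gm <- gm_from_strings(list("130/134", "130/130"), "L", c("a", "b"))
  expect_equal(rogers_distance(gm)["a", "b"], 0.5, tolerance = 1e-12)
})

test_that("Rogers distance is a bounded symmetric dissimilarity", {
  gm <- random_gm(15L, 6L, missing_rate = 0.1, seed = 5)
  d <- rogers_distance(gm)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1 + 1e-12))

  # pair with no shared typed locus errors with the pair named
  gm2 <- gm_from_strings(list(c("130/134", "."), c(".", "200/204")),
                         c("L1", "L2"), c("a", "b"))
  expect_error(rogers_distance(gm2), "share no typed locus")
})

test_that("NJ reproduces the three-point closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2])], tr$tip.label)
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3),
               tolerance = 1e-9)
})

test_that("NJ recovers additive trees exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:6, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- round(true$edge.length + 0.1, 3)
    dm <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(dm)
    # identical topology
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
    # identical path lengths between every leaf pair
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-8)
  }
})

test_that("duplicate profiles yield a zero-length cherry", {
  gm <- gm_from_strings(list(c("130/134", "200/204"),
                             c("130/134", "200/204"),
                             c("110/112", "210/214"),
                             c("118/120", "216/218")),
                        c("L1", "L2"), c("a", "a2", "b", "c"))
  tr <- neighbor_joining(rogers_distance(gm))
  w <- which(tr$tip.label %in% c("a", "a2"))
  parents <- tr$edge[match(w, tr$edge[, 2]), 1]
  expect_equal(parents[1], parents[2])  # they form a cherry
  expect_equal(sum(tr$edge.length[match(w, tr$edge[, 2])]), 0)
})

test_that("locus bootstrap gives 100% support to clonal cherries and is reproducible", {
  sim <- simulate_germplasm(sim_config(
    n_pools = 2L, n_loci = 8L, n_pure = c(4L, 4L), n_admixed = 0L,
    n_duplicate_pairs = 1L, n_synonym_groups = 0L, missing_rate = 0,
    alleles_per_locus = c(6L, 10L), seed = 31L))
  gm <- sim$gm
  clone_pair <- sim$truth$clone_groups[[1]]
  bs <- bootstrap_supports(gm, replicates = 60L, seed = 9L)
  key <- paste(sort(clone_pair), collapse = "|")
  anchor <- sort(bs$tree$tip.label)[1]
  if (anchor %in% clone_pair)
    key <- paste(sort(setdiff(sort(bs$tree$tip.label), clone_pair)),
                 collapse = "|")
  expect_equal(unname(bs$supports[key]), 100)

  bs2 <- bootstrap_supports(gm, replicates = 60L, seed = 9L)
  expect_identical(bs$supports, bs2$supports)

  bs0 <- bootstrap_supports(gm, replicates = 0L, seed = 1L)
  expect_null(bs0$tree$node.label)
  expect_length(bs0$supports, 0L)
})

test_that("Newick export round-trips topology, lengths and labels", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(neighbor_joining(dm))
  expect_match(txt, "^\\(")
  back <- ape::read.tree(text = txt)
  expect_setequal(back$tip.label, c("A", "B", "C"))

  # metacharacter-bearing labels survive quoting
  dm2 <- dm
  dimnames(dm2) <- rep(list(c("IAC 0457-11", "A(1)", "B'x")), 2)
  tr2 <- neighbor_joining(dm2)
  txt2 <- write_newick(tr2)
  expect_match(txt2, "'IAC 0457-11'", fixed = TRUE)
  back2 <- read_newick(txt2)
  expect_setequal(back2$tip.label, rownames(dm2))

  # 50-leaf random tree round-trip
  set.seed(99)
  big <- ape::rtree(50, rooted = FALSE)
  txt3 <- write_newick(big)
  back3 <- ape::read.tree(text = txt3)
  expect_equal(as.numeric(ape::dist.topo(big, back3)), 0)
  expect_equal(sort(back3$edge.length), sort(big$edge.length),
               tolerance = 1e-9)
})
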