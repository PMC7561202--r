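#' Simulation configuration for synthetic germplasm
#'
#' Describes a germplasm bank with the statistical structure the analyses
#' assume: several ancestral gene pools in Hardy-Weinberg equilibrium at
#' unlinked multi-allelic loci, admixed hybrids, exact clonal copies
#' (duplicates under the same name, synonyms under new names), per-locus
#' null alleles and sporadic missing data. Defaults emulate a ~400-accession
#' collection typed at 17 SSR loci with 10-24 alleles each and three
#' ancestral pools.
#'
#' @param n_pools number of ancestral pools (default 3).
#' @param n_loci number of loci (default 17).
#' @param alleles_per_locus inclusive range of allele counts per locus
#'   (default `c(10, 24)`).
#' @param divergence Dirichlet concentration multiplier for drawing pool
#'   allele frequencies from a shared base; smaller = more divergent pools
#'   (default 0.5).
#' @param n_pure accessions drawn purely from each pool (recycled to
#'   `n_pools`; default `c(140, 70, 60)`).
#' @param n_admixed admixed hybrid accessions (default 100).
#' @param admix_alpha symmetric Dirichlet parameter for hybrid ancestry
#'   (default 0.5).
#' @param n_duplicate_pairs clonal copies registered under the same name
#'   (default 10).
#' @param n_synonym_groups clonal copies registered under a new name
#'   (default 10).
#' @param missing_rate independent per-call missing probability
#'   (default 0.02).
#' @param null_rate per-locus null-allele frequency, scalar or length
#'   `n_loci` (default 0; realistic test values up to ~0.21).
#' @param locus_ids optional locus names (defaults to the standard 17-marker
#'   panel names when `n_loci == 17`).
#' @param seed mandatory RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_pools = 3L, n_loci = 17L,
                       alleles_per_locus = c(10L, 24L), divergence = 0.5,
                       n_pure = c(140L, 70L, 60L), n_admixed = 100L,
                       admix_alpha = 0.5, n_duplicate_pairs = 10L,
                       n_synonym_groups = 10L, missing_rate = 0.02,
                       null_rate = 0, locus_ids = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  n_pure <- rep_len(as.integer(n_pure), n_pools)
  null_rate <- rep_len(null_rate, n_loci)
  stopifnot(n_pools >= 1L, n_loci >= 1L,
            all(alleles_per_locus >= 1L), divergence > 0,
            all(n_pure >= 0L), n_admixed >= 0L,
            n_duplicate_pairs >= 0L, n_synonym_groups >= 0L,
            missing_rate >= 0, missing_rate < 1,
            all(null_rate >= 0), all(null_rate < 1))
  if (is.null(locus_ids)) {
    std <- c("VVIn74", "VVIr09", "VVIp25b", "VVIn56", "VVIn52", "VVIq57",
             "VVIp31", "VVIp77", "VVIv36", "VVIr21", "VVS2", "VVMD5",
             "VVMD7", "VVMD25", "VVMD27", "VrZAG62", "VrZAG79")
    locus_ids <- if (n_loci <= 17L) std[seq_len(n_loci)]
                 else c(std, paste0("SSR", seq_len(n_loci - 17L)))
  }
  structure(list(n_pools = as.integer(n_pools), n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 divergence = divergence, n_pure = n_pure,
                 n_admixed = as.integer(n_admixed),
                 admix_alpha = admix_alpha,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 n_synonym_groups = as.integer(n_synonym_groups),
                 missing_rate = missing_rate, null_rate = null_rate,
                 locus_ids = locus_ids, seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a synthetic germplasm collection with ground truth
#'
#' Per locus, a base allele-frequency vector is drawn from a symmetric
#' Dirichlet over an allele set whose base-pair labels form an arithmetic
#' ladder (locus-specific step of 2-4 bp, mimicking dinucleotide/compound
#' SSR motifs); pool frequencies are drawn as
#' `Dirichlet(divergence * base)`. Pure individuals draw both allele copies
#' i.i.d. from their pool; admixed individuals draw each copy from a pool
#' sampled by their Dirichlet ancestry. Clones are exact profile copies.
#' Null alleles act at the copy level: a copy is null with the per-locus
#' rate, a null/x call renders as the homozygote x/x and null/null renders
#' as missing. Independent missingness is applied afterwards.
#'
#' @param config a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth`: per-accession
#'   `ancestry` matrix, `clone_groups` (list of accession-ID vectors, first
#'   element the original; names `"duplicate"`/`"synonym"`), `null_rate` per
#'   locus, `pool_freqs` (list locus -> pool x allele matrix), and
#'   `null_masked` (logical matrix of calls affected by nulls).
#' @export
simulate_germplasm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  P <- config$n_pools
  # allele ladders: distinct bp ranges per locus to avoid cross-locus
  # collisions in downstream bookkeeping
  n_all <- sample(seq(config$alleles_per_locus[1L],
                      config$alleles_per_locus[2L]), L, replace = TRUE)
  steps <- sample(2:4, L, replace = TRUE)
  starts <- 80L + (seq_len(L) - 1L) * 120L
  ladders <- lapply(seq_len(L), function(l)
    starts[l] + steps[l] * (seq_len(n_all[l]) - 1L))
  pool_freqs <- vector("list", L)
  names(pool_freqs) <- config$locus_ids
  for (l in seq_len(L)) {
    base <- rdirichlet1(rep(1, n_all[l]))
    pf <- t(vapply(seq_len(P), function(p)
      rdirichlet1(config$divergence * base), numeric(n_all[l])))
    colnames(pf) <- ladders[[l]]
    rownames(pf) <- paste0("pool", seq_len(P))
    pool_freqs[[l]] <- pf
  }
  n_base <- sum(config$n_pure) + config$n_admixed
  ancestry <- matrix(0, n_base, P)
  origin <- character(n_base)
  idx <- 1L
  for (p in seq_len(P)) {
    for (i in seq_len(config$n_pure[p])) {
      ancestry[idx, p] <- 1
      origin[idx] <- paste0("pool", p)
      idx <- idx + 1L
    }
  }
  for (i in seq_len(config$n_admixed)) {
    ancestry[idx, ] <- rdirichlet1(rep(config$admix_alpha, P))
    origin[idx] <- "admixed"
    idx <- idx + 1L
  }
  a1 <- a2 <- matrix(NA_integer_, n_base, L)
  for (i in seq_len(n_base)) {
    for (l in seq_len(L)) {
      copies <- integer(2L)
      for (cidx in 1:2) {
        pool <- sample.int(P, 1L, prob = ancestry[i, ])
        copies[cidx] <- sample(ladders[[l]], 1L,
                               prob = pool_freqs[[l]][pool, ])
      }
      a1[i, l] <- min(copies)
      a2[i, l] <- max(copies)
    }
  }
  ids <- sprintf("ACC%04d", seq_len(n_base))
  # null alleles at the copy level (base accessions; clones are copied
  # afterwards so clone profiles stay exactly identical)
  null_masked <- matrix(FALSE, n_base, L)
  for (l in seq_len(L)) {
    r <- config$null_rate[l]
    if (r <= 0) next
    null1 <- runif(n_base) < r
    null2 <- runif(n_base) < r
    both <- null1 & null2
    one1 <- null1 & !null2   # first copy null -> homozygote for second
    one2 <- null2 & !null1
    a1[one1, l] <- a2[one1, l]
    a2[one2, l] <- a1[one2, l]
    a1[both, l] <- NA_integer_
    a2[both, l] <- NA_integer_
    null_masked[, l] <- null1 | null2
  }
  # independent missingness
  if (config$missing_rate > 0) {
    drop <- matrix(runif(n_base * L) < config$missing_rate, n_base, L)
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  # clones: exact copies of the rendered base profiles
  clone_groups <- list()
  n_clones <- config$n_duplicate_pairs + config$n_synonym_groups
  if (n_clones > n_base) stop("more clones requested than base accessions")
  donors <- sample.int(n_base, n_clones)
  extra_a1 <- matrix(NA_integer_, n_clones, L)
  extra_a2 <- matrix(NA_integer_, n_clones, L)
  extra_ids <- character(n_clones)
  extra_anc <- matrix(0, n_clones, P)
  extra_origin <- character(n_clones)
  for (k in seq_len(n_clones)) {
    d <- donors[k]
    extra_a1[k, ] <- a1[d, ]
    extra_a2[k, ] <- a2[d, ]
    extra_anc[k, ] <- ancestry[d, ]
    extra_origin[k] <- origin[d]
    if (k <= config$n_duplicate_pairs) {
      # duplicate: same name, disambiguated by a trailing plot tag that
      # normalizes away is NOT wanted -> keep the exact same visible name
      # via a distinct internal row ID
      extra_ids[k] <- paste0(ids[d], "#dup", k)
      clone_groups[[length(clone_groups) + 1L]] <-
        structure(c(ids[d], extra_ids[k]), kind = "duplicate")
    } else {
      extra_ids[k] <- sprintf("SYN%04d", k)
      clone_groups[[length(clone_groups) + 1L]] <-
        structure(c(ids[d], extra_ids[k]), kind = "synonym")
    }
  }
  ids <- c(ids, extra_ids)
  a1 <- rbind(a1, extra_a1)
  a2 <- rbind(a2, extra_a2)
  ancestry <- rbind(ancestry, extra_anc)
  origin <- c(origin, extra_origin)
  null_masked <- rbind(null_masked, null_masked[donors, , drop = FALSE])
  meta <- data.frame(origin = origin)
  gm <- genotype_matrix(ids, config$locus_ids, a1, a2, metadata = meta)
  rownames(ancestry) <- ids
  colnames(ancestry) <- paste0("pool", seq_len(P))
  list(gm = gm,
       truth = list(ancestry = ancestry, clone_groups = clone_groups,
                    null_rate = setNames(config$null_rate, config$locus_ids),
                    pool_freqs = pool_freqs, null_masked = null_masked,
                    config = config))
}

#' Named deterministic fixture datasets
#'
#' Small seed-pinned datasets used across the test suite and documentation:
#' \describe{
#'   \item{tiny6}{6 accessions x 3 loci, constructed so that two specific
#'     accessions jointly carry every allele (brute-force core tests).}
#'   \item{threepools}{n = 90 (30 per pool), 17 loci, strongly divergent
#'     pools, no admixture, no clones, no missing data.}
#'   \item{clonebank}{20 base accessions over the 7-locus identification
#'     set plus engineered duplicates, synonyms, misnamed and unreported
#'     entries, with a matching reference panel and a construction
#'     manifest.}
#' }
#'
#' @param name one of `"tiny6"`, `"threepools"`, `"clonebank"`.
#' @return the fixture: a list with at least `gm`; `clonebank` adds
#'   `panel`, `declared_names` and `manifest`; `threepools` adds `truth`.
#' @export
fixture_library <- function(name = c("tiny6", "threepools", "clonebank")) {
  name <- match.arg(name)
  switch(name,
    tiny6 = fixture_tiny6(),
    threepools = fixture_threepools(),
    clonebank = fixture_clonebank())
}

fixture_tiny6 <- function() {
  # alleles at 3 loci; accessions A1 and A4 jointly carry all 8 alleles
  loci <- c("L1", "L2", "L3")
  ids <- paste0("A", 1:6)
  a1 <- rbind(c(100, 200, 300),
              c(102, 202, 300),
              c(100, 202, 302),
              c(104, 204, 302),
              c(102, 200, 300),
              c(100, 200, 302))
  a2 <- rbind(c(102, 202, 302),
              c(102, 202, 300),
              c(100, 204, 304),
              c(106, 206, 304),
              c(104, 202, 302),
              c(100, 204, 302))
  list(gm = genotype_matrix(ids, loci, a1, a2))
}

fixture_threepools <- function() {
  cfg <- sim_config(n_pools = 3L, n_loci = 17L, divergence = 0.3,
                    n_pure = c(30L, 30L, 30L), n_admixed = 0L,
                    n_duplicate_pairs = 0L, n_synonym_groups = 0L,
                    missing_rate = 0, null_rate = 0, seed = 20201015L)
  simulate_germplasm(cfg)
}

fixture_clonebank <- function() {
  set.seed(77001L)
  loci <- IDENTIFICATION_LOCI
  n_base <- 20L
  a1 <- a2 <- matrix(NA_integer_, n_base, length(loci))
  for (j in seq_along(loci)) {
    ladder <- 120L + 30L * j + 2L * (0:11)
    pair <- matrix(sample(ladder, 2L * n_base, replace = TRUE), ncol = 2L)
    a1[, j] <- pmin(pair[, 1L], pair[, 2L])
    a2[, j] <- pmax(pair[, 1L], pair[, 2L])
  }
  base_names <- sprintf("Variety %02d", seq_len(n_base))
  # ensure base profiles are distinct
  keys <- apply(cbind(a1, a2), 1L, paste, collapse = ",")
  while (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1L]
    a1[d, 1L] <- a1[d, 1L] + 2L
    a2[d, 1L] <- max(a1[d, 1L], a2[d, 1L])
    keys <- apply(cbind(a1, a2), 1L, paste, collapse = ",")
  }
  # panel covers varieties 1..12 under their true names
  panel <- reference_panel(
    prime_names = base_names[1:12], loci = loci,
    profiles = lapply(1:12, function(i) {
      pr <- lapply(seq_along(loci), function(j) c(a1[i, j], a2[i, j]))
      names(pr) <- loci
      pr
    }),
    sources = rep("synthetic-panel", 12L))
  # accession layout:
  #  ACC01..ACC08: varieties 1..8 declared correctly      -> validated
  #  ACC09: variety 9's profile declared as "Variety 10"  -> misnamed
  #  ACC10: variety 10's profile declared as "Variety 09" -> misnamed (swap)
  #  ACC11: novel profile declared "Variety 11"           -> unknown
  #  ACC12..ACC16: varieties 13..17 (absent from panel)   -> unreported
  #  ACC17: duplicate of ACC01 (same declared name)
  #  ACC18: synonym of ACC02 (new name)                   -> misnamed
  #  ACC19, ACC20: varieties 18..19 unreported
  pick <- c(1:8, 9, 10, NA, 13:17, 1, 2, 18, 19)
  n <- length(pick)
  A1 <- A2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    src <- pick[i]
    if (is.na(src)) {  # novel profile for the "unknown" case
      A1[i, ] <- a1[11L, ]
      A2[i, ] <- a2[11L, ] + 2L
      A2[i, ] <- pmax(A1[i, ], A2[i, ])
    } else {
      A1[i, ] <- a1[src, ]
      A2[i, ] <- a2[src, ]
    }
  }
  ids <- sprintf("ACC%02d", seq_len(n))
  declared <- c(base_names[1:8],
                "Variety 10", "Variety 09", "Variety 11",
                base_names[13:17],
                base_names[1L],          # duplicate of ACC01
                "Garnacha do Sul",       # synonym of ACC02 (= Variety 02)
                base_names[18:19])
  names(declared) <- ids
  manifest <- list(
    validated = setNames(base_names[1:8], ids[1:8]),
    misnamed = data.frame(
      accession = c("ACC09", "ACC10", "ACC18"),
      declared = c("Variety 10", "Variety 09", "Garnacha do Sul"),
      prime_name = c("Variety 09", "Variety 10", "Variety 02")),
    unknown = "ACC11",
    unreported = c(ids[12:16], "ACC19", "ACC20"),
    duplicate_groups = list(c("ACC01", "ACC17")),
    synonym_groups = list(sort(c("ACC02", "ACC18")),
                          sort(c("ACC09", "ACC10"))))
  # note ACC09/ACC10 carry different profiles (varieties 9 and 10), so they
  # are NOT a synonym pair; drop that entry
  manifest$synonym_groups <- manifest$synonym_groups[1L]
  # ACC17 validated too (same profile and name as ACC01)
  manifest$validated <- c(manifest$validated,
                          setNames(base_names[1L], "ACC17"))
  list(gm = genotype_matrix(ids, loci, A1, A2),
       panel = panel, declared_names = declared, manifest = manifest)
}
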