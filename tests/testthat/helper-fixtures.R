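# in-code fixture builders shared across the suite

# genotype matrix from "a/b" strings ("." = missing); rows accessions
gm_from_strings <- function(rows, loci, ids = paste0("S", seq_along(rows))) {
  n <- length(rows); L <- length(loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      cell <- rows[[i]][j]
      if (cell != ".") {
        p <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1L]])
        a1[i, j] <- p[1L]; a2[i, j] <- p[2L]
      }
    }
  }
  genotype_matrix(ids, loci, a1, a2)
}

# random valid genotype matrix (no missing unless asked)
random_gm <- function(n, L, n_alleles = 6L, missing_rate = 0, seed = 1L) {
  set.seed(seed)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    ladder <- 100L + 50L * j + 2L * seq_len(n_alleles)
    a1[, j] <- sample(ladder, n, replace = TRUE)
    a2[, j] <- sample(ladder, n, replace = TRUE)
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(n * L) < missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  genotype_matrix(sprintf("R%03d", seq_len(n)), paste0("L", seq_len(L)),
                  a1, a2)
}

# single-locus sample under HWE with an optional null allele of frequency r:
# returns a one-locus genotype matrix of n individuals
hwe_locus_gm <- function(n, freqs, r = 0, seed = 1L, extra_missing = 0) {
  set.seed(seed)
  sizes <- 100L + 2L * seq_along(freqs)
  p <- c(freqs * (1 - r), r)  # last index = null
  idx1 <- sample.int(length(p), n, replace = TRUE, prob = p)
  idx2 <- sample.int(length(p), n, replace = TRUE, prob = p)
  null_id <- length(p)
  a1 <- a2 <- integer(n)
  for (i in seq_len(n)) {
    i1 <- idx1[i]; i2 <- idx2[i]
    if (i1 == null_id && i2 == null_id) { a1[i] <- NA; a2[i] <- NA }
    else if (i1 == null_id) { a1[i] <- a2[i] <- sizes[i2] }
    else if (i2 == null_id) { a1[i] <- a2[i] <- sizes[i1] }
    else { a1[i] <- min(sizes[i1], sizes[i2]); a2[i] <- max(sizes[i1], sizes[i2]) }
  }
  if (extra_missing > 0) {
    drop <- runif(n) < extra_missing
    a1[drop] <- NA; a2[drop] <- NA
  }
  genotype_matrix(sprintf("I%04d", seq_len(n)), "LOC", a1, a2)
}

# two fixed diverged populations: pop A fixed for allele 100, pop B for 104,
# at L loci; plus optional F1 hybrids (100/104 at every locus)
two_pop_gm <- function(n_per_pop = 30L, L = 10L, n_f1 = 0L) {
  n <- 2L * n_per_pop + n_f1
  a1 <- a2 <- matrix(0L, n, L)
  a1[seq_len(n_per_pop), ] <- 100L
  a2[seq_len(n_per_pop), ] <- 100L
  a1[n_per_pop + seq_len(n_per_pop), ] <- 104L
  a2[n_per_pop + seq_len(n_per_pop), ] <- 104L
  if (n_f1 > 0L) {
    a1[2L * n_per_pop + seq_len(n_f1), ] <- 100L
    a2[2L * n_per_pop + seq_len(n_f1), ] <- 104L
  }
  genotype_matrix(sprintf("P%03d", seq_len(n)), paste0("L", seq_len(L)),
                  a1, a2)
}

# best mean absolute error between an estimated Q and a truth matrix over
# all column permutations of Q
ancestry_mae <- function(Q, truth) {
  K <- ncol(truth)
  perms <- ssrbank:::perm_enum(K)
  best <- Inf
  for (i in seq_len(nrow(perms)))
    best <- min(best, mean(abs(Q[, perms[i, ]] - truth)))
  best
}

brute_force_best_coverage <- function(gm, m) {
  inc <- ssrbank:::allele_incidence(gm)
  n <- nrow(inc)
  best <- 0L
  for (combo in utils::combn(n, m, simplify = FALSE)) {
    cov <- sum(colSums(inc[combo, , drop = FALSE]) > 0L)
    if (cov > best) best <- cov
  }
  best
}

# Gaussian blobs (sd 0.1, centers 10 apart along distinct axes). The K·ln(n)
# BIC penalty only yields an interior argmin when the within-cluster cloud is
# genuinely multivariate (as PC scores of marker data are); the blobs
# therefore live in 30 dimensions.
gauss_blobs <- function(n_per, d, K = 3, sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  C <- matrix(0, K, d)
  if (K > 1) for (k in 2:K) C[k, k - 1] <- sep
  do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, C[k, ], `+`)))
}
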