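# encode a genotype matrix as an n x 2L matrix of 1-based allele indices
# (0 = missing copy) plus the per-locus allele registries
encode_alleles <- function(gm) {
  n <- length(gm$accession_ids); L <- length(gm$locus_ids)
  geno <- matrix(0L, n, 2L * L)
  registry <- vector("list", L)
  names(registry) <- gm$locus_ids
  for (l in seq_len(L)) {
    sizes <- sort(unique(c(gm$a1[, l], gm$a2[, l])))
    sizes <- sizes[!is.na(sizes)]
    if (!length(sizes)) sizes <- 1L  # untyped locus: single placeholder allele
    registry[[l]] <- sizes
    t1 <- !is.na(gm$a1[, l])
    geno[t1, 2L * l - 1L] <- match(gm$a1[t1, l], sizes)
    geno[t1, 2L * l] <- match(gm$a2[t1, l], sizes)
  }
  list(geno = geno, n_alleles = vapply(registry, length, 0L),
       registry = registry)
}

#' Run the admixture-model Gibbs sampler once
#'
#' Bayesian clustering of multilocus co-dominant genotypes: each allele copy
#' carries a latent cluster of origin; cluster allele frequencies have
#' independent Dirichlet(`lambda`) priors; individual membership vectors
#' `q_i` have a symmetric Dirichlet(`alpha`) prior whose single shared
#' `alpha` is updated by a Metropolis random walk under a uniform prior on
#' `(0, alpha_max]`. `Q` and `P` are posterior means over post-burn-in
#' sweeps; the model evidence is approximated as
#' `lnPD = mean(lnL) - var(lnL)/2`. Missing allele copies contribute no
#' likelihood term. `K = 1` returns a `Q` column of exact ones.
#'
#' Defaults mirror the full-scale analysis (burn-in 1e5, 1e6 recorded
#' sweeps); the scaled-down mode (e.g. `burnin = 2000, iters = 10000`) is a
#' first-class configuration used by all tests.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param burnin burn-in sweeps.
#' @param iters post-burn-in sweeps.
#' @param seed RNG seed (mandatory; no hidden global state).
#' @param lambda Dirichlet parameter for cluster allele frequencies.
#' @param alpha initial value of the membership Dirichlet parameter.
#' @param update_alpha Metropolis-update `alpha` (default) or keep it fixed.
#' @param alpha_propsd random-walk proposal sd for `alpha`.
#' @param alpha_max upper bound of the uniform prior on `alpha`.
#' @param thin record the log-likelihood every `thin` sweeps.
#' @return object of class `admixture_run`: `K`, `Q` (n x K, rows sum to 1),
#'   `P` (per-cluster allele frequencies, list by locus), `lnL_trace`,
#'   `lnPD`, `alpha`, `seed`, `burnin`, `iters`.
#' @export
run_admixture <- function(gm, K, burnin = 100000L, iters = 1000000L, seed,
                          lambda = 1, alpha = 1, update_alpha = TRUE,
                          alpha_propsd = 0.025, alpha_max = 10,
                          thin = max(1L, iters %/% 1000L)) {
  stopifnot_gm(gm)
  if (K < 1L) stop("K must be a positive integer")
  if (missing(seed)) stop("seed is required")
  if (iters < 1L || iters < thin)
    stop("iters must cover at least one recording window")
  enc <- encode_alleles(gm)
  set.seed(seed)
  fit <- admixture_gibbs_cpp(enc$geno, enc$n_alleles, as.integer(K),
                             as.integer(burnin), as.integer(iters),
                             as.integer(thin), lambda, alpha, update_alpha,
                             alpha_propsd, alpha_max)
  Q <- fit$Q
  if (K == 1L) Q[] <- 1
  rownames(Q) <- gm$accession_ids
  colnames(Q) <- paste0("C", seq_len(K))
  lnl <- fit$lnL_trace
  lnPD <- mean(lnl) - if (length(lnl) > 1L) var(lnl) / 2 else 0
  # unpack P into per-locus matrices K x n_alleles
  P <- vector("list", length(gm$locus_ids))
  names(P) <- gm$locus_ids
  off <- 0L
  for (l in seq_along(P)) {
    J <- enc$n_alleles[l]
    M <- fit$P[, off + seq_len(J), drop = FALSE]
    colnames(M) <- enc$registry[[l]]
    rownames(M) <- colnames(Q)
    P[[l]] <- M
    off <- off + J
  }
  structure(list(K = as.integer(K), Q = Q, P = P, lnL_trace = lnl,
                 lnPD = lnPD, alpha = fit$alpha, seed = seed,
                 burnin = burnin, iters = iters),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture_run: K=%d, n=%d, lnPD=%.2f (burnin %d, iters %d, seed %s)\n",
              x$K, nrow(x$Q), x$lnPD, x$burnin, x$iters, format(x$seed)))
  invisible(x)
}

#' Multi-K, multi-run admixture scan
#'
#' Runs the sampler `runs_per_K` times for each K in `K_range` (per-run
#' seeds derived deterministically from `seed`), then summarizes model
#' evidence with [evanno()].
#'
#' @inheritParams run_admixture
#' @param K_range consecutive K values to scan (default 1:10).
#' @param runs_per_K independent runs per K (default 10).
#' @param ... passed to [run_admixture()].
#' @return object of class `admixture_scan`: `runs` (list keyed
#'   `"K<k>.r<j>"`), `evanno` (the [evanno()] table), `best_K`.
#' @export
admixture_scan <- function(gm, K_range = 1:10, runs_per_K = 10L,
                           burnin = 100000L, iters = 1000000L, seed, ...) {
  if (missing(seed)) stop("seed is required")
  K_range <- sort(unique(as.integer(K_range)))
  runs <- list()
  for (K in K_range) {
    for (j in seq_len(runs_per_K)) {
      run_seed <- derive_seed(seed, K * 1000L + j)
      runs[[sprintf("K%d.r%d", K, j)]] <-
        run_admixture(gm, K, burnin = burnin, iters = iters,
                      seed = run_seed, ...)
    }
  }
  ev <- evanno(runs)
  structure(list(runs = runs, evanno = ev,
                 best_K = attr(ev, "best_K")),
            class = "admixture_scan")
}

#' @export
print.admixture_scan <- function(x, ...) {
  cat(sprintf("admixture_scan: K in {%s}, best K = %s by Evanno delta-K\n",
              paste(x$evanno$K, collapse = ", "), format(x$best_K)))
  invisible(x)
}

# deterministic stage/run seed derivation, kept below 2^31
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset)) %% 2147483629)
}

#' Evanno delta-K table
#'
#' Summarizes model evidence `lnPD` across runs grouped by K:
#' `L'(K) = mean lnPD(K) - mean lnPD(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|`,
#' `deltaK = |L''(K)| / sd(lnPD at K)`. `deltaK` is defined only for interior
#' K; when `sd = 0` at some K it is reported as `Inf` with a warning, never
#' silently dropped. The attribute `best_K` is the interior argmax of
#' `deltaK`.
#'
#' @param runs either a list of `admixture_run` objects or a data.frame with
#'   columns `K` and `lnPD` (one row per run).
#' @return data.frame with columns `K`, `n_runs`, `mean_lnPD`, `sd_lnPD`,
#'   `Lp` (L'), `Lpp_abs` (|L''|), `deltaK`; attribute `best_K`.
#' @export
evanno <- function(runs) {
  tab <- if (is.data.frame(runs)) runs else
    data.frame(K = vapply(runs, function(r) r$K, 0L),
               lnPD = vapply(runs, function(r) r$lnPD, 0))
  if (!all(c("K", "lnPD") %in% names(tab))) stop("need columns K and lnPD")
  Ks <- sort(unique(tab$K))
  if (length(Ks) < 3L || !all(diff(Ks) == 1L))
    stop("Evanno requires >= 3 consecutive K values")
  agg <- data.frame(K = Ks,
                    n_runs = vapply(Ks, function(k) sum(tab$K == k), 0L),
                    mean_lnPD = vapply(Ks, function(k) mean(tab$lnPD[tab$K == k]), 0),
                    sd_lnPD = vapply(Ks, function(k) {
                      v <- tab$lnPD[tab$K == k]
                      if (length(v) > 1L) sd(v) else NA_real_
                    }, 0))
  m <- nrow(agg)
  agg$Lp <- c(NA, diff(agg$mean_lnPD))
  agg$Lpp_abs <- c(NA, abs(diff(agg$Lp[-1L])), NA)
  agg$deltaK <- NA_real_
  for (i in seq_len(m)) {
    if (i == 1L || i == m) next
    s <- agg$sd_lnPD[i]
    if (is.na(s)) {
      warning("fewer than 2 runs at K=", agg$K[i], "; deltaK undefined")
      next
    }
    if (s == 0) {
      warning("sd(lnPD) = 0 at K=", agg$K[i], "; deltaK reported as Inf")
      agg$deltaK[i] <- Inf
    } else {
      agg$deltaK[i] <- agg$Lpp_abs[i] / s
    }
  }
  best <- if (all(is.na(agg$deltaK))) NA_integer_ else
    agg$K[which.max(agg$deltaK)]
  attr(agg, "best_K") <- best
  agg
}

# Frobenius-agreement similarity between two membership matrices
clumpp_G <- function(Qa, Qb) {
  1 - sqrt(sum((Qa - Qb)^2)) / sqrt(2 * nrow(Qa))
}

#' Align admixture runs by column permutation (CLUMPP greedy)
#'
#' Picks the first run as reference; for every other run chooses the column
#' permutation maximizing the pairwise similarity
#' `G = 1 - ||Q_ref - Q_perm||_F / sqrt(2n)`. The permutation search is
#' exhaustive for `K <= 8` and greedy (best unmatched column pair first)
#' above.
#'
#' @param runs list of `admixture_run` objects or of n x K membership
#'   matrices, all sharing n and K.
#' @return list with `Q_list` (aligned membership matrices),
#'   `permutations`, `mean_G` (mean similarity of aligned runs to the
#'   reference), and `Q_mean` (element-wise mean of the aligned matrices,
#'   rows renormalized to sum to 1).
#' @export
align_runs_greedy <- function(runs) {
  Qs <- lapply(runs, function(r) if (inherits(r, "admixture_run")) r$Q else as.matrix(r))
  if (length(Qs) < 1L) stop("no runs to align")
  dims <- vapply(Qs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all runs must share n and K")
  K <- ncol(Qs[[1L]])
  ref <- Qs[[1L]]
  perms <- vector("list", length(Qs))
  perms[[1L]] <- seq_len(K)
  G <- numeric(length(Qs))
  G[1L] <- 1
  for (r in seq_along(Qs)[-1L]) {
    Q <- Qs[[r]]
    if (K <= 8L) {
      allp <- perm_enum(K)
      best <- NULL; bestG <- -Inf
      for (pi in seq_len(nrow(allp))) {
        g <- clumpp_G(ref, Q[, allp[pi, ], drop = FALSE])
        if (g > bestG) { bestG <- g; best <- allp[pi, ] }
      }
    } else {
      # greedy: repeatedly match the closest (ref column, run column) pair
      cost <- matrix(0, K, K)
      for (a in seq_len(K)) for (b in seq_len(K))
        cost[a, b] <- sum((ref[, a] - Q[, b])^2)
      best <- integer(K)
      free_a <- free_b <- seq_len(K)
      while (length(free_a)) {
        sub <- cost[free_a, free_b, drop = FALSE]
        w <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
        best[free_a[w[1L]]] <- free_b[w[2L]]
        free_a <- free_a[-w[1L]]
        free_b <- free_b[-w[2L]]
      }
      bestG <- clumpp_G(ref, Q[, best, drop = FALSE])
    }
    Qa <- Q[, best, drop = FALSE]
    colnames(Qa) <- colnames(ref)
    Qs[[r]] <- Qa
    perms[[r]] <- best
    G[r] <- bestG
  }
  Qm <- Reduce(`+`, Qs) / length(Qs)
  Qm <- Qm / rowSums(Qm)
  list(Q_list = Qs, permutations = perms,
       mean_G = if (length(Qs) > 1L) mean(G[-1L]) else 1,
       Q_mean = Qm)
}

perm_enum <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_enum(K - 1L)
  out <- matrix(0L, 0L, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                   sub[, seq(pos, K - 1L)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Threshold classification of averaged memberships
#'
#' An individual is assigned to its argmax cluster when the maximum
#' membership is at least `threshold` (inclusive), and labeled `"admixed"`
#' otherwise.
#'
#' @param Q n x K membership matrix with rows summing to 1 (typically the
#'   `Q_mean` of [align_runs_greedy()]).
#' @param threshold assignment threshold in `(1/K, 1]` (default 0.70).
#' @return character vector of labels (cluster column names or `"admixed"`),
#'   named by the rownames of `Q`.
#' @export
assign_memberships <- function(Q, threshold = 0.70) {
  Q <- as.matrix(Q)
  K <- ncol(Q)
  if (threshold <= 1 / K || threshold > 1)
    stop("threshold must lie in (1/K, 1]")
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("rows of Q must sum to 1")
  cl <- colnames(Q)
  if (is.null(cl)) cl <- paste0("C", seq_len(K))
  lab <- ifelse(apply(Q, 1L, max) >= threshold,
                cl[apply(Q, 1L, which.max)], "admixed")
  names(lab) <- rownames(Q)
  lab
}

#' Hierarchical (second-round) admixture analysis
#'
#' Reruns the full scan/Evanno/align/assign stack independently on each
#' first-round cluster, including the admixed group. Subsets smaller than
#' `2 * max(K_range)` are skipped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param labels first-round labels (named by accession), e.g. from
#'   [assign_memberships()].
#' @inheritParams admixture_scan
#' @param threshold assignment threshold for the second round.
#' @return named list per first-round group with elements `evanno`,
#'   `best_K`, `Q_mean`, `labels` (nested labels `"<group>/<sub>"`), or
#'   `NULL` for skipped groups; attribute `nested_labels` collects all
#'   second-round labels.
#' @export
hierarchical_rounds <- function(gm, labels, K_range = 1:10, runs_per_K = 10L,
                                burnin = 100000L, iters = 1000000L, seed,
                                threshold = 0.70, ...) {
  stopifnot_gm(gm)
  if (missing(seed)) stop("seed is required")
  if (is.null(names(labels))) names(labels) <- gm$accession_ids
  groups <- sort(unique(labels))
  out <- setNames(vector("list", length(groups)), groups)
  nested <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    members <- names(labels)[labels == g]
    if (length(members) < 2L * max(K_range)) {
      warning("group '", g, "' has fewer than ", 2L * max(K_range),
              " accessions; skipped")
      next
    }
    sub <- gm[members, ]
    scan <- admixture_scan(sub, K_range = K_range, runs_per_K = runs_per_K,
                           burnin = burnin, iters = iters,
                           seed = derive_seed(seed, gi), ...)
    bK <- scan$best_K
    runs_at_best <- scan$runs[vapply(scan$runs, function(r) r$K, 0L) == bK]
    al <- align_runs_greedy(runs_at_best)
    sub_lab <- if (bK >= 2L)
      assign_memberships(al$Q_mean, threshold = threshold)
    else setNames(rep("C1", length(members)), members)
    full <- setNames(paste0(g, "/", sub_lab), names(sub_lab))
    nested <- c(nested, full)
    out[[g]] <- list(evanno = scan$evanno, best_K = bK,
                     Q_mean = al$Q_mean, labels = full)
  }
  attr(out, "nested_labels") <- nested
  out
}
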