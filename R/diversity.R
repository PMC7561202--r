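#' Allele frequencies at one locus
#'
#' Counts both allele copies of every typed call; missing calls are excluded
#' from the denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus ID or index.
#' @return list with `locus_id`, `freqs` (named numeric, allele size ->
#'   relative frequency, all > 0, summing to 1), and `n_typed` (typed
#'   accessions). With zero typed calls, `freqs` is empty and `n_typed` 0.
#' @export
allele_frequencies <- function(gm, locus) {
  stopifnot_gm(gm)
  j <- locus_index(gm, locus)
  alleles <- c(gm$a1[, j], gm$a2[, j])
  alleles <- alleles[!is.na(alleles)]
  n_typed <- length(alleles) %/% 2L
  if (!n_typed)
    return(list(locus_id = gm$locus_ids[j], freqs = numeric(0), n_typed = 0L))
  tab <- table(alleles)
  list(locus_id = gm$locus_ids[j],
       freqs = setNames(as.numeric(tab) / length(alleles), names(tab)),
       n_typed = n_typed)
}

#' Single-locus genotype-pattern frequencies
#'
#' A pattern is the full unordered single-locus genotype (the "banding
#' pattern" the marker reveals), the unit over which discriminating power is
#' defined.
#'
#' @inheritParams allele_frequencies
#' @return list with `locus_id`, `pattern_freqs` (named numeric, `"a/b"` ->
#'   frequency), `N` typed samples and `I` distinct patterns.
#' @export
pattern_frequencies <- function(gm, locus) {
  stopifnot_gm(gm)
  j <- locus_index(gm, locus)
  t1 <- !is.na(gm$a1[, j])
  pats <- paste0(gm$a1[t1, j], "/", gm$a2[t1, j])
  tab <- table(pats)
  list(locus_id = gm$locus_ids[j],
       pattern_freqs = setNames(as.numeric(tab) / length(pats), names(tab)),
       N = length(pats), I = length(tab))
}

#' Polymorphism information content (PIC)
#'
#' Botstein's marker informativeness:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2}
#' over the `n` observed alleles with frequencies `p`.
#'
#' @param freqs an allele-frequency table from [allele_frequencies()], or a
#'   bare numeric vector of frequencies.
#' @return PIC in `[0, 1]`; always `<=` expected heterozygosity.
#' @export
pic <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freqs else freqs
  if (!length(p)) stop("empty allele-frequency table")
  s2 <- sum(p^2)
  # double sum 2 sum_{i<j} p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Discriminating power of a marker
#'
#' Tessier's probability that two randomly selected samples show different
#' single-locus patterns, with finite-sample correction:
#' \deqn{D_j = 1 - \sum_{i=1}^{I} p_i \frac{N p_i - 1}{N - 1}}
#'
#' @param patterns a pattern-frequency table from [pattern_frequencies()].
#' @return Dj in `[0, 1]`.
#' @export
discriminating_power <- function(patterns) {
  N <- patterns$N
  if (N < 2L) stop("discriminating power requires N >= 2 typed samples")
  p <- patterns$pattern_freqs
  1 - sum(p * (N * p - 1) / (N - 1))
}

#' Per-locus diversity summary
#'
#' Computes, for one locus: Na (distinct alleles), Ne (effective alleles,
#' `1/sum(p^2)`), Ho (observed heterozygosity: fraction of typed calls that
#' are heterozygous), He (expected heterozygosity, `1 - sum(p^2)`; the
#' unbiased `2N/(2N-1)` variant via `unbiased = TRUE`), F (fixation index
#' `(He - Ho)/He`, `NA` when `He = 0`), PIC, Dj, and optionally the
#' null-allele frequency r.
#'
#' @inheritParams allele_frequencies
#' @param unbiased apply the `2N/(2N-1)` small-sample correction to He.
#' @param null_r also estimate the null-allele frequency (slower).
#' @return one-row data.frame with columns `locus`, `Na`, `Ne`, `Ho`, `He`,
#'   `F`, `PIC`, `Dj`, `r`.
#' @export
locus_summary <- function(gm, locus, unbiased = FALSE, null_r = FALSE) {
  af <- allele_frequencies(gm, locus)
  if (!af$n_typed) stop("no typed calls at locus ", af$locus_id)
  p <- af$freqs
  s2 <- sum(p^2)
  Na <- length(p)
  Ne <- 1 / s2
  He <- 1 - s2
  if (unbiased) He <- He * 2 * af$n_typed / (2 * af$n_typed - 1)
  j <- locus_index(gm, locus)
  t1 <- !is.na(gm$a1[, j])
  Ho <- mean(gm$a1[t1, j] != gm$a2[t1, j])
  Fi <- if (He > 0) (He - Ho) / He else NA_real_
  Dj <- if (af$n_typed >= 2L) discriminating_power(pattern_frequencies(gm, locus)) else NA_real_
  r <- if (null_r) null_allele_frequency(gm, locus) else NA_real_
  data.frame(locus = af$locus_id, Na = Na, Ne = Ne, Ho = Ho, He = He,
             F = Fi, PIC = pic(p), Dj = Dj, r = r, stringsAsFactors = FALSE)
}

#' Null-allele frequency by expectation-maximization
#'
#' Treats the null as one extra unobservable allele under Hardy-Weinberg
#' proportions: an observed homozygote `a/a` may be a true `a/a` or `a/null`.
#' Phase 1 fits the EM on typed calls only, excluding putative null
#' homozygotes (missing calls) from the likelihood; phase 2 (default on)
#' re-includes missing calls as candidate `null/null` genotypes alongside a
#' free non-genetic failure rate, so amplification failures unrelated to
#' nulls do not inflate the estimate.
#'
#' @inheritParams allele_frequencies
#' @param include_missing run phase 2 (default `TRUE`).
#' @param tol convergence threshold on `|delta r|` (default `1e-6`).
#' @param max_iter iteration cap (default 1000).
#' @param min_typed below this many typed calls the estimate is returned as
#'   `NA` with a warning (default 10).
#' @return maximum-likelihood estimate of r in `[0, 1)`; ~0 when there is no
#'   homozygote excess.
#' @export
null_allele_frequency <- function(gm, locus, include_missing = TRUE,
                                  tol = 1e-6, max_iter = 1000L,
                                  min_typed = 10L) {
  stopifnot_gm(gm)
  j <- locus_index(gm, locus)
  t1 <- !is.na(gm$a1[, j])
  n_typed <- sum(t1)
  if (n_typed < min_typed) {
    warning("fewer than ", min_typed, " typed calls at locus ",
            gm$locus_ids[j], "; null-allele frequency undefined")
    return(NA_real_)
  }
  obs1 <- gm$a1[t1, j]; obs2 <- gm$a2[t1, j]
  alleles <- sort(unique(c(obs1, obs2)))
  A <- length(alleles)
  if (A < 2L) return(0)
  i1 <- match(obs1, alleles); i2 <- match(obs2, alleles)
  hom <- i1 == i2
  n_missing <- sum(!t1)

  em <- function(use_missing) {
    # pi: visible allele freqs; r: null freq (sum(pi) + r = 1);
    # m: non-genetic failure rate (phase 2 only)
    cnt <- tabulate(c(i1, i2), A)
    pi <- cnt / sum(cnt) * 0.95
    r <- 0.05
    m <- if (use_missing) max(0.01, n_missing / (n_typed + n_missing) - r^2) else 0
    for (it in seq_len(max_iter)) {
      r_old <- r
      # E-step for observed homozygotes a/a:
      #   P(a/null | obs hom a) = 2 r / (pi_a + 2 r)  -> w null copies each
      w <- 2 * r / (pi[i1[hom]] + 2 * r)
      copy_cnt <- tabulate(c(i1[!hom], i2[!hom]), A) +
        rowsum_simple(2 - w, i1[hom], A)
      null_copies <- sum(w)
      n_geno <- n_typed
      if (use_missing && n_missing > 0L) {
        # a missing call is null/null (prob (1-m) r^2) or a non-genetic
        # failure (prob m) whose alleles carry no information
        pr_nn <- (1 - m) * r^2
        w_nn <- if (pr_nn + m > 0) pr_nn / (pr_nn + m) else 0
        null_copies <- null_copies + 2 * w_nn * n_missing
        n_geno <- n_geno + w_nn * n_missing
        m <- (1 - w_nn) * n_missing / (n_typed + n_missing)
      } else {
        # phase 1 conditions on "typed": latent null/null individuals are
        # unobservable, expected count n_typed r^2/(1-r^2)
        n_nn <- n_typed * r^2 / max(1 - r^2, 1e-12)
        null_copies <- null_copies + 2 * n_nn
        n_geno <- n_geno + n_nn
      }
      tot <- 2 * n_geno
      r <- null_copies / tot
      pi <- copy_cnt / tot
      s <- sum(pi) + r
      pi <- pi / s
      r <- r / s
      if (abs(r - r_old) < tol) break
    }
    max(0, min(r, 1 - 1e-9))
  }

  r1 <- em(use_missing = FALSE)
  if (!include_missing || n_missing == 0L) return(r1)
  em(use_missing = TRUE)
}

rowsum_simple <- function(x, g, nbins) {
  out <- numeric(nbins)
  if (length(x)) {
    agg <- rowsum(x, g)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Private and rare alleles
#'
#' An allele is private to group `g` iff it is observed in `g` and in no
#' other group; it is rare iff its whole-collection frequency is strictly
#' below `rare_threshold`.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping named character vector accession -> group label (an
#'   explicit `"admixed"` label counts as a group); every accession must be
#'   labeled.
#' @param rare_threshold strict upper bound for "rare" (default 0.05).
#' @return list with `private` (per group, data.frame locus/allele/freq) and
#'   `rare` (data.frame locus/allele/freq over the whole collection).
#' @export
private_and_rare_alleles <- function(gm, grouping, rare_threshold = 0.05) {
  stopifnot_gm(gm)
  if (!all(names(grouping) %in% gm$accession_ids))
    stop("unknown accession in grouping: ",
         paste(setdiff(names(grouping), gm$accession_ids), collapse = ", "))
  if (!all(gm$accession_ids %in% names(grouping)))
    stop("unlabeled accession(s): ",
         paste(setdiff(gm$accession_ids, names(grouping)), collapse = ", "))
  groups <- sort(unique(grouping))
  private <- setNames(vector("list", length(groups)), groups)
  for (g in groups) private[[g]] <- data.frame(locus = character(0),
                                               allele = integer(0),
                                               freq = numeric(0))
  rare <- data.frame(locus = character(0), allele = integer(0), freq = numeric(0))
  glab <- grouping[gm$accession_ids]
  for (j in seq_along(gm$locus_ids)) {
    af <- allele_frequencies(gm, j)
    if (!length(af$freqs)) next
    sizes <- as.integer(names(af$freqs))
    rare_here <- af$freqs < rare_threshold
    if (any(rare_here))
      rare <- rbind(rare, data.frame(locus = af$locus_id,
                                     allele = sizes[rare_here],
                                     freq = unname(af$freqs[rare_here])))
    # per-group presence
    present <- sapply(groups, function(g) {
      sel <- glab == g
      obs <- c(gm$a1[sel, j], gm$a2[sel, j])
      sizes %in% obs
    })
    if (is.null(dim(present))) present <- matrix(present, nrow = length(sizes))
    n_groups_with <- rowSums(present)
    for (gi in seq_along(groups)) {
      pv <- present[, gi] & n_groups_with == 1L
      if (any(pv))
        private[[groups[gi]]] <- rbind(
          private[[groups[gi]]],
          data.frame(locus = af$locus_id, allele = sizes[pv],
                     freq = unname(af$freqs[pv])))
    }
  }
  list(private = private, rare = rare)
}

#' Diversity table over all loci
#'
#' One [locus_summary()] row per locus, mirroring the standard marker report
#' (locus, Na, Ne, Ho, He, F, PIC, Dj, r).
#'
#' @inheritParams locus_summary
#' @return data.frame with one row per locus.
#' @export
diversity_table <- function(gm, unbiased = FALSE, null_r = TRUE) {
  stopifnot_gm(gm)
  do.call(rbind, lapply(gm$locus_ids, function(l)
    locus_summary(gm, l, unbiased = unbiased, null_r = null_r)))
}

#' Collection-wide totals and means across loci
#'
#' Totals sum Na and Ne over loci (the "Total" row convention of marker
#' tables); means and standard errors (`sd/sqrt(L)`) are across loci, with
#' undefined F values excluded from the F mean.
#'
#' @param gm a [genotype_matrix()] or a precomputed [diversity_table()].
#' @param ... passed to [diversity_table()] when `gm` is a genotype matrix.
#' @return list with `table` (per-locus), `total` (Na, Ne), `mean` and `se`
#'   (named vectors over Na, Ne, Ho, He, F, PIC, Dj, r).
#' @export
collection_summary <- function(gm, ...) {
  tab <- if (is.data.frame(gm)) gm else diversity_table(gm, ...)
  stats_cols <- c("Na", "Ne", "Ho", "He", "F", "PIC", "Dj", "r")
  stats_cols <- intersect(stats_cols, names(tab))
  mu <- vapply(stats_cols, function(cn) mean(tab[[cn]], na.rm = TRUE), 0)
  se <- vapply(stats_cols, function(cn) {
    v <- tab[[cn]][!is.na(tab[[cn]])]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  }, 0)
  list(table = tab,
       total = c(Na = sum(tab$Na), Ne = sum(tab$Ne)),
       mean = mu, se = se)
}
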