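# distinct (locus, allele) pairs carried by each accession, as an n x A
# logical incidence matrix over the collection's full allele set
allele_incidence <- function(gm) {
  key <- character(0)
  for (j in seq_along(gm$locus_ids)) {
    t1 <- !is.na(gm$a1[, j])
    sizes <- sort(unique(c(gm$a1[t1, j], gm$a2[t1, j])))
    key <- c(key, paste0(gm$locus_ids[j], ".", sizes))
  }
  inc <- matrix(FALSE, length(gm$accession_ids), length(key),
                dimnames = list(gm$accession_ids, key))
  for (j in seq_along(gm$locus_ids)) {
    t1 <- which(!is.na(gm$a1[, j]))
    for (i in t1) {
      inc[i, paste0(gm$locus_ids[j], ".",
                    unique(c(gm$a1[i, j], gm$a2[i, j])))] <- TRUE
    }
  }
  inc
}

obj_greater <- function(a, b, tol = 1e-12) {
  if (a[1L] != b[1L]) return(a[1L] > b[1L])
  a[2L] > b[2L] + tol
}

#' Select a core collection maximizing allele coverage
#'
#' Picks `m = ceiling(fraction * n)` accessions (or exactly `size_absolute`)
#' whose union of alleles is as large as possible. Greedy seeding (each step
#' adds the accession contributing most unseen alleles; ties broken by the
#' largest mean Rogers distance to the current members, then
#' lexicographically) followed by steepest-ascent single-swap local search on
#' the objective (allele coverage, with mean expected heterozygosity of the
#' subset as secondary criterion). Additional random-start restarts explore
#' alternative optima; results are deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param fraction requested size fraction in `(0, 1]`.
#' @param objective `"coverage"` (allele capture, default) or `"EN"`
#'   (average entry-to-nearest-entry Rogers distance).
#' @param seed RNG seed for the random restarts.
#' @param restarts total number of starts (1 greedy + `restarts - 1` random).
#' @param size_absolute exact core size overriding the fractional rounding.
#' @return object of class `core_collection`: `fraction`, `members`,
#'   `alleles_captured`, `coverage_pct`, `summary` (see [evaluate_core()]).
#' @export
select_core <- function(gm, fraction, objective = c("coverage", "EN"),
                        seed = 1L, restarts = 10L, size_absolute = NULL) {
  stopifnot_gm(gm)
  objective <- match.arg(objective)
  n <- length(gm$accession_ids)
  m <- if (!is.null(size_absolute)) as.integer(size_absolute)
       else as.integer(ceiling(fraction * n))
  if (is.null(size_absolute) && (fraction <= 0 || fraction > 1))
    stop("fraction must lie in (0, 1]")
  if (m < 1L || m > n) stop("core size out of range")
  inc <- allele_incidence(gm)
  D <- rogers_distance(gm)
  he_cache <- new.env(parent = emptyenv())
  he_fun <- function(members) {
    key <- paste(sort(members), collapse = ",")
    if (!is.null(he_cache[[key]])) return(he_cache[[key]])
    sub <- gm[gm$accession_ids[members], ]
    he <- mean(vapply(seq_along(sub$locus_ids), function(j) {
      af <- allele_frequencies(sub, j)
      if (length(af$freqs)) 1 - sum(af$freqs^2) else NA_real_
    }, 0), na.rm = TRUE)
    he_cache[[key]] <- he
    he
  }
  en_fun <- function(members) {
    if (length(members) < 2L) return(0)
    sub <- D[members, members, drop = FALSE]
    diag(sub) <- Inf
    mean(apply(sub, 1L, min))
  }
  cov_fun <- function(members) {
    if (objective == "coverage")
      sum(colSums(inc[members, , drop = FALSE]) > 0L)
    else en_fun(members)
  }
  sec_fun <- function(members) {
    if (objective == "coverage") he_fun(members) else 0
  }
  # steepest-ascent single-swap search; the secondary criterion (mean He)
  # is only evaluated on primary-objective ties
  improve <- function(members) {
    cur_cov <- cov_fun(members)
    cur_sec <- sec_fun(members)
    repeat {
      best_swap <- NULL
      best_cov <- cur_cov
      best_sec <- cur_sec
      outside <- setdiff(seq_len(n), members)
      for (out_i in seq_along(members)) {
        for (in_i in outside) {
          cand <- members
          cand[out_i] <- in_i
          cc <- cov_fun(cand)
          if (cc < best_cov) next
          if (cc > best_cov) {
            best_cov <- cc
            best_sec <- sec_fun(cand)
            best_swap <- c(out_i, in_i)
          } else {
            cs <- sec_fun(cand)
            if (cs > best_sec + 1e-12) {
              best_sec <- cs
              best_swap <- c(out_i, in_i)
            }
          }
        }
      }
      if (is.null(best_swap)) break
      members[best_swap[1L]] <- best_swap[2L]
      cur_cov <- best_cov
      cur_sec <- best_sec
    }
    list(members = members, obj = c(coverage = cur_cov, he = cur_sec))
  }
  greedy_seed <- function() {
    members <- integer(0)
    seen <- rep(FALSE, ncol(inc))
    for (step in seq_len(m)) {
      gain <- vapply(seq_len(n), function(i) {
        if (i %in% members) -1L else sum(inc[i, ] & !seen)
      }, 0L)
      cand <- which(gain == max(gain))
      if (length(cand) > 1L && length(members)) {
        md <- vapply(cand, function(i) mean(D[i, members]), 0)
        cand <- cand[md >= max(md) - 1e-12]
      }
      pick <- cand[order(gm$accession_ids[cand])][1L]
      members <- c(members, pick)
      seen <- seen | inc[pick, ]
    }
    members
  }
  set.seed(seed)
  starts <- c(list(greedy_seed()),
              lapply(seq_len(max(0L, restarts - 1L)),
                     function(s) sample.int(n, m)))
  best <- NULL
  for (st in starts) {
    res <- improve(st)
    if (is.null(best) || obj_greater(res$obj, best$obj)) best <- res
  }
  members <- sort(gm$accession_ids[best$members])
  summary <- evaluate_core(gm, members)
  structure(list(fraction = if (is.null(size_absolute)) fraction else m / n,
                 members = members,
                 alleles_captured = summary$alleles_captured,
                 coverage_pct = summary$coverage_pct,
                 summary = summary),
            class = "core_collection")
}

#' @export
print.core_collection <- function(x, ...) {
  cat(sprintf("core_collection: %d accessions (fraction %.3g), %d alleles captured (%.2f%%)\n",
              length(x$members), x$fraction, x$alleles_captured,
              x$coverage_pct))
  invisible(x)
}

#' Evaluate a core subset's diversity
#'
#' Recomputes the per-locus statistics on the subset and reports the
#' marker-table totals (Na and Ne summed over loci), mean Ho and He, and the
#' percentage of the whole collection's alleles captured.
#'
#' @param gm the full [genotype_matrix()].
#' @param members accession IDs of the subset.
#' @return list with `n`, `alleles_captured`, `coverage_pct`, `Na_total`,
#'   `Ne_total`, `Ho_mean`, `He_mean`, `table` (per-locus data.frame).
#' @export
evaluate_core <- function(gm, members) {
  stopifnot_gm(gm)
  if (!length(members)) stop("empty subset")
  if (!all(members %in% gm$accession_ids))
    stop("unknown member accession(s)")
  inc <- allele_incidence(gm)
  total_alleles <- ncol(inc)
  captured <- sum(colSums(inc[members, , drop = FALSE]) > 0L)
  sub <- gm[members, ]
  tab <- diversity_table(sub, null_r = FALSE)
  list(n = length(members),
       alleles_captured = captured,
       coverage_pct = 100 * captured / total_alleles,
       Na_total = sum(tab$Na),
       Ne_total = sum(tab$Ne),
       Ho_mean = mean(tab$Ho),
       He_mean = mean(tab$He),
       table = tab)
}

#' Core collections at several size fractions
#'
#' Convenience wrapper running [select_core()] at each fraction (default
#' 0.1, 0.2, 0.3) and assembling the evaluation table.
#'
#' @inheritParams select_core
#' @param fractions numeric vector of size fractions.
#' @return list with `cores` (list of `core_collection`) and `table`
#'   (data.frame mirroring the usual core-comparison layout).
#' @export
core_collection_series <- function(gm, fractions = c(0.1, 0.2, 0.3),
                                   seed = 1L, restarts = 10L) {
  cores <- lapply(seq_along(fractions), function(i)
    select_core(gm, fractions[i], seed = derive_seed(seed, i),
                restarts = restarts))
  names(cores) <- paste0("core_", fractions)
  full <- evaluate_core(gm, gm$accession_ids)
  tab <- do.call(rbind, lapply(cores, function(cc)
    data.frame(size = cc$fraction, N = cc$summary$n,
               Na = cc$summary$alleles_captured, Ne = cc$summary$Ne_total,
               Ho = cc$summary$Ho_mean, He = cc$summary$He_mean,
               coverage_pct = cc$coverage_pct)))
  tab <- rbind(tab, data.frame(size = 1, N = full$n, Na = full$Na_total,
                               Ne = full$Ne_total, Ho = full$Ho_mean,
                               He = full$He_mean, coverage_pct = 100))
  rownames(tab) <- c(names(cores), "collection")
  list(cores = cores, table = tab)
}
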