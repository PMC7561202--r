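#' Allele-indicator matrix for multivariate analysis
#'
#' One column per (locus, allele); entries are the within-individual relative
#' frequency of the allele (0, 0.5 or 1). Missing calls are imputed with the
#' column mean (configurable to zero-fill), and columns are centered so the
#' matrix is ready for PCA.
#'
#' @param gm a [genotype_matrix()].
#' @param impute `"mean"` (default) or `"zero"` for missing calls.
#' @param center center the columns (default `TRUE`).
#' @return numeric matrix `n x sum(Na)` with a `key` attribute (data.frame
#'   `locus`, `allele` per column) and a `col_center` attribute.
#' @export
allele_indicator_matrix <- function(gm, impute = c("mean", "zero"),
                                    center = TRUE) {
  stopifnot_gm(gm)
  impute <- match.arg(impute)
  blocks <- list()
  key <- data.frame(locus = character(0), allele = integer(0))
  for (j in seq_along(gm$locus_ids)) {
    t1 <- !is.na(gm$a1[, j])
    sizes <- sort(unique(c(gm$a1[t1, j], gm$a2[t1, j])))
    if (!length(sizes)) next
    X <- matrix(NA_real_, length(gm$accession_ids), length(sizes))
    X[t1, ] <- 0
    idx1 <- cbind(which(t1), match(gm$a1[t1, j], sizes))
    idx2 <- cbind(which(t1), match(gm$a2[t1, j], sizes))
    X[idx1] <- X[idx1] + 0.5
    X[idx2] <- X[idx2] + 0.5
    if (any(!t1)) {
      fill <- if (impute == "mean") colMeans(X, na.rm = TRUE) else 0
      X[!t1, ] <- rep(fill, each = sum(!t1))
    }
    blocks[[length(blocks) + 1L]] <- X
    key <- rbind(key, data.frame(locus = gm$locus_ids[j], allele = sizes))
  }
  M <- do.call(cbind, blocks)
  rownames(M) <- gm$accession_ids
  colnames(M) <- paste0(key$locus, ".", key$allele)
  ctr <- colMeans(M)
  if (center) M <- sweep(M, 2L, ctr)
  attr(M, "key") <- key
  attr(M, "col_center") <- ctr
  M
}

#' Principal components of an allele-indicator matrix
#'
#' Exact decomposition (SVD of the centered matrix, equivalent to an
#' eigen-decomposition of its covariance); reports per-axis and cumulative
#' variance percentages.
#'
#' @param M centered numeric matrix (from [allele_indicator_matrix()]).
#' @param n_components number of axes to return (default: all).
#' @return list with `scores` (n x n_components), `loadings`, `eigenvalues`
#'   (all axes), `variance_pct`, `cum_variance_pct`.
#' @export
pca_scores <- function(M, n_components = NULL) {
  maxc <- min(nrow(M) - 1L, ncol(M))
  if (is.null(n_components)) n_components <- maxc
  if (n_components > maxc)
    stop("n_components exceeds min(n-1, columns) = ", maxc)
  pc <- prcomp(M, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- seq_len(n_components)
  list(scores = pc$x[, keep, drop = FALSE],
       loadings = pc$rotation[, keep, drop = FALSE],
       eigenvalues = ev,
       variance_pct = 100 * ev / sum(ev),
       cum_variance_pct = cumsum(100 * ev / sum(ev)))
}

#' K-means / BIC scan for the number of clusters
#'
#' For each K in `1..Kmax` runs K-means with `n_starts` restarts and keeps
#' the best within-cluster sum of squares `W_K`; the Bayesian information
#' criterion is `BIC(K) = n log(W_K / n) + K log(n)` and the chosen K is its
#' argmin (ties break toward smaller K).
#'
#' @param scores numeric matrix of retained PC scores (rows = individuals).
#' @param Kmax maximum number of clusters (default 20; must be `< n`).
#' @param n_starts K-means restarts per K (default 10).
#' @param seed RNG seed.
#' @param iter_max K-means iteration cap.
#' @return list with `bic` (data.frame `K`, `W`, `BIC`), `best_K`, and
#'   `labels` (cluster labels at `best_K`).
#' @export
kmeans_bic_scan <- function(scores, Kmax = 20L, n_starts = 10L, seed,
                            iter_max = 50L) {
  if (missing(seed)) stop("seed is required")
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (Kmax >= n) stop("Kmax must be smaller than the number of individuals")
  set.seed(seed)
  W <- numeric(Kmax)
  labs <- vector("list", Kmax)
  totss <- sum(sweep(scores, 2L, colMeans(scores))^2)
  for (K in seq_len(Kmax)) {
    if (K == 1L) {
      W[1L] <- totss
      labs[[1L]] <- rep(1L, n)
      next
    }
    km <- suppressWarnings(
      kmeans(scores, centers = K, nstart = n_starts, iter.max = iter_max))
    W[K] <- km$tot.withinss
    labs[[K]] <- km$cluster
  }
  bic <- n * log(pmax(W, 1e-300) / n) + seq_len(Kmax) * log(n)
  best_K <- which(bic == min(bic))[1L]
  list(bic = data.frame(K = seq_len(Kmax), W = W, BIC = bic),
       best_K = best_K, labels = labs[[best_K]])
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Multiclass linear discriminant analysis on retained PC scores, maximizing
#' the between/within variance ratio. Returns discriminant coordinates,
#' per-individual posterior group memberships and the reassignment rate (the
#' fraction of individuals whose discriminant classification matches the
#' input label).
#'
#' @param scores PC score matrix (individuals x retained PCs).
#' @param labels group labels (K >= 2 groups).
#' @param n_da number of discriminant axes (default and maximum `K - 1`).
#' @return object of class `dapc_fit`: `discriminant_coords`
#'   (n x n_da), `posterior`, `assigned`, `reassignment_rate`, `lda`.
#' @export
dapc_fit <- function(scores, labels, n_da = NULL) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least 2 groups")
  if (ncol(scores) >= nrow(scores))
    stop("retain fewer PCs than individuals")
  if (is.null(n_da)) n_da <- K - 1L
  if (n_da > K - 1L) stop("n_da cannot exceed K - 1")
  fit <- tryCatch(
    MASS::lda(scores, grouping = labels),
    error = function(e) {
      # singular within-group scatter: ridge-regularize by jittering scale
      message("within-group scatter singular; adding ridge 1e-8")
      MASS::lda(scores + matrix(rnorm(length(scores), sd = 1e-8),
                                nrow(scores)), grouping = labels)
    })
  pred <- predict(fit, scores)
  nd <- min(n_da, ncol(pred$x))
  structure(list(discriminant_coords = pred$x[, seq_len(nd), drop = FALSE],
                 posterior = pred$posterior,
                 assigned = as.character(pred$class),
                 reassignment_rate = mean(pred$class == labels),
                 lda = fit),
            class = "dapc_fit")
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat(sprintf("dapc_fit: %d groups, %d discriminant axes, reassignment rate %.3f\n",
              ncol(x$posterior), ncol(x$discriminant_coords),
              x$reassignment_rate))
  invisible(x)
}

#' Full DAPC pipeline on a genotype matrix
#'
#' Allele-indicator transform, PCA retaining enough axes to reach
#' `variance_target` percent of the variance (or a fixed `n_pc`), K-means /
#' BIC scan for the cluster number, then discriminant analysis of the
#' K-means groups.
#'
#' @param gm a [genotype_matrix()].
#' @param Kmax maximum clusters for the BIC scan (default 20).
#' @param n_pc fixed number of retained PCs; if `NULL`, the smallest count
#'   reaching `variance_target`.
#' @param variance_target cumulative variance percentage to retain
#'   (default 94, mirroring the usual "keep most of the variance" practice).
#' @param n_starts,seed passed to [kmeans_bic_scan()].
#' @return object of class `dapc_result`: `bic_curve`, `best_K`,
#'   `retained_pcs`, `variance_explained`, `cluster_labels`,
#'   `discriminant_coords`, `reassignment_rate`, plus the underlying
#'   `pca` and `dapc` fits.
#' @export
dapc_analysis <- function(gm, Kmax = 20L, n_pc = NULL, variance_target = 94,
                          n_starts = 10L, seed) {
  if (missing(seed)) stop("seed is required")
  M <- allele_indicator_matrix(gm)
  pc <- pca_scores(M)
  if (is.null(n_pc))
    n_pc <- which(pc$cum_variance_pct >= variance_target)[1L]
  n_pc <- min(n_pc, ncol(pc$scores))
  scores <- pc$scores[, seq_len(n_pc), drop = FALSE]
  scan <- kmeans_bic_scan(scores, Kmax = Kmax, n_starts = n_starts,
                          seed = seed)
  if (scan$best_K >= 2L) {
    fit <- dapc_fit(scores, scan$labels)
    dc <- fit$discriminant_coords
    rr <- fit$reassignment_rate
  } else {
    fit <- NULL
    dc <- NULL
    rr <- NA_real_
  }
  structure(list(bic_curve = scan$bic, best_K = scan$best_K,
                 retained_pcs = n_pc,
                 variance_explained = pc$cum_variance_pct[n_pc],
                 cluster_labels = setNames(scan$labels, gm$accession_ids),
                 discriminant_coords = dc, reassignment_rate = rr,
                 pca = pc, dapc = fit),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("dapc_result: best K = %d (BIC), %d PCs retained (%.1f%% variance)\n",
              x$best_K, x$retained_pcs, x$variance_explained))
  invisible(x)
}
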