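#' ssrbank: microsatellite fingerprinting and diversity analysis
#'
#' Tools for SSR-based characterization of clonal germplasm collections:
#' diversity statistics, Bayesian admixture clustering, DAPC, Rogers'
#' distance / neighbor-joining trees, identity resolution and core-collection
#' selection, plus a synthetic-germplasm simulator for verification.
#'
#' @useDynLib ssrbank, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dist kmeans prcomp predict rbinom rgamma rmultinom rnorm
#'   runif sd setNames var
#' @importFrom utils combn read.csv write.csv write.table head
#' @keywords internal
"_PACKAGE"

#' Construct a genotype matrix of unordered diploid allele-size pairs
#'
#' The central container of the package: `n` accessions typed at `L`
#' co-dominant multi-allelic loci. Each call is an unordered pair of positive
#' integer allele lengths (base pairs); homozygotes are stored as a pair of
#' equal values, and calls are normalized so the smaller allele comes first.
#' Missing calls are `NA` in both allele slabs.
#'
#' @param accession_ids character vector of unique accession labels.
#' @param locus_ids character vector of unique locus labels.
#' @param a1,a2 integer matrices (`n x L`) of allele sizes; `NA` in both for a
#'   missing call. Pairs are reordered so `a1 <= a2`.
#' @param metadata optional data.frame of per-accession annotations
#'   (one row per accession).
#' @return An object of class `genotype_matrix` with elements
#'   `accession_ids`, `locus_ids`, `a1`, `a2`, `metadata`.
#' @export
genotype_matrix <- function(accession_ids, locus_ids, a1, a2, metadata = NULL) {
  accession_ids <- as.character(accession_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(accession_ids))
    stop("duplicate accession ID(s): ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ID(s): ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  n <- length(accession_ids)
  L <- length(locus_ids)
  if (length(a1) != n * L || length(a2) != n * L)
    stop("allele matrices must be n_accessions x n_loci")
  a1 <- matrix(as.integer(a1), nrow = n, ncol = L,
               dimnames = list(accession_ids, locus_ids))
  a2 <- matrix(as.integer(a2), nrow = n, ncol = L,
               dimnames = list(accession_ids, locus_ids))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-call (one allele missing) at accession '%s', locus '%s'",
                 accession_ids[w[1]], locus_ids[w[2]]))
  }
  bad <- !is.na(a1) & (a1 <= 0L | a2 <= 0L)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive allele size at accession '%s', locus '%s'",
                 accession_ids[w[1]], locus_ids[w[2]]))
  }
  # normalize unordered pairs: min allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != length(accession_ids))
      stop("metadata must have one row per accession")
    rownames(metadata) <- accession_ids
  }
  structure(list(accession_ids = accession_ids, locus_ids = locus_ids,
                 a1 = a1, a2 = a2, metadata = metadata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$a1))
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%d missing calls, %.1f%%)\n",
              length(x$accession_ids), length(x$locus_ids), n_missing,
              100 * n_missing / length(x$a1)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$accession_ids), length(x$locus_ids))

#' Subset a genotype matrix by accessions and/or loci
#'
#' @param x a `genotype_matrix`.
#' @param i accession selector (indices, logical, or IDs).
#' @param j locus selector (indices, logical, or IDs).
#' @param ... unused.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$accession_ids)
  if (missing(j)) j <- seq_along(x$locus_ids)
  if (is.character(i)) i <- match(i, x$accession_ids)
  if (is.character(j)) j <- match(j, x$locus_ids)
  if (anyNA(i)) stop("unknown accession ID in subset")
  if (anyNA(j)) stop("unknown locus ID in subset")
  genotype_matrix(x$accession_ids[i], x$locus_ids[j],
                  x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  metadata = if (!is.null(x$metadata)) x$metadata[i, , drop = FALSE])
}

#' @rdname genotype_matrix
#' @param x object to test.
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' @method all.equal genotype_matrix
#' @export
all.equal.genotype_matrix <- function(target, current, ...) {
  all.equal(unclass(target)[c("accession_ids", "locus_ids", "a1", "a2")],
            unclass(current)[c("accession_ids", "locus_ids", "a1", "a2")], ...)
}

# logical n x L matrix: TRUE where the call is typed
typed_mask <- function(gm) !is.na(gm$a1)

stopifnot_gm <- function(gm) {
  if (!is_genotype_matrix(gm)) stop("expected a genotype_matrix")
  invisible(gm)
}

locus_index <- function(gm, locus) {
  j <- if (is.character(locus)) match(locus, gm$locus_ids) else as.integer(locus)
  if (is.na(j) || j < 1L || j > length(gm$locus_ids))
    stop("unknown locus: ", locus)
  j
}
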