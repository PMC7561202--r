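#' Rogers' genetic distance between accessions
#'
#' Each individual is represented per locus as an allele-frequency vector
#' with entries 0, 1/2, 1; the per-locus distance is
#' \deqn{d_l = \sqrt{\tfrac12 \sum_a (x_a - y_a)^2}}
#' and the individual distance is the mean of `d_l` over loci typed in both
#' individuals (pairwise deletion), so distances stay in `[0, 1]`.
#'
#' @param gm a [genotype_matrix()].
#' @return a symmetric `dist`-convertible matrix (class `matrix`) with
#'   accession IDs as dimnames, zero diagonal, entries in `[0, 1]`.
#' @export
rogers_distance <- function(gm) {
  stopifnot_gm(gm)
  n <- length(gm$accession_ids)
  dsum <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (j in seq_along(gm$locus_ids)) {
    t1 <- !is.na(gm$a1[, j])
    if (sum(t1) < 2L) next
    sizes <- sort(unique(c(gm$a1[t1, j], gm$a2[t1, j])))
    X <- matrix(0, sum(t1), length(sizes))
    X[cbind(seq_len(sum(t1)), match(gm$a1[t1, j], sizes))] <-
      X[cbind(seq_len(sum(t1)), match(gm$a1[t1, j], sizes))] + 0.5
    X[cbind(seq_len(sum(t1)), match(gm$a2[t1, j], sizes))] <-
      X[cbind(seq_len(sum(t1)), match(gm$a2[t1, j], sizes))] + 0.5
    dl <- as.matrix(dist(X)) / sqrt(2)
    idx <- which(t1)
    dsum[idx, idx] <- dsum[idx, idx] + dl
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  off <- cnt == 0L & row(cnt) != col(cnt)
  if (any(off)) {
    w <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("accessions '%s' and '%s' share no typed locus",
                 gm$accession_ids[w[1L]], gm$accession_ids[w[2L]]))
  }
  d <- dsum / pmax(cnt, 1L)
  diag(d) <- 0
  dimnames(d) <- list(gm$accession_ids, gm$accession_ids)
  d
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard agglomeration on the Q-criterion (Saitou & Nei as reformulated by
#' Studier & Keppler). Ties in Q are broken by the lexicographically smallest
#' pair of subtree labels (a subtree is labeled by its smallest leaf), so the
#' result is reproducible. Negative estimated branch lengths are clamped to 0
#' with the deficit transferred to the sibling edge, preserving the pair's
#' summed length.
#'
#' @param dm symmetric distance matrix with labels as dimnames (e.g. from
#'   [rogers_distance()]), or a `dist` object.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  labels <- rownames(dm)
  n <- nrow(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 3L) stop("neighbor joining requires >= 3 labels")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  D <- dm
  # build with placeholder tip labels so arbitrary accession names (spaces,
  # parentheses, ...) never enter the Newick text; real labels are restored
  # on the phylo object afterwards
  nwk <- paste0("t", seq_len(n))
  rep_lab <- labels
  active <- seq_len(n)
  while (length(active) > 3L) {
    r <- length(active)
    Da <- D[active, active, drop = FALSE]
    R <- rowSums(Da)
    Q <- (r - 2) * Da - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_lab <- apply(cand, 1L, function(ij) {
      p <- sort(c(rep_lab[active[ij[1L]]], rep_lab[active[ij[2L]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(pair_lab)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- Da[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    cl <- clamp_pair(li, lj)
    ai <- active[i]; aj <- active[j]
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[ai], cl[1L], nwk[aj], cl[2L])
    # distances from the new node u to remaining nodes
    rest <- active[-c(i, j)]
    du <- (D[ai, rest] + D[aj, rest] - dij) / 2
    u <- ai  # reuse slot ai for the merged node
    D[u, rest] <- du
    D[rest, u] <- du
    nwk[u] <- new_nwk
    rep_lab[u] <- min(rep_lab[ai], rep_lab[aj])
    active <- sort(c(rest, u))
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[a], la, nwk[b], lb, nwk[c3], lc)
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- labels[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

clamp_pair <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- li + lj; lj <- 0 }
  c(max(li, 0), max(lj, 0))
}

quote_newick_label <- function(x) {
  if (grepl("[][ \t(),:;']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# each split is represented by the sorted side NOT containing the first
# label of `all_labels`, pasted with "|"
tree_splits <- function(tree, all_labels = sort(tree$tip.label)) {
  n <- length(tree$tip.label)
  anchor <- all_labels[1L]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- sort(setdiff(all_labels, side))
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples loci (columns) with replacement, recomputes the Rogers distance
#' and NJ tree for each replicate, and scores every internal edge of the main
#' tree by the percentage of replicates containing the same bipartition.
#' Supports are attached as internal node labels.
#'
#' @param gm a [genotype_matrix()] with at least 2 loci.
#' @param replicates bootstrap replicate count (default 1000; 0 returns the
#'   tree without supports).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `tree` (a `phylo`; `node.label` holds supports as
#'   percentages for internal edges, `NA` for the root) and `supports`
#'   (named numeric by bipartition key).
#' @export
bootstrap_supports <- function(gm, replicates = 1000L, seed) {
  stopifnot_gm(gm)
  if (length(gm$locus_ids) < 2L) stop("bootstrap requires >= 2 loci")
  if (missing(seed)) stop("seed is required")
  main <- neighbor_joining(rogers_distance(gm))
  if (replicates <= 0L)
    return(list(tree = main, supports = setNames(numeric(0), character(0))))
  set.seed(seed)
  L <- length(gm$locus_ids)
  all_labels <- sort(main$tip.label)
  main_splits <- tree_splits(main, all_labels)
  hits <- setNames(numeric(length(main_splits)), main_splits)
  for (b in seq_len(replicates)) {
    pick <- sample.int(L, L, replace = TRUE)
    gb <- genotype_matrix(gm$accession_ids,
                          paste0("L", seq_len(L)),
                          gm$a1[, pick, drop = FALSE],
                          gm$a2[, pick, drop = FALSE])
    tb <- try(neighbor_joining(rogers_distance(gb)), silent = TRUE)
    if (inherits(tb, "try-error")) next
    sb <- tree_splits(tb, all_labels)
    inb <- main_splits %in% sb
    hits[inb] <- hits[inb] + 1
  }
  supports <- 100 * hits / replicates
  # attach supports as node labels: match each internal node's split
  n <- length(main$tip.label)
  node_lab <- rep(NA_character_, main$Nnode)
  anchor <- all_labels[1L]
  for (nd in seq_len(main$Nnode)) {
    node_id <- n + nd
    tips <- tips_below(main, node_id)
    side <- sort(main$tip.label[tips])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- sort(setdiff(all_labels, side))
    key <- paste(side, collapse = "|")
    if (key %in% names(supports))
      node_lab[nd] <- formatC(supports[[key]], format = "fg")
  }
  main$node.label <- node_lab
  list(tree = main, supports = supports)
}

tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= n) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' Write a tree to Newick text
#'
#' Branch lengths are kept; internal node labels (bootstrap supports) are
#' emitted as standard Newick internal labels. Labels containing Newick
#' metacharacters (spaces, parentheses, commas, ...) are single-quoted, with
#' embedded quotes doubled, per the Newick standard; [read_newick()] undoes
#' the quoting.
#'
#' @param tree a `phylo`.
#' @param path optional output file.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  placeholders <- paste0("qlbl", seq_along(tree$tip.label), "x")
  quoted <- vapply(tree$tip.label, quote_newick_label, "")
  needs <- quoted != tree$tip.label
  out_tree <- tree
  out_tree$tip.label <- ifelse(needs, placeholders, tree$tip.label)
  txt <- ape::write.tree(out_tree)
  for (i in which(needs))
    txt <- sub(placeholders[i], quoted[i], txt, fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick string or file, honouring quoted labels
#'
#' Inverse of [write_newick()]: single-quoted labels (with doubled embedded
#' quotes) are restored verbatim.
#'
#' @param text a Newick string, or `NULL` when reading from `path`.
#' @param path optional file to read from.
#' @return a `phylo`.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  # extract quoted labels and substitute parse-safe placeholders
  m <- gregexpr("'(?:[^']|'')*'", text)[[1L]]
  restored <- character(0)
  if (m[1L] != -1L) {
    pieces <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1L]]
    restored <- gsub("''", "'", substr(pieces, 2L, nchar(pieces) - 1L))
    for (i in seq_along(pieces))
      text <- sub(pieces[i], paste0("qlbl", i, "x"), text, fixed = TRUE)
  }
  tree <- ape::read.tree(text = text)
  if (length(restored)) {
    hit <- grepl("^qlbl[0-9]+x$", tree$tip.label)
    idx <- as.integer(sub("^qlbl([0-9]+)x$", "\\1", tree$tip.label[hit]))
    tree$tip.label[hit] <- restored[idx]
  }
  tree
}
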