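#' The 7-locus fingerprint set used for variety identification
#'
#' The locus subset adopted by the international grapevine reference
#' databases for cultivar identification and profile exchange.
#' @export
IDENTIFICATION_LOCI <- c("VVS2", "VVMD5", "VVMD7", "VVMD25", "VVMD27",
                         "VrZAG62", "VrZAG79")

#' Normalize an accession/variety name for comparison
#'
#' Case-folds, strips accents and punctuation, collapses whitespace. Distinct
#' words are never merged ("Pedro Ximenez" and "Pedro Gimenez" stay distinct).
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  y <- iconv(enc2utf8(x), from = "UTF-8", to = "ASCII//TRANSLIT")
  bad <- is.na(y)
  # transliteration unavailable in this locale: drop non-ASCII bytes instead
  y[bad] <- iconv(enc2utf8(x[bad]), from = "UTF-8", to = "ASCII", sub = "")
  # accents transliterate to quote marks (e.g. a-acute -> 'a'); drop those
  # outright so "Niagara" and its accented spelling compare equal, then map
  # remaining punctuation to spaces
  x <- gsub("['`\"^~]+", "", y)
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Canonical profile key over a locus subset
#'
#' Deterministic serialization of an accession's calls over a locus subset:
#' locus-sorted, allele-sorted, missing loci recorded explicitly as `"?"`.
#' Two accessions share a key iff their profiles are identical at every
#' compared locus (missing-vs-typed breaks identity).
#'
#' @param gm a [genotype_matrix()].
#' @param accession accession ID or index.
#' @param loci locus subset (default: all loci).
#' @return a single character key.
#' @export
profile_key <- function(gm, accession, loci = gm$locus_ids) {
  stopifnot_gm(gm)
  i <- if (is.character(accession)) match(accession, gm$accession_ids) else accession
  if (is.na(i)) stop("unknown accession: ", accession)
  loci <- sort(loci)
  j <- match(loci, gm$locus_ids)
  if (anyNA(j)) stop("unknown locus in subset")
  cells <- ifelse(is.na(gm$a1[i, j]), "?",
                  paste0(gm$a1[i, j], "/", gm$a2[i, j]))
  paste(paste0(loci, "=", cells), collapse = ";")
}

#' Group accessions with identical multilocus profiles
#'
#' Accessions are grouped by exact profile identity over the compared loci.
#' Within a profile group, accessions sharing the same normalized name form a
#' duplicate set; a group spanning more than one distinct name is a synonym
#' group.
#'
#' In `"strict"` mode (default) a missing call at any compared locus
#' excludes the accession (with a warning) and grouping is by exact key
#' equality — an equivalence relation by construction. In `"lenient"` mode
#' accessions typed at `min_loci` or more are kept and two accessions match
#' when they agree at every locus typed in both (at least `min_loci` shared);
#' because such agreement is not transitive, lenient groups are connected
#' components of the match graph and can chain profiles that differ at
#' mutually missing loci.
#'
#' @param gm a [genotype_matrix()].
#' @param loci locus subset used for comparison (default: all loci).
#' @param names declared names; defaults to the accession IDs.
#' @param mode `"strict"` (exact keys over all compared loci) or
#'   `"lenient"` (shared-typed-loci comparison).
#' @param min_loci minimum typed loci required to compare an accession
#'   (defaults: all loci in strict mode, 6 in lenient mode).
#' @return list with `duplicate_groups` (list of accession-ID vectors sharing
#'   name and profile), `synonym_groups` (profile groups spanning >= 2
#'   distinct names), `n_unique_genotypes` (distinct profiles among
#'   compared accessions), `excluded` (accessions with too much missing
#'   data), and `key_by_accession` (strict mode only).
#' @export
find_duplicates_and_synonyms <- function(gm, loci = gm$locus_ids,
                                         names = NULL,
                                         mode = c("strict", "lenient"),
                                         min_loci = NULL) {
  stopifnot_gm(gm)
  mode <- match.arg(mode)
  if (is.null(min_loci))
    min_loci <- if (mode == "strict") length(loci) else min(6L, length(loci))
  if (is.null(names)) names <- setNames(gm$accession_ids, gm$accession_ids)
  j <- match(loci, gm$locus_ids)
  if (anyNA(j)) stop("unknown locus in subset")
  typed <- rowSums(!is.na(gm$a1[, j, drop = FALSE]))
  ok <- typed >= min_loci
  excluded <- gm$accession_ids[!ok]
  if (length(excluded))
    warning(length(excluded), " accession(s) typed at fewer than ", min_loci,
            " of the compared loci were excluded: ",
            paste(head(excluded, 5L), collapse = ", "),
            if (length(excluded) > 5L) ", ..." else "")
  accs <- gm$accession_ids[ok]
  if (mode == "strict") {
    keys <- vapply(accs, function(a) profile_key(gm, a, loci), "")
    groups <- split(accs, keys)
  } else {
    keys <- setNames(rep(NA_character_, length(accs)), accs)
    groups <- lenient_groups(gm, accs, j, min_loci)
  }
  dup_groups <- list()
  syn_groups <- list()
  for (grp in groups) {
    if (length(grp) < 2L) next
    nn <- normalize_name(names[grp])
    by_name <- split(grp, nn)
    for (dset in by_name) if (length(dset) >= 2L)
      dup_groups[[length(dup_groups) + 1L]] <- unname(dset)
    if (length(unique(nn)) >= 2L)
      syn_groups[[length(syn_groups) + 1L]] <- unname(grp)
  }
  # deterministic ordering
  ord <- function(gl) gl[order(vapply(gl, `[[`, "", 1L))]
  list(duplicate_groups = ord(dup_groups),
       synonym_groups = ord(syn_groups),
       n_unique_genotypes = length(groups),
       excluded = excluded,
       key_by_accession = keys)
}

# connected components of the "identical at all shared typed loci (>= min
# shared)" graph, via union-find
lenient_groups <- function(gm, accs, j, min_shared) {
  idx <- match(accs, gm$accession_ids)
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(max(n - 1L, 0L))) {
    for (b in seq(a + 1L, n)) {
      ta <- !is.na(gm$a1[idx[a], j]); tb <- !is.na(gm$a1[idx[b], j])
      shared <- which(ta & tb)
      if (length(shared) < min_shared) next
      js <- j[shared]
      if (all(gm$a1[idx[a], js] == gm$a1[idx[b], js]) &&
          all(gm$a2[idx[a], js] == gm$a2[idx[b], js])) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(accs, roots))
}

#' Match accession profiles against a reference fingerprint panel
#'
#' Trueness-to-type validation: each accession's profile over the panel's
#' locus subset is compared with every panel entry by exact equality.
#' An exact match to an entry whose prime name equals the declared name
#' (after normalization) validates the accession; a match to a different
#' prime name flags misnaming; no match with the declared name present in
#' the panel flags the accession "unknown"; otherwise it is unreported.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `reference_panel` (its loci must all be in `gm`).
#' @param declared_names named character vector accession -> declared name;
#'   defaults to the accession IDs.
#' @param min_loci minimum typed loci to attempt a match (default: all panel
#'   loci — strict mode; accessions below it are excluded with a warning).
#' @return list with `validated` (data.frame accession/prime_name),
#'   `misnamed` (accession/declared/matched prime_name), `unreported`
#'   (accessions matching no entry, declared name absent from panel),
#'   `unknown` (declared name in panel but profile matches nothing), and
#'   `excluded`.
#' @export
match_to_references <- function(gm, panel, declared_names = NULL,
                                min_loci = length(panel$loci)) {
  stopifnot_gm(gm)
  if (is.null(declared_names))
    declared_names <- setNames(gm$accession_ids, gm$accession_ids)
  if (!all(panel$loci %in% gm$locus_ids))
    stop("panel loci missing from genotype matrix: ",
         paste(setdiff(panel$loci, gm$locus_ids), collapse = ", "))
  panel_keys <- vapply(seq_along(panel$prime_names), function(k) {
    pr <- panel$profiles[[k]]
    loci <- sort(panel$loci)
    paste(paste0(loci, "=", vapply(pr[loci], function(p)
      paste0(p[1L], "/", p[2L]), "")), collapse = ";")
  }, "")
  panel_norm <- normalize_name(panel$prime_names)
  j <- match(panel$loci, gm$locus_ids)
  typed <- rowSums(!is.na(gm$a1[, j, drop = FALSE]))
  ok <- typed >= min_loci
  excluded <- gm$accession_ids[!ok]
  if (length(excluded))
    warning(length(excluded),
            " accession(s) with missing calls among the panel loci were excluded")
  validated <- data.frame(accession = character(0), prime_name = character(0))
  misnamed <- data.frame(accession = character(0), declared = character(0),
                         prime_name = character(0))
  unreported <- character(0)
  unknown <- character(0)
  for (acc in gm$accession_ids[ok]) {
    key <- profile_key(gm, acc, panel$loci)
    hits <- which(panel_keys == key)
    declared <- declared_names[[acc]]
    if (length(hits)) {
      prime_hits <- unique(panel$prime_names[hits])
      if (length(unique(panel_norm[hits])) > 1L)
        stop("panel inconsistency: profile of '", acc,
             "' matches entries with different prime names: ",
             paste(prime_hits, collapse = ", "))
      prime <- prime_hits[1L]
      if (normalize_name(declared) == panel_norm[hits[1L]]) {
        validated <- rbind(validated,
                           data.frame(accession = acc, prime_name = prime))
      } else {
        misnamed <- rbind(misnamed,
                          data.frame(accession = acc, declared = declared,
                                     prime_name = prime))
      }
    } else if (normalize_name(declared) %in% panel_norm) {
      unknown <- c(unknown, acc)
    } else {
      unreported <- c(unreported, acc)
    }
  }
  list(validated = validated, misnamed = misnamed, unreported = unreported,
       unknown = unknown, excluded = excluded)
}

#' Full identity report
#'
#' Combines internal profile grouping (duplicates/synonyms over
#' `grouping_loci`) with reference-panel matching (over the panel's loci,
#' when a panel is supplied). The matching categories
#' validated/misnamed/unknown/unreported (plus excluded) partition the
#' accession set; duplicate and synonym groups are an overlay on that
#' partition, since a synonym-group member can itself be validated or
#' misnamed.
#'
#' @param gm a [genotype_matrix()].
#' @param panel optional `reference_panel`.
#' @param declared_names accession -> declared name (defaults to IDs).
#' @param grouping_loci loci used for duplicate/synonym grouping (default:
#'   all loci).
#' @return object of class `identity_report`.
#' @export
identity_report <- function(gm, panel = NULL, declared_names = NULL,
                            grouping_loci = gm$locus_ids) {
  grp <- find_duplicates_and_synonyms(gm, loci = grouping_loci,
                                      names = declared_names)
  ref <- if (!is.null(panel))
    match_to_references(gm, panel, declared_names = declared_names)
  structure(c(grp, list(reference = ref)), class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("identity_report: %d unique genotypes, %d duplicate group(s), %d synonym group(s)\n",
              x$n_unique_genotypes, length(x$duplicate_groups),
              length(x$synonym_groups)))
  if (!is.null(x$reference))
    cat(sprintf("  reference matching: %d validated, %d misnamed, %d unknown, %d unreported\n",
                nrow(x$reference$validated), nrow(x$reference$misnamed),
                length(x$reference$unknown), length(x$reference$unreported)))
  invisible(x)
}
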