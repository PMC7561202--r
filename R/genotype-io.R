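#' Read a genotype table from delimited text
#'
#' Two dialects are supported. `"pairs_csv"` (canonical): first column is the
#' accession ID, each remaining column one locus, cells `"a/b"` with missing
#' calls written `"."` (empty cells also count as missing). `"two_column_csv"`:
#' two adjacent columns per locus holding the two allele sizes, missing coded
#' `0` or blank; locus IDs are taken from the first column of each pair
#' (a trailing suffix such as `"_1"`/`"_2"` or `".1"` is stripped).
#'
#' @param path file path (or connection) to delimited text.
#' @param dialect `"pairs_csv"` or `"two_column_csv"`.
#' @param sep field separator, default `","` (use `"\t"` for TSV).
#' @param metadata_cols character vector of column names to treat as
#'   per-accession metadata rather than loci (pairs_csv only).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("pairs_csv", "two_column_csv"),
                                sep = ",", metadata_cols = NULL) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, sep = sep, check.names = FALSE, colClasses = "character",
                 strip.white = TRUE)
  if (ncol(df) < 2L) stop("genotype table needs an ID column plus loci")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate accession ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  meta <- NULL
  if (!is.null(metadata_cols)) {
    keep <- intersect(metadata_cols, names(body))
    if (length(keep)) {
      meta <- body[, keep, drop = FALSE]
      body <- body[, setdiff(names(body), keep), drop = FALSE]
    }
  }
  if (dialect == "pairs_csv") {
    loci <- names(body)
    n <- length(ids); L <- length(loci)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (j in seq_len(L)) {
      cell <- trimws(body[[j]])
      miss <- cell %in% c(".", "", "NA")
      parts <- strsplit(cell[!miss], "/", fixed = TRUE)
      nn <- lengths(parts)
      if (any(nn != 2L)) {
        bad <- which(!miss)[which(nn != 2L)[1L]]
        stop(sprintf("cell '%s' at row '%s', locus '%s' is not an 'a/b' pair",
                     cell[bad], ids[bad], loci[j]))
      }
      v1 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
      v2 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
      if (anyNA(v1) || anyNA(v2)) {
        bad <- which(!miss)[which(is.na(v1) | is.na(v2))[1L]]
        stop(sprintf("non-integer allele token in cell '%s' at row '%s', locus '%s'",
                     cell[bad], ids[bad], loci[j]))
      }
      a1[!miss, j] <- v1
      a2[!miss, j] <- v2
    }
  } else {
    if (ncol(body) %% 2L != 0L)
      stop("two_column_csv requires an even number of allele columns")
    L <- ncol(body) %/% 2L
    loci <- sub("([._ -]?[12])$", "", names(body)[2L * seq_len(L) - 1L])
    n <- length(ids)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (j in seq_len(L)) {
      c1 <- trimws(body[[2L * j - 1L]]); c2 <- trimws(body[[2L * j]])
      m1 <- c1 %in% c("", "0", ".", "NA"); m2 <- c2 %in% c("", "0", ".", "NA")
      if (any(m1 != m2)) {
        bad <- which(m1 != m2)[1L]
        stop(sprintf("half-call at row '%s', locus '%s'", ids[bad], loci[j]))
      }
      v1 <- suppressWarnings(as.integer(c1[!m1]))
      v2 <- suppressWarnings(as.integer(c2[!m1]))
      if (anyNA(v1) || anyNA(v2)) {
        bad <- which(!m1)[which(is.na(v1) | is.na(v2))[1L]]
        stop(sprintf("non-integer allele token at row '%s', locus '%s'",
                     ids[bad], loci[j]))
      }
      a1[!m1, j] <- v1
      a2[!m1, j] <- v2
    }
  }
  genotype_matrix(ids, loci, a1, a2, metadata = meta)
}

#' Write a genotype matrix in the canonical pairs_csv dialect
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path, sep = ",") {
  stopifnot_gm(gm)
  cells <- matrix(".", nrow(gm$a1), ncol(gm$a1))
  t1 <- !is.na(gm$a1)
  cells[t1] <- paste0(gm$a1[t1], "/", gm$a2[t1])
  df <- data.frame(accession = gm$accession_ids, cells, check.names = FALSE)
  names(df) <- c("accession", gm$locus_ids)
  write.csv2_sep(df, path, sep)
  invisible(path)
}

write.csv2_sep <- function(df, path, sep) {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Encode a genotype matrix as STRUCTURE-format text
#'
#' Emits two rows per accession (one per allele copy). Allele sizes are
#' recoded to consecutive integers per locus; missing calls are coded `-9`.
#' The per-locus recoding table is returned so the encoding is invertible
#' (see [decode_structure_input()]).
#'
#' @param gm a [genotype_matrix()].
#' @param path optional file to write the text to; a JSON copy of the
#'   recoding table is then written alongside it (`<path>.recoding.json`).
#' @return list with `text` (character vector of lines) and `recoding`
#'   (named list per locus: integer code -> allele size).
#' @export
write_structure_input <- function(gm, path = NULL) {
  stopifnot_gm(gm)
  L <- length(gm$locus_ids)
  recoding <- vector("list", L)
  names(recoding) <- gm$locus_ids
  c1 <- c2 <- matrix(-9L, nrow(gm$a1), L)
  for (j in seq_len(L)) {
    sizes <- sort(unique(c(gm$a1[, j], gm$a2[, j])))
    sizes <- sizes[!is.na(sizes)]
    recoding[[j]] <- sizes  # code k (1-based) -> sizes[k]
    t1 <- !is.na(gm$a1[, j])
    c1[t1, j] <- match(gm$a1[t1, j], sizes)
    c2[t1, j] <- match(gm$a2[t1, j], sizes)
  }
  header <- paste(gm$locus_ids, collapse = "\t")
  lines <- character(2L * nrow(gm$a1))
  for (i in seq_len(nrow(gm$a1))) {
    lines[2L * i - 1L] <- paste(c(gm$accession_ids[i], c1[i, ]), collapse = "\t")
    lines[2L * i] <- paste(c(gm$accession_ids[i], c2[i, ]), collapse = "\t")
  }
  text <- c(header, lines)
  if (!is.null(path)) {
    writeLines(text, path)
    jsonlite::write_json(recoding, paste0(path, ".recoding.json"),
                         digits = NA)
  }
  list(text = text, recoding = recoding)
}

#' Decode STRUCTURE-format text back to a genotype matrix
#'
#' @param text character vector of lines as produced by
#'   [write_structure_input()].
#' @param recoding the recoding table returned by [write_structure_input()].
#' @return a [genotype_matrix()].
#' @export
decode_structure_input <- function(text, recoding) {
  loci <- strsplit(text[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(text[-1L], "\t", fixed = TRUE)
  if (length(body) %% 2L != 0L) stop("odd number of data rows")
  n <- length(body) %/% 2L
  ids <- vapply(body[2L * seq_len(n) - 1L], `[[`, "", 1L)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    r1 <- as.integer(body[[2L * i - 1L]][-1L])
    r2 <- as.integer(body[[2L * i]][-1L])
    for (j in seq_along(loci)) {
      if (r1[j] != -9L) {
        a1[i, j] <- recoding[[loci[j]]][r1[j]]
        a2[i, j] <- recoding[[loci[j]]][r2[j]]
      }
    }
  }
  genotype_matrix(ids, loci, a1, a2)
}

#' Read a reference fingerprint panel
#'
#' A reference panel holds published multi-locus profiles of prime-named
#' varieties (canonically the 7-locus grapevine identification set). Format:
#' CSV with columns `prime_name`, `source`, then one column per locus with
#' `"a/b"` cells (no missing calls allowed).
#'
#' @param path CSV file path.
#' @param sep field separator.
#' @return object of class `reference_panel`: list with `prime_names`,
#'   `sources`, `loci`, and `profiles` (a genotype_matrix keyed by row index).
#' @export
read_reference_panel <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE, colClasses = "character",
                 strip.white = TRUE)
  need <- c("prime_name", "source")
  if (!all(need %in% names(df)))
    stop("reference panel needs 'prime_name' and 'source' columns")
  loci <- setdiff(names(df), need)
  if (!length(loci)) stop("reference panel has no locus columns")
  if (any(!nzchar(df$prime_name))) stop("empty prime_name in reference panel")
  reference_panel(df$prime_name, loci,
                  profiles_from_cells(df[, loci, drop = FALSE]),
                  sources = df$source)
}

profiles_from_cells <- function(cells) {
  lapply(seq_len(nrow(cells)), function(i) {
    pr <- lapply(as.character(unlist(cells[i, ])), function(s) {
      p <- sort(as.integer(strsplit(s, "/", fixed = TRUE)[[1L]]))
      if (length(p) != 2L || anyNA(p)) stop("bad panel cell: ", s)
      p
    })
    names(pr) <- names(cells)
    pr
  })
}

#' Construct a reference panel in code
#'
#' @param prime_names character vector of variety prime names.
#' @param loci declared locus subset covered by every entry.
#' @param profiles list (one per entry) of named lists locus -> integer
#'   allele pair.
#' @param sources character vector of provenance strings.
#' @return a `reference_panel` object.
#' @export
reference_panel <- function(prime_names, loci, profiles,
                            sources = rep("local", length(prime_names))) {
  if (any(!nzchar(prime_names))) stop("prime_name must be non-empty")
  profiles <- lapply(profiles, function(pr) {
    if (!setequal(names(pr), loci))
      stop("every panel entry must cover exactly the declared locus subset")
    lapply(pr[loci], function(p) sort(as.integer(p)))
  })
  structure(list(prime_names = as.character(prime_names), loci = loci,
                 profiles = profiles, sources = sources),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d entries over %d loci (%s)\n",
              length(x$prime_names), length(x$loci),
              paste(x$loci, collapse = ", ")))
  invisible(x)
}

#' Standardize allele sizes against a reference panel
#'
#' Fragment-size calls from different instruments/ladders can be shifted by a
#' small systematic per-locus offset. Given anchor accessions of known
#' (trusted) identity, the per-locus offset is estimated as the mode of
#' (reference allele - observed allele) over all anchor accessions and both
#' alleles, and added to every call at that locus. The mode (not the mean) is
#' used so a single mistyped anchor cannot corrupt the offset.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `reference_panel` whose loci are all present in `gm`.
#' @param anchors named character vector: accession ID -> prime name.
#' @param min_consistency minimum fraction of anchor alleles that must agree
#'   with the modal offset at a locus (default 0.8); below it, an error lists
#'   the discordant anchors.
#' @return list with `gm` (shifted matrix), `offsets` (named integer per
#'   locus), and `consistency` (fraction of anchor alleles matching the mode).
#' @export
standardize_alleles <- function(gm, panel, anchors, min_consistency = 0.8) {
  stopifnot_gm(gm)
  if (!all(names(anchors) %in% gm$accession_ids))
    stop("anchor accession(s) not in genotype matrix: ",
         paste(setdiff(names(anchors), gm$accession_ids), collapse = ", "))
  if (!all(anchors %in% panel$prime_names))
    stop("anchor prime name(s) not in panel: ",
         paste(setdiff(anchors, panel$prime_names), collapse = ", "))
  if (!all(panel$loci %in% gm$locus_ids))
    stop("panel loci missing from genotype matrix")
  offsets <- setNames(integer(length(panel$loci)), panel$loci)
  consistency <- setNames(rep(NA_real_, length(panel$loci)), panel$loci)
  for (loc in panel$loci) {
    j <- locus_index(gm, loc)
    diffs <- integer(0)
    who <- character(0)
    for (acc in names(anchors)) {
      i <- match(acc, gm$accession_ids)
      if (is.na(gm$a1[i, j])) next
      ref <- panel$profiles[[match(anchors[[acc]], panel$prime_names)]][[loc]]
      obs <- c(gm$a1[i, j], gm$a2[i, j])
      diffs <- c(diffs, ref - obs)
      who <- c(who, acc, acc)
    }
    if (!length(diffs)) {
      warning("no anchors typed at locus ", loc, "; offset 0 assumed")
      offsets[loc] <- 0L
      next
    }
    tab <- table(diffs)
    mode_off <- as.integer(names(tab)[which.max(tab)])
    frac <- max(tab) / length(diffs)
    consistency[loc] <- frac
    if (frac < min_consistency)
      stop(sprintf(
        "locus %s: only %.0f%% of anchor alleles agree with modal offset %+d; discordant anchors: %s",
        loc, 100 * frac, mode_off,
        paste(unique(who[diffs != mode_off]), collapse = ", ")))
    offsets[loc] <- mode_off
    if (mode_off != 0L) {
      t1 <- !is.na(gm$a1[, j])
      gm$a1[t1, j] <- gm$a1[t1, j] + mode_off
      gm$a2[t1, j] <- gm$a2[t1, j] + mode_off
    }
  }
  list(gm = gm, offsets = offsets, consistency = consistency)
}
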