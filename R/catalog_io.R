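#' Construct a peptide catalog
#'
#' A peptide catalog is an ordered collection of uniquely identified
#' amino-acid sequences with optional provenance labels. It is the container
#' for candidate peptide pools and for reference ACP/AMP sets.
#'
#' @param ids character vector of unique record ids.
#' @param sequences character vector of amino-acid sequences (uppercased on
#'   construction; must be non-empty).
#' @param source_db optional character vector: originating set or database
#'   label per record.
#' @param species optional character vector: taxon label per record.
#' @param name catalog name.
#' @return an object of class `peptide_catalog`.
#' @examples
#' cat1 <- peptide_catalog(c("p1", "p2"), c("MKTAYI", "GIGKFLHSAK"))
#' length(cat1)
#' @export
peptide_catalog <- function(ids, sequences, source_db = NA_character_,
                            species = NA_character_, name = "catalog") {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop("`ids` and `sequences` must have equal length")
  }
  if (anyNA(ids) || any(!nzchar(ids))) stop("record ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(sequences))) stop("sequences must be non-empty")
  records <- data.frame(
    id = ids,
    sequence = sequences,
    source_db = rep_len(as.character(source_db), length(ids)),
    species = rep_len(as.character(species), length(ids)),
    stringsAsFactors = FALSE
  )
  structure(list(name = as.character(name), records = records),
            class = "peptide_catalog")
}

#' @export
length.peptide_catalog <- function(x) nrow(x$records)

#' @export
print.peptide_catalog <- function(x, ...) {
  cat(sprintf("peptide_catalog '%s': %d record(s)\n", x$name, length(x)))
  if (length(x) > 0) {
    show <- utils::head(x$records, 5)
    cat(sprintf("  %s  (%d aa)\n", show$id, nchar(show$sequence)), sep = "")
    if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5L))
  }
  invisible(x)
}

#' @export
as.data.frame.peptide_catalog <- function(x, ...) x$records

#' Sequences of a peptide catalog
#'
#' @param catalog a `peptide_catalog`.
#' @return named character vector of sequences (names are record ids).
#' @export
catalog_sequences <- function(catalog) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  stats::setNames(catalog$records$sequence, catalog$records$id)
}

#' Read a peptide catalog from FASTA
#'
#' Record ids are taken from the header up to the first whitespace; the
#' remainder of the header, if any, is stored as `source_db`. Sequences are
#' uppercased. Duplicate ids are an error.
#'
#' @param path path to a FASTA file.
#' @param name catalog name (defaults to the file name).
#' @return a `peptide_catalog`.
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(lines[first], ">")) {
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header",
                 first, path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  peptide_catalog(ids, seqs, source_db = desc,
                  name = if (is.null(name)) basename(path) else name)
}

#' Write a peptide catalog to FASTA
#'
#' Sequences are wrapped at 60 columns. Headers are the record ids.
#'
#' @param catalog a `peptide_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  set <- Biostrings::AAStringSet(catalog_sequences(catalog))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Retain only peptides made of the 20 canonical amino acids
#'
#' Sequences containing any non-canonical letter (including B, J, O, U, X, Z)
#' are removed, mirroring the exclusion of peptides with non-natural residues
#' from curated ACP sets. The ids of removed records are attached as
#' attribute `"removed_ids"`.
#'
#' @param catalog a `peptide_catalog`.
#' @return the filtered `peptide_catalog` (possibly empty), with attribute
#'   `removed_ids`.
#' @export
filter_natural_aa <- function(catalog) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
              catalog$records$sequence)
  removed <- catalog$records$id[!ok]
  out <- catalog
  out$records <- catalog$records[ok, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "removed_ids") <- removed
  out
}

#' Deduplicated union of peptide catalogs
#'
#' Merges two catalogs keeping one record per distinct sequence. Duplicates
#' are defined by exact full-sequence string equality; the first-seen record
#' (catalog a before catalog b, each in input order) is kept, so the result
#' order is deterministic. With `catalog_b = NULL` this deduplicates a single
#' catalog.
#'
#' @param catalog_a,catalog_b `peptide_catalog` objects (`catalog_b` optional).
#' @param name name of the resulting catalog.
#' @return a `peptide_catalog` with no duplicated sequences.
#' @export
deduplicate_union <- function(catalog_a, catalog_b = NULL, name = "union") {
  stopifnot(inherits(catalog_a, "peptide_catalog"))
  records <- catalog_a$records
  if (!is.null(catalog_b)) {
    stopifnot(inherits(catalog_b, "peptide_catalog"))
    records <- rbind(catalog_a$records, catalog_b$records)
  }
  keep <- !duplicated(records$sequence)
  records <- records[keep, , drop = FALSE]
  # id collisions across catalogs for distinct sequences: disambiguate
  if (anyDuplicated(records$id)) {
    records$id <- make.unique(records$id, sep = "_dup")
  }
  rownames(records) <- NULL
  out <- structure(list(name = name, records = records),
                   class = "peptide_catalog")
  out
}

#' Sequence overlap between two peptide catalogs
#'
#' Computes the exact-sequence intersection between the deduplicated first
#' catalog and the second catalog. The reported percentage uses the
#' deduplicated size of `catalog_a` as denominator: `catalog_a` is
#' conventionally the merged (union) reference set whose fraction with a
#' property -- e.g. ACPs that are also antimicrobial -- is of interest.
#'
#' @param catalog_a a `peptide_catalog`; denominator set (deduplicated).
#' @param catalog_b a `peptide_catalog`; the property set.
#' @return an object of class `overlap_stats`: list with `n_a`, `n_b`
#'   (unique sequence counts), `n_union_unique` (deduplicated size of
#'   `catalog_a`), `n_overlap`, and `overlap_pct` (one decimal).
#' @examples
#' a <- peptide_catalog(paste0("a", 1:3), c("MK", "MR", "ME"))
#' b <- peptide_catalog(paste0("b", 1:2), c("MK", "WW"))
#' overlap_stats(a, b)$overlap_pct  # 33.3
#' @export
overlap_stats <- function(catalog_a, catalog_b) {
  stopifnot(inherits(catalog_a, "peptide_catalog"),
            inherits(catalog_b, "peptide_catalog"))
  ua <- unique(catalog_a$records$sequence)
  ub <- unique(catalog_b$records$sequence)
  if (length(ua) == 0) stop("empty union: overlap percentage undefined")
  n_overlap <- length(intersect(ua, ub))
  structure(list(
    n_a = length(ua),
    n_b = length(ub),
    n_union_unique = length(ua),
    n_overlap = n_overlap,
    overlap_pct = round(100 * n_overlap / length(ua), 1)
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: %d of %d unique sequences (%.1f%%)\n",
              x$n_overlap, x$n_union_unique, x$overlap_pct))
  invisible(x)
}

#' Recall rate as a percentage
#'
#' Fraction of a peptide pool recovered by a prediction step, reported to two
#' decimals.
#'
#' @param recalled number of pool members recovered (`0 <= recalled <= pool`).
#' @param pool pool size (`> 0`).
#' @return percentage, rounded to 2 decimals.
#' @examples
#' recall_rate(1033, 1279)  # 80.77
#' @export
recall_rate <- function(recalled, pool) {
  stopifnot(length(recalled) == 1L, length(pool) == 1L)
  if (pool <= 0) stop("`pool` must be positive")
  if (recalled < 0 || recalled > pool) {
    stop("`recalled` must lie in [0, pool]")
  }
  round(100 * recalled / pool, 2)
}

#' Summarize a cell-line inhibition screen
#'
#' Given a peptides-by-cell-lines table of percent survival (relative to a
#' vehicle control), counts peptides whose growth inhibition
#' (100 - survival) reaches the threshold in at least one cell line.
#'
#' @param survival_pct_table numeric matrix or data frame, peptides as rows
#'   (rownames = peptide ids), cell lines as columns; values in \[0, 100\].
#' @param inhibition_threshold_pct inhibition threshold in percent,
#'   in (0, 100); default 20.
#' @return an object of class `screen_summary`: `n_peptides`, `n_active`,
#'   `active_pct` (one decimal), and `per_peptide_hits` (named integer count
#'   of cell lines at or above threshold per peptide).
#' @export
summarize_screen <- function(survival_pct_table, inhibition_threshold_pct = 20) {
  m <- as.matrix(survival_pct_table)
  if (length(m) == 0 || nrow(m) == 0) stop("empty screen table")
  if (!is.numeric(m)) stop("screen table must be numeric")
  if (anyNA(m) || any(m < 0) || any(m > 100)) {
    stop("survival values must lie in [0, 100]")
  }
  thr <- inhibition_threshold_pct
  if (thr <= 0 || thr >= 100) stop("threshold must lie in (0, 100)")
  inhibition <- 100 - m
  hits <- as.integer(rowSums(inhibition >= thr))
  names(hits) <- if (is.null(rownames(m))) {
    paste0("peptide_", seq_len(nrow(m)))
  } else rownames(m)
  n_active <- sum(hits >= 1L)
  structure(list(
    n_peptides = nrow(m),
    n_active = n_active,
    active_pct = round(100 * n_active / nrow(m), 1),
    per_peptide_hits = hits
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen: %d of %d peptides active in >=1 cell line (%.1f%%)\n",
              x$n_active, x$n_peptides, x$active_pct))
  invisible(x)
}

#' Write overlap statistics as TSV
#' @param x an `overlap_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(x, path) {
  stopifnot(inherits(x, "overlap_stats"))
  df <- data.frame(n_a = x$n_a, n_b = x$n_b,
                   n_union_unique = x$n_union_unique,
                   n_overlap = x$n_overlap, overlap_pct = x$overlap_pct)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a screen summary as TSV
#' @param x a `screen_summary` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  stopifnot(inherits(x, "screen_summary"))
  df <- data.frame(peptide_id = names(x$per_peptide_hits),
                   n_cell_lines_inhibited = unname(x$per_peptide_hits),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_peptides=%d\tn_active=%d\tactive_pct=%.1f",
                     x$n_peptides, x$n_active, x$active_pct), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
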