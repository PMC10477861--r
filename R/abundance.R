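#' Mapping parameters for protein-space read mapping
#'
#' Controls the internal seed-and-extend mapper that aligns six-frame
#' translations of DNA reads against a peptide catalog. Defaults are chosen so
#' that reads drawn exactly from a catalog peptide's coding sequence (with at
#' least `min_match_len` in-frame codons) always map, while uniform-random
#' reads map with negligible probability.
#'
#' @param kmer_size seed k-mer length in residues (>= 3,
#'   `<= min_match_len`); default 4.
#' @param min_match_len minimum accepted ungapped match span in residues;
#'   default 8.
#' @param min_identity minimum fraction of identical residues over the match
#'   span, in (0, 1\]; default 0.9.
#' @param substitution_matrix substitution matrix name (see
#'   [substitution_matrix()]); default `"BLOSUM62"`.
#' @param min_orf_len minimum translated fragment length in residues;
#'   default 8.
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(kmer_size = 4L, min_match_len = 8L,
                           min_identity = 0.9,
                           substitution_matrix = "BLOSUM62",
                           min_orf_len = 8L) {
  kmer_size <- as.integer(kmer_size)
  min_match_len <- as.integer(min_match_len)
  min_orf_len <- as.integer(min_orf_len)
  if (kmer_size < 3L) stop("`kmer_size` must be >= 3")
  if (kmer_size > min_match_len) stop("`kmer_size` must be <= `min_match_len`")
  if (min_identity <= 0 || min_identity > 1) {
    stop("`min_identity` must lie in (0, 1]")
  }
  structure(list(kmer_size = kmer_size, min_match_len = min_match_len,
                 min_identity = min_identity,
                 substitution_matrix = substitution_matrix,
                 min_orf_len = min_orf_len),
            class = "mapping_params")
}

#' Six-frame translation of a DNA read
#'
#' Translates the read in the three forward and three reverse-complement
#' frames under the standard genetic code. Fragments are split at stop codons
#' and at codons containing ambiguous bases (which would translate to X);
#' only fragments of at least `min_orf_len` residues are returned. Frames are
#' labelled +1, +2, +3 (forward) and -1, -2, -3 (reverse complement).
#'
#' @param read DNA string over A, C, G, T, N (case-insensitive).
#' @param min_orf_len minimum fragment length in residues; default 8.
#' @return data frame with columns `fragment` (amino-acid string) and
#'   `frame` (integer in +-1..3); zero rows if no frame yields a long-enough
#'   fragment.
#' @examples
#' translate_six_frames("ATGGCCAAAGGTTTACCCGGG", min_orf_len = 3)
#' @export
translate_six_frames <- function(read, min_orf_len = 8L) {
  stopifnot(is.character(read), length(read) == 1L)
  if (grepl("[^ACGTNacgtn]", read)) {
    stop("read must be over the alphabet {A, C, G, T, N}")
  }
  res <- cpp_translate_six_frames(toupper(read), as.integer(min_orf_len))
  data.frame(fragment = as.character(res$fragment),
             frame = as.integer(res$frame),
             stringsAsFactors = FALSE)
}

#' Build an amino-acid k-mer index over a peptide catalog
#'
#' Every position of every catalog peptide of length >= `kmer_size` is
#' indexed; postings are deterministic in catalog order. Peptides shorter
#' than the k-mer size are excluded with a warning.
#'
#' @param catalog a `peptide_catalog`.
#' @param kmer_size k-mer length in residues (>= 3); default 4.
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(catalog, kmer_size = 4L) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  kmer_size <- as.integer(kmer_size)
  if (kmer_size < 3L) stop("`kmer_size` must be >= 3")
  short <- nchar(catalog$records$sequence) < kmer_size
  if (any(short)) {
    warning("excluding ", sum(short), " peptide(s) shorter than the k-mer ",
            "size: ", paste(catalog$records$id[short], collapse = ", "))
  }
  recs <- catalog$records[!short, , drop = FALSE]
  xptr <- cpp_build_index(recs$id, recs$sequence, kmer_size)
  structure(list(xptr = xptr, kmer_size = kmer_size,
                 peptide_ids = recs$id, n_kmers = cpp_index_size(xptr)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d, %d peptide(s), %d distinct k-mer(s)\n",
              x$kmer_size, length(x$peptide_ids), x$n_kmers))
  invisible(x)
}

#' Postings for one k-mer
#'
#' @param index a `kmer_index`.
#' @param kmer amino-acid k-mer of the index's k.
#' @return data frame with columns `peptide` (id) and `offset` (0-based
#'   position within the peptide); zero rows if the k-mer is absent.
#' @export
kmer_postings <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  res <- cpp_query_index(index$xptr, toupper(kmer))
  data.frame(peptide = as.character(res$peptide),
             offset = as.integer(res$offset), stringsAsFactors = FALSE)
}

#' Map a DNA read to its best-hit catalog peptide
#'
#' Each translated fragment (see [translate_six_frames()]) is seeded by exact
#' k-mer matches against the index and extended without gaps under the
#' substitution matrix; a candidate hit must span at least `min_match_len`
#' residues at identity >= `min_identity`. Among candidates the
#' highest-scoring one wins; ties break to the lexicographically smallest
#' peptide id. A read maps to at most one peptide.
#'
#' @param read DNA string.
#' @param index a `kmer_index` built with `params$kmer_size`.
#' @param params a `mapping_params` object.
#' @return the best-hit peptide id, or `NA_character_` for no hit.
#' @export
map_read <- function(read, index, params = mapping_params()) {
  map_reads(read, index, params)
}

#' Map many DNA reads to their best-hit catalog peptides
#'
#' Vectorized form of [map_read()].
#'
#' @param reads character vector of DNA reads.
#' @param index a `kmer_index`.
#' @param params a `mapping_params` object.
#' @return character vector of best-hit peptide ids (`NA` = no hit).
#' @export
map_reads <- function(reads, index, params = mapping_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(params, "mapping_params"))
  if (index$kmer_size != params$kmer_size) {
    stop("index was built with k = ", index$kmer_size,
         " but params$kmer_size = ", params$kmer_size)
  }
  sub <- substitution_matrix(params$substitution_matrix)
  hit <- cpp_map_reads(index$xptr, toupper(reads), params$min_orf_len,
                       params$min_match_len, params$min_identity, sub)
  ifelse(is.na(hit), NA_character_, index$peptide_ids[hit])
}

#' Per-sample read set
#'
#' Container for one metagenomic sample: either in-memory reads or a path to
#' a FASTA/FASTQ file streamed at profiling time.
#'
#' @param sample_id sample identifier.
#' @param group group label, `"case"` or `"control"`.
#' @param reads character vector of DNA reads (optional if `path` given).
#' @param path path to a FASTA or FASTQ file (optional if `reads` given).
#' @param total_reads total sequenced reads; defaults to `length(reads)` or
#'   the number of records in `path`.
#' @return an object of class `sample_reads`.
#' @export
sample_reads <- function(sample_id, group, reads = NULL, path = NULL,
                         total_reads = NULL) {
  group <- match.arg(group, c("case", "control"))
  if (is.null(reads) && is.null(path)) {
    stop("one of `reads` or `path` is required")
  }
  if (!is.null(reads) && !is.null(total_reads) &&
      total_reads != length(reads)) {
    stop("`total_reads` must equal the number of reads supplied")
  }
  if (!is.null(reads) && is.null(total_reads)) total_reads <- length(reads)
  structure(list(sample_id = as.character(sample_id), group = group,
                 reads = reads, path = path, total_reads = total_reads),
            class = "sample_reads")
}

# Load the reads of a sample_reads object (streams from file if needed).
load_sample_reads <- function(sample) {
  if (!is.null(sample$reads)) return(sample$reads)
  if (!file.exists(sample$path)) {
    stop("read file missing for sample ", sample$sample_id, ": ", sample$path)
  }
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", sample$path, ignore.case = TRUE)) {
    "fastq"
  } else "fasta"
  as.character(Biostrings::readDNAStringSet(sample$path, format = fmt))
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `group` (case/control) and
#' `path` to each sample's FASTA/FASTQ reads. Relative paths are resolved
#' against the sheet's directory.
#'
#' @param path sample sheet path.
#' @return list of `sample_reads` objects.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "path")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) {
      p2 <- file.path(base, p)
      if (file.exists(p2)) p <- p2
    }
    sample_reads(df$sample_id[i], df$group[i], path = p)
  })
}

#' Profile peptide abundance across samples (coverage per million reads)
#'
#' Maps each sample's reads against the catalog and reports, per peptide and
#' sample, the mapped-read count scaled to one million total sequenced reads:
#' `CPM = mapped_reads * 1e6 / total_reads`. Each read contributes to at most
#' one peptide, so per-sample CPM sums never exceed one million. A per-residue
#' length-normalized variant is available via `length_normalize = TRUE`
#' (counts divided by peptide length before scaling).
#'
#' @param samples list of `sample_reads` objects.
#' @param catalog a `peptide_catalog`.
#' @param params a `mapping_params` object.
#' @param length_normalize divide mapped counts by peptide residue length
#'   before CPM scaling; default `FALSE`.
#' @param verbose log per-sample mapped/total counts to stderr.
#' @return an object of class `abundance_matrix`: list with `values`
#'   (peptides x samples numeric matrix), `peptide_ids`, `sample_ids`,
#'   `group_labels`, `mapped_reads`, `total_reads`.
#' @export
profile_abundance <- function(samples, catalog, params = mapping_params(),
                              length_normalize = FALSE, verbose = FALSE) {
  if (inherits(samples, "sample_reads")) samples <- list(samples)
  stopifnot(length(samples) >= 1, inherits(catalog, "peptide_catalog"))
  if (length(catalog) == 0) stop("catalog is empty")
  index <- build_kmer_index(catalog, params$kmer_size)
  pep_ids <- catalog$records$id
  pep_len <- nchar(catalog$records$sequence)
  sub <- substitution_matrix(params$substitution_matrix)
  n_s <- length(samples)
  values <- matrix(0, nrow = length(pep_ids), ncol = n_s,
                   dimnames = list(pep_ids, NULL))
  sample_ids <- character(n_s)
  groups <- character(n_s)
  mapped <- integer(n_s)
  totals <- numeric(n_s)
  for (i in seq_len(n_s)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "sample_reads"))
    reads <- load_sample_reads(s)
    total <- if (is.null(s$total_reads)) length(reads) else s$total_reads
    if (total == 0) stop("sample ", s$sample_id, " has zero total reads")
    hit <- cpp_map_reads(index$xptr, toupper(reads), params$min_orf_len,
                         params$min_match_len, params$min_identity, sub)
    counts <- tabulate(hit, nbins = length(index$peptide_ids))
    cnt <- stats::setNames(numeric(length(pep_ids)), pep_ids)
    cnt[index$peptide_ids] <- counts
    eff <- if (length_normalize) cnt / pep_len else cnt
    values[, i] <- eff * 1e6 / total
    sample_ids[i] <- s$sample_id
    groups[i] <- s$group
    mapped[i] <- sum(counts)
    totals[i] <- total
    if (verbose) {
      message(sprintf("sample %s: %d/%d reads mapped", s$sample_id,
                      mapped[i], as.integer(total)))
    }
  }
  colnames(values) <- sample_ids
  structure(list(values = values, peptide_ids = pep_ids,
                 sample_ids = sample_ids, group_labels = groups,
                 mapped_reads = mapped, total_reads = totals),
            class = "abundance_matrix")
}

#' Construct an abundance matrix from CPM values
#'
#' Mainly for tests and for loading externally computed matrices.
#'
#' @param values peptides x samples numeric matrix of CPM values (>= 0), with
#'   rownames = peptide ids and colnames = sample ids.
#' @param group_labels character vector (`"case"`/`"control"`) per sample.
#' @return an `abundance_matrix`.
#' @export
abundance_matrix <- function(values, group_labels) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("CPM values must be non-negative")
  if (length(group_labels) != ncol(values)) {
    stop("one group label per sample column is required")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("peptide_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  structure(list(values = values, peptide_ids = rownames(values),
                 sample_ids = colnames(values),
                 group_labels = as.character(group_labels),
                 mapped_reads = NULL, total_reads = NULL),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d peptide(s) x %d sample(s) [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$group_labels)),
                            as.integer(table(x$group_labels))),
                    collapse = ", ")))
  invisible(x)
}

#' Write an abundance matrix as TSV
#'
#' Layout: a first header row of sample ids (first cell `peptide_id`), a
#' second header row of group labels (first cell `#group`), then one row per
#' peptide.
#'
#' @param x an `abundance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("peptide_id", x$sample_ids), collapse = "\t"), con)
  writeLines(paste(c("#group", x$group_labels), collapse = "\t"), con)
  df <- data.frame(peptide_id = x$peptide_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' Inverse of [write_abundance_tsv()].
#'
#' @param path input path.
#' @return an `abundance_matrix`.
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[2], "#group")) {
    stop("not an abundance TSV (missing '#group' header row): ", path)
  }
  sample_ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  groups <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  df <- read.delim(path, skip = 2L, header = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- list(df[[1]], sample_ids)
  abundance_matrix(values, groups)
}
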