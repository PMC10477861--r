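#' Global pairwise alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch global alignment under the Gotoh three-state
#' recurrence. A gap of length L costs `gap_open + (L - 1) * gap_extend`, end
#' gaps are penalized (no free end gaps), and scores are kept in exact
#' half-unit arithmetic so half-integer extend penalties never produce float
#' ties. The traceback is deterministic with state preference
#' diagonal > up > left; the score is the stable contract, the alignment
#' strings are one optimal alignment among possibly several.
#'
#' Identity is reported over the full alignment length including gap columns.
#'
#' @param seq_a,seq_b amino-acid strings of canonical residues.
#' @param matrix substitution matrix name or 20x20 matrix
#'   (see [substitution_matrix()]); default `"BLOSUM62"`.
#' @param gap_open gap opening penalty (>= `gap_extend`); default 10.
#' @param gap_extend gap extension penalty (> 0, multiple of 0.5);
#'   default 0.5.
#' @return an object of class `alignment_result`: `score`, `aligned_a`,
#'   `aligned_b`, `alignment_length`, `n_identical`, `identity_pct`.
#' @examples
#' aln <- needleman_wunsch("HEAGAWGHEE", "PAWHEAE")
#' aln$score
#' @export
needleman_wunsch <- function(seq_a, seq_b, matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  if (gap_extend <= 0) stop("`gap_extend` must be positive")
  if (gap_open < gap_extend) stop("`gap_open` must be >= `gap_extend`")
  open2 <- 2 * gap_open
  ext2 <- 2 * gap_extend
  if (abs(open2 - round(open2)) > 1e-9 || abs(ext2 - round(ext2)) > 1e-9) {
    stop("gap penalties must be multiples of 0.5")
  }
  sub <- substitution_matrix(matrix)
  sub2 <- sub * 2L
  res <- cpp_nw_affine(toupper(seq_a), toupper(seq_b), sub2,
                       as.integer(round(open2)), as.integer(round(ext2)))
  ga <- res$aligned_a
  gb <- res$aligned_b
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  n_ident <- sum(ca == cb & ca != "-")
  len <- length(ca)
  structure(list(
    score = res$score2 / 2,
    aligned_a = ga, aligned_b = gb,
    alignment_length = len,
    n_identical = n_ident,
    identity_pct = 100 * n_ident / len
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("global alignment: score %.1f, identity %.1f%% (%d/%d)\n",
              x$score, x$identity_pct, x$n_identical, x$alignment_length))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

# Coerce a catalog or character vector to a named sequence vector.
as_sequence_set <- function(x, default_prefix = "seq") {
  if (inherits(x, "peptide_catalog")) return(catalog_sequences(x))
  stopifnot(is.character(x))
  if (is.null(names(x))) {
    names(x) <- paste0(default_prefix, seq_along(x))
  }
  x
}

#' Pairwise identity distribution between peptide sets
#'
#' Computes global-alignment identities for all cross pairs of `set_a` and
#' `set_b` (or all unordered within-`set_a` pairs if `within = TRUE`,
#' self-pairs excluded), bins them into fixed-width identity bins, and
#' reports the fraction of pairs above requested thresholds.
#'
#' @param set_a,set_b `peptide_catalog` objects or (named) character vectors
#'   of sequences; `set_b` ignored when `within = TRUE`.
#' @param within compare `set_a` against itself; default `FALSE`.
#' @param thresholds identity thresholds (percent) for `fraction_over`;
#'   default 80.
#' @param bin_width identity bin width in percentage points; default 10.
#' @param ... passed to [needleman_wunsch()] (matrix, gap penalties).
#' @return an object of class `identity_distribution`: `pairs` (data frame
#'   `id_a`, `id_b`, `score`, `identity_pct`), `pair_identities`,
#'   `bin_counts` (histogram over `[0, 100]` in `bin_width` steps, closed on
#'   the right), `fraction_over` (named by threshold).
#' @export
identity_distribution <- function(set_a, set_b = NULL, within = FALSE,
                                  thresholds = 80, bin_width = 10, ...) {
  a <- as_sequence_set(set_a, "a")
  if (length(a) == 0) stop("`set_a` is empty")
  if (within) {
    if (length(a) < 2) stop("`within = TRUE` requires >= 2 sequences")
    idx <- utils::combn(length(a), 2)
    ia <- idx[1, ]; ib <- idx[2, ]
    b <- a
  } else {
    if (is.null(set_b)) stop("`set_b` is required when `within = FALSE`")
    b <- as_sequence_set(set_b, "b")
    if (length(b) == 0) stop("`set_b` is empty")
    grid <- expand.grid(seq_along(a), seq_along(b))
    ia <- grid[[1]]; ib <- grid[[2]]
  }
  n <- length(ia)
  score <- numeric(n)
  ident <- numeric(n)
  for (i in seq_len(n)) {
    aln <- needleman_wunsch(a[[ia[i]]], b[[ib[i]]], ...)
    score[i] <- aln$score
    ident[i] <- aln$identity_pct
  }
  pairs <- data.frame(id_a = names(a)[ia], id_b = names(b)[ib],
                      score = score, identity_pct = ident,
                      stringsAsFactors = FALSE)
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  bins <- table(cut(ident, breaks = breaks, include.lowest = TRUE,
                    right = TRUE))
  fraction_over <- vapply(thresholds, function(t) mean(ident > t), numeric(1))
  names(fraction_over) <- paste0(">", thresholds, "%")
  structure(list(pairs = pairs, pair_identities = ident,
                 bin_counts = bins, fraction_over = fraction_over),
            class = "identity_distribution")
}

#' @export
print.identity_distribution <- function(x, ...) {
  cat(sprintf("identity_distribution: %d pair(s), median identity %.1f%%\n",
              nrow(x$pairs), stats::median(x$pair_identities)))
  for (nm in names(x$fraction_over)) {
    cat(sprintf("  fraction %s: %.4f\n", nm, x$fraction_over[[nm]]))
  }
  invisible(x)
}

#' Contrast two identity distributions
#'
#' One-sided (default) Welch t contrast between the pairwise identities of
#' two distributions, e.g. within-reference identities versus
#' candidate-to-reference identities. Delegates to [contrast_sets()].
#'
#' @param dist_a,dist_b `identity_distribution` objects (>= 2 pairs each).
#' @param sidedness `"greater"` (default: tests dist_a higher),
#'   `"less"`, or `"two.sided"`.
#' @return a `set_contrast`.
#' @export
compare_identity_distributions <- function(dist_a, dist_b,
                                           sidedness = c("greater", "less",
                                                         "two.sided")) {
  stopifnot(inherits(dist_a, "identity_distribution"),
            inherits(dist_b, "identity_distribution"))
  sidedness <- match.arg(sidedness)
  contrast_sets(dist_a$pair_identities, dist_b$pair_identities,
                sidedness = sidedness)
}

#' Write pairwise identities as TSV
#' @param dist an `identity_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(dist, path) {
  stopifnot(inherits(dist, "identity_distribution"))
  write.table(dist$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an identity histogram as TSV
#' @param dist an `identity_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identity_hist_tsv <- function(dist, path) {
  stopifnot(inherits(dist, "identity_distribution"))
  df <- data.frame(bin = names(dist$bin_counts),
                   count = as.integer(dist$bin_counts),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
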