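# Kyte-Doolittle hydropathy scale (J Mol Biol 1982), canonical residues.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Split a sequence into residues, erroring on the first non-canonical one.
split_residues <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty ", what)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% AA_ALPHABET))
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d of %s",
                 res[bad[1]], bad[1], what))
  }
  res
}

#' GRAVY score (grand average of hydropathy)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues.
#' Negative values indicate hydrophilic peptides, positive values hydrophobic
#' ones; the score is bounded by the scale's extremes (-4.5 for Arg, +4.5 for
#' Ile).
#'
#' @param sequence amino-acid string of canonical residues.
#' @return numeric GRAVY score.
#' @examples
#' gravy("AAA")  # 1.8
#' gravy("AK")   # -1.05
#' @export
gravy <- function(sequence) {
  res <- split_residues(sequence)
  mean(KD_HYDROPATHY[res])
}

#' Net charge at neutral pH (counting formula)
#'
#' Counts basic minus acidic residues: (#K + #R) - (#D + #E). Histidine and
#' the termini are excluded; see the methods vignette for the rationale of
#' this deterministic convention. A Henderson-Hasselbalch estimate at a given
#' pH is available via `method = "hh"`.
#'
#' @param sequence amino-acid string of canonical residues.
#' @param method `"count"` (default) or `"hh"` (Henderson-Hasselbalch with
#'   side-chain and terminal pKa values).
#' @param pH pH for `method = "hh"`; default 7.0.
#' @return signed numeric charge (integer-valued for `method = "count"`).
#' @examples
#' net_charge("KRK")   # 3
#' net_charge("DDE")   # -3
#' @export
net_charge <- function(sequence, method = c("count", "hh"), pH = 7.0) {
  method <- match.arg(method)
  res <- split_residues(sequence)
  if (method == "count") {
    return(sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")))
  }
  # Henderson-Hasselbalch with EMBOSS-style pKa values
  pka_pos <- c(K = 10.53, R = 12.48, H = 6.00)
  pka_neg <- c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07)
  pos <- sum(vapply(names(pka_pos), function(a) {
    sum(res == a) / (1 + 10^(pH - pka_pos[[a]]))
  }, numeric(1)))
  neg <- sum(vapply(names(pka_neg), function(a) {
    sum(res == a) / (1 + 10^(pka_neg[[a]] - pH))
  }, numeric(1)))
  nterm <- 1 / (1 + 10^(pH - 8.6))
  cterm <- 1 / (1 + 10^(3.6 - pH))
  pos + nterm - neg - cterm
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 canonical residues in a sequence. All 20 keys
#' are always present (zeros included); fractions sum to 1.
#'
#' @param sequence amino-acid string of canonical residues.
#' @return named numeric vector of length 20.
#' @export
aa_composition <- function(sequence) {
  res <- split_residues(sequence)
  counts <- table(factor(res, levels = AA_ALPHABET))
  as.numeric(counts) / length(res) -> frac
  stats::setNames(frac, AA_ALPHABET)
}

#' Physicochemical profile of a peptide catalog
#'
#' @param catalog a `peptide_catalog`.
#' @return data frame with columns `id`, `length`, `gravy`, `net_charge`,
#'   then the 20 residue-frequency columns.
#' @export
physchem_profile <- function(catalog) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  seqs <- catalog_sequences(catalog)
  comp <- t(vapply(seqs, aa_composition, numeric(20)))
  data.frame(
    id = names(seqs),
    length = nchar(seqs),
    gravy = vapply(seqs, gravy, numeric(1)),
    net_charge = vapply(seqs, net_charge, numeric(1)),
    comp,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write a physicochemical profile table as TSV
#' @param profile data frame from [physchem_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_physchem_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Histogram of peptide lengths over closed bins
#'
#' Bins are closed on both ends and defined by consecutive edge pairs:
#' `bin_edges = c(6, 30, 50)` gives bins \[6, 30\] and \[31, 50\]. Lengths
#' falling outside every bin are counted in an `overflow` bin.
#'
#' @param catalog a `peptide_catalog`.
#' @param bin_edges strictly increasing integer vector of length >= 2.
#' @return named integer vector of bin counts plus an `overflow` count;
#'   counts sum to the catalog size.
#' @examples
#' cat1 <- peptide_catalog(c("a", "b", "c"),
#'                         c(strrep("A", 10), strrep("A", 20), strrep("A", 35)))
#' length_bins(cat1, c(6, 30, 50))  # [6-30]: 2, [31-50]: 1
#' @export
length_bins <- function(catalog, bin_edges) {
  stopifnot(inherits(catalog, "peptide_catalog"))
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing with length >= 2")
  }
  lens <- nchar(catalog$records$sequence)
  nb <- length(bin_edges) - 1L
  lo <- c(bin_edges[1], bin_edges[-c(1, length(bin_edges))] + 1L)
  hi <- bin_edges[-1]
  counts <- integer(nb + 1L)
  labels <- c(sprintf("[%d-%d]", lo, hi), "overflow")
  for (l in lens) {
    hit <- which(l >= lo & l <= hi)
    if (length(hit) == 0) counts[nb + 1L] <- counts[nb + 1L] + 1L
    else counts[hit[1]] <- counts[hit[1]] + 1L
  }
  stats::setNames(counts, labels)
}

#' Welch t contrast between two sets of values
#'
#' Unequal-variance (Welch) two-sample t-test with explicit sidedness.
#' `"greater"` tests whether set a exceeds set b; `"less"` the reverse.
#' Two constant sets are degenerate: the p-value is 1 when they are
#' identical (0 when not), and the result is flagged.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param sidedness `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return an object of class `set_contrast`: `statistic`, `p_value`,
#'   `direction` (`"a higher"`, `"b higher"`, `"equal"`), `test_name`,
#'   `sidedness`, `degenerate`.
#' @export
contrast_sets <- function(values_a, values_b,
                          sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each set must contain at least 2 values")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  direction <- if (ma > mb) "a higher" else if (mb > ma) "b higher" else "equal"
  degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
  if (degenerate) {
    if (ma == mb) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(ma - mb) * Inf
      p <- switch(sidedness,
                  two.sided = 0,
                  greater = if (ma > mb) 0 else 1,
                  less = if (ma < mb) 0 else 1)
    }
  } else {
    tt <- t.test(values_a, values_b, alternative = sidedness,
                 var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(statistic = stat, p_value = p, direction = direction,
                 test_name = "Welch two-sample t-test",
                 sidedness = sidedness, degenerate = degenerate),
            class = "set_contrast")
}

#' @export
print.set_contrast <- function(x, ...) {
  cat(sprintf("%s (%s): t = %.4g, p = %.4g, %s%s\n",
              x$test_name, x$sidedness, x$statistic, x$p_value, x$direction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Write set contrasts as TSV
#' @param contrasts named list of `set_contrast` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contrasts_tsv <- function(contrasts, path) {
  df <- do.call(rbind, lapply(names(contrasts), function(nm) {
    x <- contrasts[[nm]]
    data.frame(comparison = nm, test = x$test_name, sidedness = x$sidedness,
               statistic = x$statistic, p_value = x$p_value,
               direction = x$direction, degenerate = x$degenerate,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
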