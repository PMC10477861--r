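#' Synthetic cohort configuration
#'
#' Parameters of the two-group synthetic metagenome generator. Defaults
#' emulate a desk-scale case/control gut-metagenome comparison: per-peptide
#' base relative abundances are log-normal, a planted subset differs between
#' groups by a fixed symmetric log2 fold-change, and every sample adds
#' log-normal biological jitter so rank tests face realistic overdispersion.
#'
#' @param n_peptides catalog size the config is meant for; default 1000.
#' @param frac_planted fraction of peptides carrying a planted effect;
#'   default 0.05 (signs alternate: half control-enriched, half
#'   case-enriched).
#' @param planted_log2fc absolute planted log2 fold-change (control over
#'   case); default 3. Split symmetrically: control gets `2^(+lfc/2)`,
#'   case `2^(-lfc/2)`.
#' @param n_ctrl,n_case samples per group; default 30 each.
#' @param reads_per_sample total reads per sample; default 1e5.
#' @param read_length_nt read length; default 100.
#' @param base_meanlog,base_sdlog log-normal parameters of per-peptide base
#'   relative abundance; defaults `log(2e-4)` and 0.5.
#' @param jitter_sdlog per-sample log-normal biological jitter sd (log
#'   scale); default 0.5.
#' @param min_overlap_nt minimum overlap of a coding read with the coding
#'   sequence; default 24 (codon-aligned windows, see the methods vignette).
#' @param seed master seed (mandatory); per-sample streams are derived from
#'   it deterministically.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 1000L, frac_planted = 0.05,
                       planted_log2fc = 3, n_ctrl = 30L, n_case = 30L,
                       reads_per_sample = 1e5, read_length_nt = 100L,
                       base_meanlog = log(2e-4), base_sdlog = 0.5,
                       jitter_sdlog = 0.5, min_overlap_nt = 24L,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is mandatory")
  }
  stopifnot(n_peptides >= 1, n_ctrl >= 1, n_case >= 1,
            reads_per_sample >= 1, read_length_nt >= 1,
            frac_planted > 0, frac_planted <= 1,
            min_overlap_nt >= 3, min_overlap_nt %% 3 == 0)
  if (frac_planted * n_peptides < 1) {
    stop("`frac_planted * n_peptides` must be >= 1")
  }
  if (min_overlap_nt > 3 * floor(read_length_nt / 3)) {
    stop("`min_overlap_nt` cannot exceed the read length")
  }
  structure(list(n_peptides = as.integer(n_peptides),
                 frac_planted = frac_planted,
                 planted_log2fc = planted_log2fc,
                 n_ctrl = as.integer(n_ctrl), n_case = as.integer(n_case),
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length_nt = as.integer(read_length_nt),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 jitter_sdlog = jitter_sdlog,
                 min_overlap_nt = as.integer(min_overlap_nt),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random peptide catalog
#'
#' Uniform-random canonical sequences with lengths uniform in
#' `length_range`. The default range (31-50 residues) matches the length
#' profile of metagenome-mined candidate peptides, which run longer than
#' classical database ACPs (6-30 residues).
#'
#' @param n number of peptides (>= 1).
#' @param length_range integer vector `c(min, max)`, `1 <= min <= max`.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @param prefix id prefix; ids are `<prefix>0001`, ...
#' @return a `peptide_catalog`.
#' @export
generate_catalog <- function(n, length_range = c(31L, 50L), seed,
                             prefix = "pep") {
  stopifnot(n >= 1)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    stop("`length_range` must be c(min, max) with 1 <= min <= max")
  }
  with_seed(seed, {
    span <- length_range[2] - length_range[1] + 1L
    lens <- length_range[1] + sample.int(span, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(l) {
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
    }, character(1))
    ids <- sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))),
                   seq_len(n))
    peptide_catalog(ids, seqs, name = "synthetic")
  })
}

# Reverse codon table: canonical residue -> synonymous codons (standard code).
reverse_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_ALPHABET]
}

#' Reverse-translate a peptide to a DNA coding sequence
#'
#' Picks a uniform-random synonymous codon per residue under the standard
#' genetic code, so translating the output in frame +1 recovers the peptide
#' exactly.
#'
#' @param peptide amino-acid string of canonical residues.
#' @param seed optional RNG seed (caller's RNG state restored).
#' @return DNA string of length `3 * nchar(peptide)`.
#' @examples
#' reverse_translate("M")  # "ATG"
#' @export
reverse_translate <- function(peptide, seed = NULL) {
  res <- split_residues(peptide, "peptide")
  tab <- reverse_codon_table()
  with_seed(seed, {
    paste(vapply(res, function(a) {
      cods <- tab[[a]]
      cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
  })
}

# Reverse complement for plain character vectors of DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a two-group cohort of metagenomic samples
#'
#' Per sample, each read is a peptide-coding read with probability equal to
#' that sample's per-peptide relative abundance (base abundance drawn
#' log-normally, scaled by `2^(+-planted_log2fc/2)` by group for planted
#' peptides, then jittered log-normally per sample), otherwise a
#' uniform-random background read. Coding reads are codon-aligned random
#' windows of the peptide's reverse-translated coding sequence (at least
#' `min_overlap_nt` of coding bases), padded with random flanking sequence to
#' the read length, on a random strand. Fully reproducible for a given
#' config.
#'
#' @param catalog a `peptide_catalog` (its size overrides
#'   `config$n_peptides`).
#' @param config a `sim_config`.
#' @param out_dir optional directory: when given, per-sample FASTQ files
#'   (constant quality), a sample sheet TSV, a truth TSV and the catalog
#'   FASTA are written there, and the returned samples reference the files
#'   instead of holding reads in memory.
#' @return list with `samples` (list of `sample_reads`), `truth` (data
#'   frame: `peptide_id`, `planted_log2fc`, `base_abundance`, `is_null`),
#'   and `config`.
#' @export
simulate_cohort <- function(catalog, config, out_dir = NULL) {
  stopifnot(inherits(catalog, "peptide_catalog"),
            inherits(config, "sim_config"))
  n_pep <- length(catalog)
  pep_ids <- catalog$records$id
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  }
  with_seed(config$seed, {
    # planted truth
    n_planted <- max(1L, round(config$frac_planted * n_pep))
    planted_idx <- sort(sample.int(n_pep, n_planted))
    signs <- rep_len(c(1, -1), n_planted)
    lfc <- numeric(n_pep)
    lfc[planted_idx] <- signs * config$planted_log2fc
    base <- rlnorm(n_pep, config$base_meanlog, config$base_sdlog)
    truth <- data.frame(peptide_id = pep_ids, planted_log2fc = lfc,
                        base_abundance = base, is_null = lfc == 0,
                        stringsAsFactors = FALSE)
    # fixed coding sequence per peptide
    cds <- vapply(catalog$records$sequence, function(p) {
      reverse_translate(p)
    }, character(1), USE.NAMES = FALSE)
    # per-sample derived seed streams
    n_samples <- config$n_ctrl + config$n_case
    groups <- c(rep("control", config$n_ctrl), rep("case", config$n_case))
    sample_ids <- sprintf("%s%03d", ifelse(groups == "control", "ctrl", "case"),
                          c(seq_len(config$n_ctrl), seq_len(config$n_case)))
    sample_seeds <- sample.int(2147483646L, n_samples)
    samples <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      set.seed(sample_seeds[i])
      gmult <- if (groups[i] == "control") 2^(lfc / 2) else 2^(-lfc / 2)
      jitter <- rlnorm(n_pep, 0, config$jitter_sdlog)
      frac <- base * gmult * jitter
      ftot <- sum(frac)
      if (ftot >= 1) {
        stop(sprintf("expected coding fraction %.3f >= 1 in sample %s; ",
                     ftot, sample_ids[i]),
             "lower the base abundance or catalog size")
      }
      counts <- rmultinom(1, config$reads_per_sample, c(frac, 1 - ftot))[, 1]
      reads <- generate_sample_reads(counts, cds, config)
      if (!is.null(out_dir)) {
        fq <- file.path(out_dir, paste0(sample_ids[i], ".fastq"))
        write_fastq(reads, fq, id_prefix = sample_ids[i])
        samples[[i]] <- sample_reads(sample_ids[i], groups[i], path = fq,
                                     total_reads = length(reads))
      } else {
        samples[[i]] <- sample_reads(sample_ids[i], groups[i], reads = reads)
      }
    }
    if (!is.null(out_dir)) {
      write_fasta(catalog, file.path(out_dir, "catalog.fasta"))
      write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sheet <- data.frame(
        sample_id = sample_ids, group = groups,
        path = paste0(sample_ids, ".fastq"), stringsAsFactors = FALSE)
      write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      yaml::write_yaml(unclass(config), file.path(out_dir, "manifest.yaml"))
    }
    list(samples = samples, truth = truth, config = config)
  })
}

# Build one sample's reads: counts is length n_pep + 1 (background last).
# Coding windows are codon-aligned so a read overlapping the coding sequence
# by `min_overlap_nt` always carries min_overlap_nt/3 in-frame codons.
generate_sample_reads <- function(counts, cds, config) {
  n_pep <- length(cds)
  rl <- config$read_length_nt
  cc <- counts[seq_len(n_pep)]
  m <- sum(cc)
  reads <- character(0)
  if (m > 0) {
    pidx <- rep.int(seq_len(n_pep), cc)
    len <- nchar(cds)[pidx]
    ov <- pmin(config$min_overlap_nt, 3L * (len %/% 3L))
    w_max <- 3L * (rl %/% 3L)
    n_starts <- (len - ov) %/% 3L + 1L
    s <- 3L * pmin(n_starts - 1L, as.integer(floor(runif(m) * n_starts)))
    w <- pmin(w_max, len - s)
    coding <- substring(cds[pidx], s + 1L, s + w)
    pad <- rl - w
    fl <- pmin(pad, as.integer(floor(runif(m) * (pad + 1L))))
    fr <- pad - fl
    flanks <- cpp_random_dna(m, rl)
    reads <- paste0(substring(flanks, 1L, fl), coding,
                    substring(flanks, fl + 1L, fl + fr))
    flip <- runif(m) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
  }
  bg <- cpp_random_dna(counts[n_pep + 1L], rl)
  c(reads, bg)
}

#' Write DNA reads as FASTQ with constant quality
#'
#' @param reads character vector of DNA reads.
#' @param path output path.
#' @param id_prefix read id prefix.
#' @param quality_char quality character for every base; default `"I"`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, id_prefix = "read",
                        quality_char = "I") {
  set <- Biostrings::DNAStringSet(reads)
  names(set) <- sprintf("%s_%07d", id_prefix, seq_along(reads))
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}
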