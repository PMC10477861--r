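test_that("six-frame translation follows the standard code and stop rule", {
  # hand translation: ATG GCC AAA -> MAK in frame +1
  tf <- translate_six_frames("ATGGCCAAAGGTTTACCCGGGATTATT", min_orf_len = 3)
  expect_true("MAKGLPGII" %in% tf$fragment[tf$frame == 1])
  # in-frame stop splits the fragment
  tf2 <- translate_six_frames("ATGGCCAAATAAATGGCCAAA", min_orf_len = 3)
  plus1 <- tf2$fragment[tf2$frame == 1]
  expect_equal(plus1, c("MAK", "MAK"))
  # short read yields nothing at high min_orf_len
  expect_equal(nrow(translate_six_frames("ATGGCC", min_orf_len = 8)), 0L)
  expect_error(translate_six_frames("ATGQ"), "alphabet")
})

test_that("reverse-complement reads give mirrored frame sets", {
  set.seed(31)
  read <- cpp_random_dna(1, 60)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  f1 <- translate_six_frames(read, min_orf_len = 3)
  f2 <- translate_six_frames(rc, min_orf_len = 3)
  expect_setequal(f1$fragment[f1$frame > 0], f2$fragment[f2$frame < 0])
  expect_setequal(f1$fragment[f1$frame < 0], f2$fragment[f2$frame > 0])
})

test_that("codons containing N translate to X and split fragments", {
  # ATG GCC AAA | N.. | ATG GCC AAA: N codon acts as a separator
  tf <- translate_six_frames("ATGGCCAAANNNATGGCCAAA", min_orf_len = 3)
  expect_equal(tf$fragment[tf$frame == 1], c("MAK", "MAK"))
})

test_that("k-mer index covers every position and reports postings in order", {
  cat1 <- peptide_catalog(c("pA", "pB"), c("MKTP", "AMKT"))
  idx <- build_kmer_index(cat1, 3)
  expect_equal(sort(c(kmer_postings(idx, "MKT")$peptide,
                      kmer_postings(idx, "KTP")$peptide,
                      kmer_postings(idx, "AMK")$peptide)),
               c("pA", "pA", "pB", "pB"))
  p <- kmer_postings(idx, "MKT")
  expect_equal(p$peptide, c("pA", "pB"))
  expect_equal(p$offset, c(0L, 1L))
  expect_equal(nrow(kmer_postings(idx, "WWW")), 0L)
  # peptides shorter than k excluded with a warning
  short <- peptide_catalog(c("s1", "s2"), c("MK", "MKTPAY"))
  expect_warning(idx2 <- build_kmer_index(short, 4), "shorter")
  expect_equal(idx2$peptide_ids, "s2")
})

test_that("reads encoding an exact peptide substring map to that peptide", {
  cat1 <- generate_catalog(10, c(31, 50), seed = 5)
  params <- mapping_params()
  idx <- build_kmer_index(cat1, params$kmer_size)
  for (i in c(1, 4, 10)) {
    cds <- reverse_translate(cat1$records$sequence[i], seed = i)
    read <- substr(cds, 1, 45) # 15 codons
    expect_equal(map_read(read, idx, params), cat1$records$id[i])
    # and on the reverse strand
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(read)))
    expect_equal(map_read(rc, idx, params), cat1$records$id[i])
  }
})

test_that("random reads with no shared seed return no hit", {
  cat1 <- peptide_catalog("pep1", strrep("W", 40)) # poly-Trp never arises
  idx <- build_kmer_index(cat1, 4)
  set.seed(17)
  reads <- cpp_random_dna(20, 60)
  hits <- map_reads(reads, idx)
  expect_true(all(is.na(hits)))
})

test_that("equal-scoring hits break ties to the smaller peptide id", {
  shared <- "MKTPAYIWQH" # 10 residues shared by both peptides
  cat1 <- peptide_catalog(c("pB", "pA"),
                          c(paste0(shared, "CCCCC"), paste0(shared, "WWWWW")))
  read <- reverse_translate(shared, seed = 3)
  idx <- build_kmer_index(cat1, 4)
  expect_equal(map_read(read, idx), "pA")
})

test_that("mapper agrees with the brute-force all-vs-all oracle", {
  set.seed(2024)
  params <- mapping_params()
  sub <- substitution_matrix("BLOSUM62")
  cat1 <- generate_catalog(8, c(10, 20), seed = 77)
  idx <- build_kmer_index(cat1, params$kmer_size)
  n_checked <- 0
  for (rep in 1:40) {
    if (rep %% 2 == 0) {
      read <- cpp_random_dna(1, 60)
    } else {
      # half the reads carry a (possibly partial) coding window
      i <- sample.int(8, 1)
      cds <- reverse_translate(cat1$records$sequence[i])
      s <- sample.int(max(1, nchar(cds) - 30), 1)
      core <- substr(cds, s, min(nchar(cds), s + 29))
      read <- paste0(cpp_random_dna(1, 15), core, cpp_random_dna(1, 15))
    }
    got <- map_read(read, idx, params)
    want <- oracle_map_read(read, cat1, params, sub)
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 40)
})

test_that("CPM follows the mapped-count-per-million definition", {
  cat1 <- peptide_catalog("pep1", "MKTPAYIWQHLDNRGG")
  cds <- reverse_translate("MKTPAYIWQHLDNRGG", seed = 8)
  reads <- c(rep(cds, 10), as.character(cpp_random_dna(30, 48)))
  s <- sample_reads("s1", "control", reads = reads)
  mat <- profile_abundance(list(s), cat1)
  expect_equal(unname(mat$values["pep1", "s1"]), 10 * 1e6 / 40)
  # duplicating every read (and the total) leaves CPM unchanged
  s2 <- sample_reads("s2", "control", reads = rep(reads, 2))
  mat2 <- profile_abundance(list(s2), cat1)
  expect_equal(unname(mat2$values["pep1", "s2"]),
               unname(mat$values["pep1", "s1"]))
})

test_that("profile results are independent of read input order", {
  cat1 <- generate_catalog(5, c(31, 40), seed = 9)
  cds <- vapply(cat1$records$sequence, reverse_translate, character(1))
  set.seed(10)
  reads <- c(substring(cds, 1, 45), cpp_random_dna(50, 45))
  m1 <- profile_abundance(sample_reads("s", "case", reads = reads), cat1)
  m2 <- profile_abundance(sample_reads("s", "case", reads = rev(reads)), cat1)
  expect_equal(m1$values, m2$values)
})

test_that("per-sample CPM sums never exceed one million", {
  cat1 <- generate_catalog(6, c(31, 40), seed = 21)
  sc <- sim_config(n_peptides = 6, frac_planted = 0.5, n_ctrl = 2, n_case = 2,
                   reads_per_sample = 3000, base_meanlog = log(0.02),
                   seed = 21)
  sim <- simulate_cohort(cat1, sc)
  mat <- profile_abundance(sim$samples, cat1)
  expect_true(all(colSums(mat$values) <= 1e6 + 1e-6))
  expect_true(all(mat$mapped_reads <= mat$total_reads))
})

test_that("reads from a single peptide concentrate all CPM on it", {
  cat1 <- generate_catalog(5, c(31, 40), seed = 33)
  cds <- reverse_translate(cat1$records$sequence[3], seed = 33)
  starts <- seq(1, nchar(cds) - 45, by = 3)
  reads <- substring(cds, starts, starts + 44)
  mat <- profile_abundance(sample_reads("s", "case", reads = reads), cat1)
  nonzero <- mat$peptide_ids[mat$values[, 1] > 0]
  expect_equal(nonzero, cat1$records$id[3])
})

test_that("abundance matrix TSV round-trips values and group labels", {
  set.seed(12)
  mat <- null_abundance_matrix(10, 3, 4)
  f <- tempfile(fileext = ".tsv")
  write_abundance_tsv(mat, f)
  back <- read_abundance_tsv(f)
  expect_equal(back$values, mat$values)
  expect_equal(back$group_labels, mat$group_labels)
})

test_that("degenerate profiling inputs raise errors", {
  cat1 <- peptide_catalog("p", "MKTPAYIW")
  expect_error(
    profile_abundance(sample_reads("s", "case", reads = character(0),
                                   total_reads = 0), cat1),
    "zero total reads")
  expect_error(sample_reads("s", "case"), "required")
  expect_error(sample_reads("s", "neither", reads = "ACGT"))
  expect_error(mapping_params(kmer_size = 9, min_match_len = 8), "<=")
})
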