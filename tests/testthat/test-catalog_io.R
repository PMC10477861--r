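test_that("FASTA round-trip preserves ids, order and sequences", {
  ids <- c("p1", "p2", "p3")
  seqs <- c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "GIGKFLHSAK", "ACDEFGHIKL")
  path <- write_temp_fasta(ids, seqs)
  cat1 <- read_fasta(path)
  expect_s3_class(cat1, "peptide_catalog")
  expect_equal(length(cat1), 3L)
  expect_equal(cat1$records$id, ids)
  expect_equal(cat1$records$sequence, seqs)
  out <- tempfile(fileext = ".fasta")
  write_fasta(cat1, out)
  cat2 <- read_fasta(out)
  expect_equal(cat2$records$id, cat1$records$id)
  expect_equal(cat2$records$sequence, cat1$records$sequence)
})

test_that("FASTA ids stop at first whitespace and sequences are uppercased", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "mktp", ">p2", "GIGK"), path)
  cat1 <- read_fasta(path)
  expect_equal(cat1$records$id, c("p1", "p2"))
  expect_equal(cat1$records$sequence[1], "MKTP")
  expect_equal(cat1$records$source_db[1], "some description")
})

test_that("malformed FASTA and duplicate headers are errors", {
  bad <- tempfile()
  writeLines(c("MKTP", ">p1", "ACDE"), bad)
  expect_error(read_fasta(bad), "line 1")
  dup <- tempfile()
  writeLines(c(">p1", "MKTP", ">p1", "ACDE"), dup)
  expect_error(read_fasta(dup), "duplicate")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("natural amino-acid filter removes all non-canonical letters", {
  cat1 <- peptide_catalog(c("a", "b", "c", "d", "e"),
                          c("MKT", "MXZ", "ACDEFGHIKLMNPQRSTVWY", "MBU", "MJO"))
  out <- filter_natural_aa(cat1)
  expect_equal(out$records$id, c("a", "c"))
  expect_equal(attr(out, "removed_ids"), c("b", "d", "e"))
  # all-canonical catalog unchanged
  ok <- peptide_catalog(c("x", "y"), c("MK", "WYV"))
  expect_equal(filter_natural_aa(ok)$records, ok$records)
})

test_that("deduplicate_union keeps first-seen records and is idempotent", {
  a <- peptide_catalog(c("a1", "a2", "a3"), c("MK", "MR", "MK"),
                       source_db = "A")
  b <- peptide_catalog(c("b1", "b2"), c("MK", "WW"), source_db = "B")
  u <- deduplicate_union(a, b)
  expect_equal(u$records$sequence, c("MK", "MR", "WW"))
  expect_equal(u$records$source_db, c("A", "A", "B")) # first-seen provenance
  # idempotent
  u2 <- deduplicate_union(u)
  expect_equal(u2$records$sequence, u$records$sequence)
  # |union| <= |A| + |B|
  expect_lte(length(u), length(a) + length(b))
  # disjoint sets of sizes 3 and 4 give 7
  d1 <- peptide_catalog(paste0("x", 1:3), c("AA", "CC", "DD"))
  d2 <- peptide_catalog(paste0("y", 1:4), c("EE", "FF", "GG", "HH"))
  expect_equal(length(deduplicate_union(d1, d2)), 7L)
  # internal duplicate only: 3 records with 1 duplicate -> 2
  expect_equal(length(deduplicate_union(a)), 2L)
})

test_that("overlap percentage follows the intersection-over-union definition", {
  a <- peptide_catalog(paste0("a", 1:5), c("AA", "CC", "DD", "EE", "FF"))
  expect_equal(overlap_stats(a, a)$overlap_pct, 100.0)
  b <- peptide_catalog(paste0("b", 1:2), c("WW", "YY"))
  expect_equal(overlap_stats(a, b)$overlap_pct, 0.0)
  c3 <- peptide_catalog(paste0("c", 1:3), c("AA", "CC", "WW"))
  st <- overlap_stats(a, c3)
  expect_equal(st$n_overlap, 2L)
  expect_equal(st$n_union_unique, 5L)
  expect_equal(st$overlap_pct, 40.0)
  expect_lte(st$n_overlap, min(st$n_a, st$n_b))
})

test_that("recall rate validates its inputs and rounds to two decimals", {
  expect_equal(recall_rate(1033, 1279), 80.77)
  expect_equal(recall_rate(0, 10), 0)
  expect_equal(recall_rate(10, 10), 100)
  expect_error(recall_rate(5, 0), "positive")
  expect_error(recall_rate(11, 10), "\\[0, pool\\]")
})

test_that("screen summary applies the >=20% inhibition in >=1 cell line rule", {
  # hand-evaluated 3x2 toy table
  toy <- matrix(c(85, 95, 79, 100, 100, 100), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("l1", "l2")))
  s <- summarize_screen(toy, 20)
  expect_equal(s$n_active, 1L)
  expect_equal(unname(s$per_peptide_hits), c(0L, 1L, 0L))
  # all survival 100 -> nothing active
  full <- matrix(100, 2, 2)
  expect_equal(summarize_screen(full, 20)$n_active, 0L)
  # boundary: inhibition exactly at threshold counts as active
  edge <- matrix(80, 1, 1)
  expect_equal(summarize_screen(edge, 20)$n_active, 1L)
  expect_error(summarize_screen(matrix(numeric(0), 0, 0)), "empty")
  expect_error(summarize_screen(matrix(150, 1, 1)), "\\[0, 100\\]")
})

test_that("lowering the screen threshold never decreases the active count", {
  set.seed(401)
  tab <- matrix(runif(40 * 6, 0, 100), nrow = 40)
  thresholds <- c(80, 60, 40, 20, 10, 5)
  counts <- vapply(thresholds, function(t) {
    summarize_screen(tab, t)$n_active
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("overlap and screen summaries serialize to TSV", {
  a <- peptide_catalog(paste0("a", 1:4), c("AA", "CC", "DD", "EE"))
  b <- peptide_catalog(paste0("b", 1:2), c("AA", "CC"))
  f1 <- tempfile(fileext = ".tsv")
  write_overlap_tsv(overlap_stats(a, b), f1)
  df <- read.delim(f1)
  expect_equal(df$overlap_pct, 50.0)
  f2 <- tempfile(fileext = ".tsv")
  tab <- matrix(c(50, 90), 1, 2, dimnames = list("p1", NULL))
  write_screen_tsv(summarize_screen(tab, 20), f2)
  expect_match(readLines(f2, n = 1), "n_active=1")
})
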