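test_that("presence filter keeps peptides seen in any sample", {
  vals <- matrix(0, 5, 4,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  vals[1, 2] <- 3
  vals[3, ] <- c(1, 0, 0, 2)
  vals[5, 4] <- 0.1
  mat <- abundance_matrix(vals, c("control", "control", "case", "case"))
  expect_equal(presence_filter(mat), c("p1", "p3", "p5"))
})

test_that("Wilcoxon exact branch reproduces hand-enumerated p-values", {
  # {1,2,3} vs {4,5,6}: 2 of the 20 rank splits are as extreme -> p = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical value sets carry no shift evidence -> p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1)
  # interleaved tie-free sets: 4 of 6 splits as extreme -> p = 2/3
  expect_equal(wilcoxon_rank_sum(c(1, 3), c(2, 4)), 2 / 3)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon p is invariant under strictly increasing transforms", {
  set.seed(5)
  x <- rlnorm(7); y <- rlnorm(9, 0.8)
  p0 <- wilcoxon_rank_sum(x, y)
  expect_equal(wilcoxon_rank_sum(log(x), log(y)), p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3), p0)
  expect_equal(wilcoxon_rank_sum(2 * x + 7, 2 * y + 7), p0)
})

test_that("exact Wilcoxon agrees with full permutation enumeration", {
  set.seed(81)
  for (rep in 1:12) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1)
    y <- sample(setdiff(seq_len(50), x), n2)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon_exact(x, y),
                 info = sprintf("rep %d (n1=%d, n2=%d)", rep, n1, n2))
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(123)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log2 fold change is antisymmetric and pseudocount-guarded", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(4000, 1000, pseudocount = 1e-9), 2,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(3, 11), -log2_fold_change(11, 3))
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 2), "non-negative")
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "positive")
})

test_that("funnel reproduces a hand-executed toy example", {
  # 6 peptides, 10 + 10 samples: p1 planted control-enriched, p2 planted
  # case-enriched, p3 flat, p4-p6 absent.
  n <- 10
  vals <- matrix(0, 6, 2 * n,
                 dimnames = list(paste0("p", 1:6),
                                 c(paste0("c", 1:n), paste0("k", 1:n))))
  vals[1, ] <- c(800 + (1:n), 40 + (1:n))     # ctrl ~ 805, case ~ 45
  vals[2, ] <- c(30 + (1:n), 900 + (1:n))     # case-enriched
  vals[3, ] <- c(500 + (1:n), 500 + (1:n) + 0.5)
  mat <- abundance_matrix(vals, c(rep("control", n), rep("case", n)))
  out <- run_funnel(mat, funnel_config())
  r <- out$report
  expect_equal(r$n_input, 6L)
  expect_equal(r$n_present, 3L)
  expect_equal(r$n_significant, 2L)      # p1 and p2 separate perfectly
  expect_equal(r$n_fc_pass, 2L)          # |log2fc| > 2 both
  expect_equal(r$n_ctrl_enriched, 1L)    # only p1
  expect_equal(r$retained_ids$ctrl_enriched, "p1")
  # floor: p1 ctrl mean ~805.5 CPM = 8.055e-4 rel abundance > 2e-4
  expect_equal(r$n_abundant, 1L)
  expect_equal(r$retained_ids$abundant, "p1")
  # results table consistency
  res <- out$results
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all((res$log2fc > 0) == (res$enriched_in == "control")))
})

test_that("vacuous thresholds retain every control-leaning present peptide", {
  set.seed(55)
  mat <- null_abundance_matrix(40, 8, 8)
  cfg <- funnel_config(fdr_threshold = 1 + 1e-9, log2fc_cutoff = 1e-12,
                       abundance_floor = 1e-300)
  out <- run_funnel(mat, cfg)
  expect_equal(out$report$n_abundant,
               sum(out$results$log2fc > 1e-12))
})

test_that("an all-zero matrix yields zero counts at every stage", {
  vals <- matrix(0, 4, 6, dimnames = list(paste0("p", 1:4), NULL))
  mat <- abundance_matrix(vals, rep(c("control", "case"), each = 3))
  out <- run_funnel(mat)
  r <- out$report
  expect_equal(c(r$n_present, r$n_significant, r$n_fc_pass,
                 r$n_ctrl_enriched, r$n_abundant), rep(0L, 5))
})

test_that("funnel counts are non-increasing along the stages", {
  set.seed(66)
  for (rep in 1:5) {
    mat <- null_abundance_matrix(60, 6, 6, sdlog = 2)
    # sprinkle zeros so presence bites
    mat$values[sample(length(mat$values), 80)] <- 0
    r <- run_funnel(mat, funnel_config(fdr_threshold = 0.5,
                                       log2fc_cutoff = 0.2,
                                       abundance_floor = 1e-5))$report
    counts <- c(r$n_input, r$n_present, r$n_significant, r$n_fc_pass,
                r$n_ctrl_enriched, r$n_abundant)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("funnel requires both groups and writes its TSV outputs", {
  vals <- matrix(1, 3, 4, dimnames = list(paste0("p", 1:3), NULL))
  mono <- abundance_matrix(vals, rep("case", 4))
  expect_error(run_funnel(mono), "both")
  mat <- abundance_matrix(vals, rep(c("control", "case"), 2))
  out <- run_funnel(mat)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_differential_tsv(out$results, f1)
  write_funnel_tsv(out$report, f2)
  expect_equal(nrow(read.delim(f1)), 3L)
  fr <- read.delim(f2)
  expect_equal(fr$stage, c("input", "present", "significant", "fc_pass",
                           "ctrl_enriched", "abundant"))
  expect_equal(fr$n_retained[1], 3L)
})
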