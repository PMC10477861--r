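#' Funnel configuration
#'
#' Thresholds of the differential-enrichment funnel. The abundance floor is
#' on the relative-abundance (fraction of total reads) scale; with the
#' default 2e-4 it corresponds to 200 CPM. Which group's mean is compared
#' against the floor is configurable because conventions differ.
#'
#' @param fdr_threshold BH-adjusted p-value threshold (strict `<`);
#'   default 0.05.
#' @param log2fc_cutoff absolute log2 fold-change cutoff (strict `>`);
#'   default 2.
#' @param abundance_floor mean relative-abundance floor (strict `>`);
#'   default 2e-4.
#' @param pseudocount CPM offset added to both means before the ratio;
#'   default 0.5.
#' @param floor_scale `"fraction"` (default; floor compared against mean
#'   CPM / 1e6) or `"cpm"`.
#' @param floor_group group whose mean is compared to the floor,
#'   `"control"` (default) or `"case"`.
#' @return an object of class `funnel_config`.
#' @export
funnel_config <- function(fdr_threshold = 0.05, log2fc_cutoff = 2,
                          abundance_floor = 2e-4, pseudocount = 0.5,
                          floor_scale = c("fraction", "cpm"),
                          floor_group = c("control", "case")) {
  floor_scale <- match.arg(floor_scale)
  floor_group <- match.arg(floor_group)
  if (fdr_threshold <= 0 || log2fc_cutoff <= 0 || abundance_floor <= 0 ||
      pseudocount <= 0) {
    stop("all funnel thresholds must be positive")
  }
  structure(list(fdr_threshold = fdr_threshold,
                 log2fc_cutoff = log2fc_cutoff,
                 abundance_floor = abundance_floor,
                 pseudocount = pseudocount,
                 floor_scale = floor_scale,
                 floor_group = floor_group),
            class = "funnel_config")
}

#' Presence filter
#'
#' Retains peptides observed (CPM > 0) in at least one sample of either
#' group.
#'
#' @param matrix an `abundance_matrix`.
#' @return character vector of retained peptide ids.
#' @export
presence_filter <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (nrow(matrix$values) == 0) stop("empty abundance matrix")
  keep <- rowSums(matrix$values > 0) >= 1
  matrix$peptide_ids[keep]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Two-tailed Mann-Whitney / Wilcoxon rank-sum test between two groups of
#' abundance values. The exact null distribution is used when the smaller
#' group has at most 8 observations and the combined values are tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param values_ctrl,values_case numeric vectors, each non-empty, combined
#'   length >= 2.
#' @return two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(values_ctrl, values_case) {
  if (length(values_ctrl) == 0 || length(values_case) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(values_ctrl) + length(values_case) < 2) {
    stop("combined sample size must be >= 2")
  }
  ties <- anyDuplicated(c(values_ctrl, values_case)) > 0
  exact <- !ties && min(length(values_ctrl), length(values_case)) <= 8
  p <- suppressWarnings(
    wilcox.test(values_ctrl, values_case, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
  # all values tied across both groups: no evidence of a shift
  if (is.nan(p)) p <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with enforced monotonicity, capped at 1; input
#' order is preserved.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values (same length and order).
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Log2 fold change, control over case
#'
#' `log2((mean_ctrl + pseudocount) / (mean_case + pseudocount))`; positive
#' values indicate enrichment in the control (healthy) group.
#'
#' @param mean_ctrl,mean_case group mean abundances (>= 0), CPM scale.
#' @param pseudocount positive offset; default 0.5.
#' @return log2 fold change (vectorized).
#' @export
log2_fold_change <- function(mean_ctrl, mean_case, pseudocount = 0.5) {
  if (any(mean_ctrl < 0) || any(mean_case < 0)) {
    stop("means must be non-negative")
  }
  if (pseudocount <= 0) stop("`pseudocount` must be positive")
  log2((mean_ctrl + pseudocount) / (mean_case + pseudocount))
}

#' Run the differential-enrichment funnel
#'
#' Stages, in order:
#' 1. presence (CPM > 0 in >= 1 sample);
#' 2. two-sided Wilcoxon rank-sum per peptide, BH FDR computed over present
#'    peptides only, retain FDR < `fdr_threshold`;
#' 3. |log2FC| > `log2fc_cutoff`;
#' 4. log2FC > 0 (control/healthy-enriched);
#' 5. mean relative abundance in the floor group > `abundance_floor`.
#'
#' All inequalities at thresholds are strict.
#'
#' @param matrix an `abundance_matrix` containing both groups.
#' @param config a `funnel_config`.
#' @return list with `results` (data frame: `peptide_id`, `mean_ctrl`,
#'   `mean_case`, `p_value`, `fdr`, `log2fc`, `enriched_in` for every present
#'   peptide) and `report` (a `funnel_report`: stage counts `n_input`,
#'   `n_present`, `n_significant`, `n_fc_pass`, `n_ctrl_enriched`,
#'   `n_abundant` and per-stage `retained_ids`).
#' @export
run_funnel <- function(matrix, config = funnel_config()) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(config, "funnel_config"))
  groups <- matrix$group_labels
  if (!all(c("case", "control") %in% groups)) {
    stop("abundance matrix must contain both 'case' and 'control' samples")
  }
  ctrl <- matrix$values[, groups == "control", drop = FALSE]
  case <- matrix$values[, groups == "case", drop = FALSE]

  present <- presence_filter(matrix)
  keep <- matrix$peptide_ids %in% present

  results <- data.frame(peptide_id = character(0), mean_ctrl = numeric(0),
                        mean_case = numeric(0), p_value = numeric(0),
                        fdr = numeric(0), log2fc = numeric(0),
                        enriched_in = character(0), stringsAsFactors = FALSE)
  if (any(keep)) {
    idx <- which(keep)
    p <- vapply(idx, function(i) {
      wilcoxon_rank_sum(ctrl[i, ], case[i, ])
    }, numeric(1))
    mc <- rowMeans(ctrl)[idx]
    mk <- rowMeans(case)[idx]
    lfc <- log2_fold_change(mc, mk, config$pseudocount)
    results <- data.frame(
      peptide_id = matrix$peptide_ids[idx],
      mean_ctrl = unname(mc),
      mean_case = unname(mk),
      p_value = p,
      fdr = bh_adjust(p),
      log2fc = lfc,
      enriched_in = ifelse(lfc > 0, "control",
                           ifelse(lfc < 0, "case", "none")),
      stringsAsFactors = FALSE
    )
  }

  sig <- results[results$fdr < config$fdr_threshold, , drop = FALSE]
  fc <- sig[abs(sig$log2fc) > config$log2fc_cutoff, , drop = FALSE]
  ctrl_enr <- fc[fc$log2fc > 0, , drop = FALSE]
  floor_mean <- if (config$floor_group == "control") {
    ctrl_enr$mean_ctrl
  } else ctrl_enr$mean_case
  floor_val <- if (config$floor_scale == "fraction") {
    floor_mean / 1e6
  } else floor_mean
  abundant <- ctrl_enr[floor_val > config$abundance_floor, , drop = FALSE]

  report <- structure(list(
    n_input = length(matrix$peptide_ids),
    n_present = nrow(results),
    n_significant = nrow(sig),
    n_fc_pass = nrow(fc),
    n_ctrl_enriched = nrow(ctrl_enr),
    n_abundant = nrow(abundant),
    retained_ids = list(
      present = results$peptide_id,
      significant = sig$peptide_id,
      fc_pass = fc$peptide_id,
      ctrl_enriched = ctrl_enr$peptide_id,
      abundant = abundant$peptide_id
    ),
    config = config
  ), class = "funnel_report")
  list(results = results, report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("differential-enrichment funnel:\n")
  cat(sprintf("  input:               %6d\n", x$n_input))
  cat(sprintf("  present:             %6d\n", x$n_present))
  cat(sprintf("  FDR < %-6.3g        %6d\n",
              x$config$fdr_threshold, x$n_significant))
  cat(sprintf("  |log2FC| > %-4.3g     %6d\n",
              x$config$log2fc_cutoff, x$n_fc_pass))
  cat(sprintf("  control-enriched:    %6d\n", x$n_ctrl_enriched))
  cat(sprintf("  abundance > %-8.3g %6d\n",
              x$config$abundance_floor, x$n_abundant))
  invisible(x)
}

#' Write differential results as TSV
#' @param results data frame from [run_funnel()]`$results`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a funnel report as TSV
#'
#' One row per stage: stage name, retained count, and a comma-separated
#' retained-id list.
#'
#' @param report a `funnel_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel_tsv <- function(report, path) {
  stopifnot(inherits(report, "funnel_report"))
  stages <- c("input", "present", "significant", "fc_pass",
              "ctrl_enriched", "abundant")
  counts <- c(report$n_input, report$n_present, report$n_significant,
              report$n_fc_pass, report$n_ctrl_enriched, report$n_abundant)
  ids <- c("", vapply(report$retained_ids, paste, character(1),
                      collapse = ","))
  df <- data.frame(stage = stages, n_retained = counts, retained_ids = ids,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
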