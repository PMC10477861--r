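# acpmine

Mining anticancer peptide (ACP) candidates from gut metagenomes.

Known ACPs overlap strongly with antimicrobial peptides, so AMP-style
prediction over metagenome-encoded peptides yields large candidate pools —
far too large to synthesize and screen. `acpmine` implements the second
mining stage that makes such a campaign tractable: it quantifies each
candidate peptide's abundance across case/control metagenomic cohorts
(e.g. colorectal-cancer patients vs healthy controls) and keeps the
candidates that are statistically enriched in **healthy** individuals, the
signature expected of a peptide antagonizing tumors.

The package provides, as composable R functions plus a thin command-line
tool (`exec/acpmine`):

* **Catalog handling** — FASTA I/O, exact-sequence deduplication, filtering
  to the 20 canonical residues, overlap/recall statistics, cell-line screen
  summaries (`read_fasta`, `deduplicate_union`, `overlap_stats`,
  `recall_rate`, `summarize_screen`).
* **Protein-space abundance** — six-frame translation of DNA reads,
  k-mer-seeded ungapped mapping against the peptide catalog (BLOSUM62,
  span ≥ 8 residues, identity ≥ 0.9 by default), and coverage per million
  reads: CPM(p, s) = mapped_reads(p, s) × 10⁶ / total_reads(s)
  (`translate_six_frames`, `map_read`, `profile_abundance`).
* **The mining funnel** — presence → per-peptide two-tailed Wilcoxon
  rank-sum → Benjamini–Hochberg FDR < 0.05 → |log2FC| > 2 →
  control-enriched (log2FC > 0) → mean relative abundance > 2×10⁻⁴, with
  log2FC = log2((CPM̄_control + 0.5)/(CPM̄_case + 0.5)) and per-stage
  retention counts (`run_funnel`, `wilcoxon_rank_sum`, `bh_adjust`).
* **Novelty assessment** — affine-gap Needleman–Wunsch global alignment
  (Gotoh recurrence; gap open 10, extend 0.5; identity over the full
  alignment length) and pairwise identity distributions
  (`needleman_wunsch`, `identity_distribution`).
* **Physicochemical profiling** — GRAVY (Kyte–Doolittle mean hydropathy),
  net charge (#K + #R − #D − #E), amino-acid composition, length
  histograms, Welch t contrasts (`gravy`, `net_charge`, `physchem_profile`).
* **Synthetic cohorts** — a fully seeded generator of two-group read sets
  with planted log-normal abundances and known fold-changes, so the entire
  pipeline is testable offline (`generate_catalog`, `simulate_cohort`).

See `vignettes/mining-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

Simulate a small cohort with planted healthy-enriched peptides, profile it,
and run the funnel:

```r
library(acpmine)

catalog <- generate_catalog(200, c(31, 50), seed = 42)
sc  <- sim_config(n_peptides = 200, frac_planted = 0.05, planted_log2fc = 3,
                  n_ctrl = 15, n_case = 15, reads_per_sample = 2e4, seed = 42)
sim <- simulate_cohort(catalog, sc)
mat <- profile_abundance(sim$samples, catalog)
res <- run_funnel(mat, funnel_config())
res$report
#> differential-enrichment funnel:
#>   input:                  200
#>   present:                200
#>   FDR < 0.05              10
#>   |log2FC| > 2             9
#>   control-enriched:         4
#>   abundance > 0.0002        4
```

Ten peptides differ significantly between groups (both directions), nine
pass the fold-change cutoff, four of those are enriched in controls and
abundant enough to retain. All four are planted control-enriched peptides
(five were planted; one fell below the abundance floor):

```r
res$results[res$results$peptide_id %in% res$report$retained_ids$abundant,
            c("peptide_id", "mean_ctrl", "mean_case", "fdr", "log2fc")]
#>         peptide_id mean_ctrl mean_case          fdr   log2fc
#> pep0024    pep0024  393.3333  70.00000 0.0006462647 2.481890
#> pep0049    pep0049  610.0000  76.66667 0.0002769707 2.983942
#> pep0128    pep0128  900.0000 156.66667 0.0006462647 2.518431
#> pep0153    pep0153  610.0000  63.33333 0.0002769707 3.257609
```

Means are CPM; `log2fc` near the planted value of 3 means roughly 8-fold
higher abundance in healthy controls. Characterize a candidate against a
known ACP (magainin-2-like vs buforin-like sequences):

```r
needleman_wunsch("GIGKFLHSAKKFGKAFVGEIMNS",
                 "KWKLFKKIEKVGQNIRDGIIKAGPAVAVVGQATQIAK")
#> global alignment: score -12.5, identity 15.8% (6/38)
gravy("GIGKFLHSAKKFGKAFVGEIMNS")       # 0.083  (mildly hydrophobic)
net_charge("GIGKFLHSAKKFGKAFVGEIMNS")  # +3     (cationic)
```

The same pipeline runs from the shell:

```sh
exec/acpmine simulate --out cohort/ --seed 42
exec/acpmine profile  --catalog cohort/catalog.fasta \
                      --samples cohort/samples.tsv --out cohort/abundance.tsv
exec/acpmine mine     --abundance cohort/abundance.tsv --out cohort/mining
```

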