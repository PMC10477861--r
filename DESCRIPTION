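Package: acpmine
Title: Mining Anticancer Peptide Candidates from Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining candidate anticancer peptides (ACPs) from gut
    metagenomic cohorts. Provides peptide catalog handling (FASTA input and
    output, deduplication, natural amino-acid filtering, overlap statistics),
    protein-space mapping of short DNA reads against a peptide catalog via
    six-frame translation and seed-and-extend alignment, coverage-per-million
    abundance profiling, a differential-enrichment funnel (presence filter,
    Wilcoxon rank-sum tests, Benjamini-Hochberg false discovery rate control,
    log2 fold-change and abundance-floor filters), affine-gap Needleman-Wunsch
    global alignment with identity statistics for sequence-novelty assessment,
    physicochemical descriptors (GRAVY hydropathy, net charge, amino-acid
    composition), and a synthetic two-group cohort simulator with planted
    differential signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
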