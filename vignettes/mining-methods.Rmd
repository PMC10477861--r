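---
title: "Mining anticancer peptide candidates from metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining anticancer peptide candidates from metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpmine)
```

## The problem

Anticancer peptides (ACPs) overlap heavily with antimicrobial peptides
(AMPs), and AMP prediction models recall known ACPs well. That makes the gut
metagenome — a vast reservoir of peptide-coding sequence — a plausible place
to mine for new ACP candidates. A prediction model alone, however, produces
long candidate lists with many false positives. `acpmine` implements the
second, epidemiological stage of such a mining campaign: given a candidate
peptide catalog and case/control metagenomic cohorts (here, colorectal
cancer patients versus healthy controls), quantify each peptide's abundance
in every sample and keep the candidates that are statistically enriched in
*healthy* individuals — the signature one expects of a peptide that
antagonizes tumors.

The package covers peptide catalog handling, protein-space read mapping with
coverage-per-million (CPM) abundance, the differential-enrichment funnel,
sequence-novelty assessment by global alignment, physicochemical
descriptors, and a synthetic cohort generator with planted ground truth that
makes the whole pipeline testable without any external downloads.

## Abundance: protein-space read mapping

Peptide catalogs live in amino-acid space while metagenomic reads are DNA,
so each read is translated in all six frames (three forward, three on the
reverse complement) under the standard genetic code. Fragments are split at
stop codons and at codons containing ambiguous bases (which would translate
to `X`), and only fragments of at least `min_orf_len` residues (default 8)
are kept.

Each fragment is then matched against the catalog by a seed-and-extend
search: exact amino-acid k-mers (default k = 4) seed candidate
peptide/diagonal pairs, and each diagonal is scanned for its best-scoring
ungapped segment under BLOSUM62 subject to two acceptance constraints — a
span of at least `min_match_len` residues (default 8) and at least
`min_identity` identical positions over the span (default 0.9). Among
accepted candidates the highest-scoring one wins; ties break to the
lexicographically smallest peptide id, and a read contributes to at most one
peptide even if it covers it at two offsets. The mapper is validated against
a brute-force oracle that aligns every fragment against every peptide at
every diagonal and enumerates every contiguous segment.

The defaults were chosen so that a read carrying at least eight in-frame
codons of a catalog peptide's coding sequence always maps, while a
uniform-random 100-nt read maps with probability below 1e-4 against a
1000-peptide catalog (an exact shared 8-mer, or a 9-mer with one mismatch,
is essentially required). All thresholds are exposed in `mapping_params()`
because no single published parameterization exists for this step.

Abundance is *coverage per million reads*:

$$\mathrm{CPM}(p, s) = \frac{\text{reads of sample } s \text{ mapped to }
p \times 10^6}{\text{total reads of sample } s}.$$

We use mapped-read counts per million *total* reads (the convention implied
by an idxstats-style counting workflow); a per-residue length-normalized
variant is available via `length_normalize = TRUE` but is not the default,
and normalization by mapped rather than total reads is deliberately not
offered — it would make CPM depend on the catalog.

## The differential-enrichment funnel

`run_funnel()` applies five ordered stages:

1. **Presence** — keep peptides with CPM > 0 in at least one sample of
   either group. "Present" is interpreted over all samples rather than
   cases only; with case-only presence a peptide absent from cases but
   common in controls (exactly the signature being mined) would be
   discarded.
2. **Significance** — per-peptide two-tailed Wilcoxon rank-sum test between
   groups, Benjamini–Hochberg adjustment computed *over the present peptides
   only*, retain FDR < 0.05. Computing BH after the presence filter mirrors
   the stage ordering of the funnel; adjusting over the full input catalog
   would mix never-observed peptides into the multiplicity correction.
3. **Effect size** — |log2FC| > 2, where
   log2FC = log2((mean CPM control + c) / (mean CPM case + c)) with
   pseudocount c = 0.5 CPM for zero-safety.
4. **Direction** — log2FC > 0, i.e. enriched in healthy controls.
5. **Abundance floor** — mean *relative* abundance (CPM / 10^6) in the
   control group > 2e-4, removing candidates too rare to validate. The
   floor's scale (fraction vs CPM) and group are configurable
   (`funnel_config()`) because conventions differ; the default reads the
   threshold on the fraction scale, applied to the control mean, since the
   direction stage has just selected control-enriched peptides.

All threshold comparisons are strict inequalities. The Wilcoxon test uses
the exact null distribution when the smaller group has at most 8
observations and the pooled values are tie-free, and the normal
approximation with tie and continuity corrections otherwise; completely tied
inputs (all values equal) return p = 1. Cohorts are pooled into a single
two-group comparison; per-cohort stratified testing or meta-analytic
combination is out of scope.

## Sequence novelty

Candidates are compared to reference ACP sets with global Needleman–Wunsch
alignment under affine gap penalties (Gotoh three-state recurrence),
defaults BLOSUM62, gap open 10, gap extend 0.5. Conventions:

* a gap of length L costs `open + (L - 1) * extend`;
* end gaps are penalized (no free end gaps);
* identity is reported over the full alignment length including gap columns;
* scores are kept in doubled integer units so half-integer extend penalties
  never create floating-point ties;
* the traceback prefers diagonal over up over left, making the reported
  alignment deterministic; the *score* is the tested contract, since optimal
  alignments need not be unique.

`identity_distribution()` aggregates pairwise identities (within a set or
across two sets) into 10-point bins and threshold exceedance fractions, and
`compare_identity_distributions()` contrasts two such distributions with a
one-sided Welch t-test.

## Physicochemical descriptors

GRAVY is the arithmetic mean of Kyte–Doolittle hydropathy values; a
homopolymer's GRAVY equals its residue's table value, which the tests
exploit as ground truth. Net charge defaults to the counting formula
(#K + #R) − (#D + #E) at neutral pH, excluding histidine and the termini.
The literature tools this step replaces do not document a single charge
formula, so the package's contract is the deterministic count; a
Henderson–Hasselbalch estimate at arbitrary pH is available via
`net_charge(method = "hh")` for users who want partial charges. Length
histograms use bins closed on both ends (`[6–30]`, `[31–50]`), matching how
peptide length ranges are conventionally quoted. Set-level contrasts use
Welch's unequal-variance t-test with explicit sidedness; two constant sets
are flagged degenerate (p = 1 if identical, 0 otherwise) rather than
erroring mid-pipeline.

## The synthetic cohort generator

`simulate_cohort()` emulates a two-group gut-metagenome cohort at desk
scale. Per peptide, a base relative abundance is drawn log-normally
(default meanlog = log(2e-4), sdlog = 0.5); a planted subset (default 5%)
receives a symmetric group effect, control × 2^(+lfc/2) and case
× 2^(−lfc/2) with |lfc| = 3 by default, signs alternating so half the
planted peptides are control-enriched and half case-enriched and the
overall abundance scale stays group-balanced. Every sample adds independent
log-normal jitter (sdlog 0.5) so the rank tests face realistic
overdispersion rather than pure counting noise. Read counts per peptide are
multinomial; coding reads are random codon-aligned windows of the peptide's
reverse-translated coding sequence (minimum 24 nt of coding bases), padded
to the read length (default 100 nt) with uniform-random flanks, on a random
strand; all remaining reads are uniform-random background DNA.

Defaults were set once, before any end-to-end runs, to represent a
realistic-but-detectable regime: a median base abundance of 2e-4 places
null peptides at the funnel's abundance floor, so control-enriched planted
peptides (boosted ×2^1.5) sit comfortably above it while a few with
unluckily low base abundance may legitimately fail the floor stage; 30
samples per group and 1e5 reads per sample give the Wilcoxon stage clear
power at |lfc| = 3. Windows are codon-aligned so that every coding read
carries at least eight complete in-frame codons and is guaranteed mappable
at the mapper's defaults — with arbitrary phase a 24-nt overlap can contain
only seven complete codons and would undercount coverage.

Determinism: the master seed drives planted assignment, base abundances and
per-peptide coding sequences, and per-sample RNG streams are derived from it
by sample index, so a simulation is byte-identical across runs (the test
suite asserts identical FASTQ output).

What the generator does *not* emulate: real genomic background (background
reads are uniform-random DNA, which makes spurious mapping quantifiably
rare but also means the mapper is never challenged with homologous
sequence), sequencing error, GC bias, paired-end structure, or strain-level
variation. Passing the recovery tests therefore demonstrates that the
pipeline's statistics and bookkeeping are correct under its stated model,
not that the mapper is robust to real-world homology; with real data the
protein-space mapping step inherits the usual caveats of short-read peptide
quantification.

## Problem sizes used by the automated checks

The end-to-end recovery check runs the full generator → mapper → funnel
chain at the generator's defaults (1000 peptides, 5% planted at |lfc| = 3,
30 + 30 samples, 1e5 reads per sample, ~6 million reads in total) and
requires sensitivity ≥ 0.9 for planted control-enriched peptides with an
empirical false-discovery proportion ≤ 0.1. Error control is checked on a
global-null matrix of 500 peptides × 60 samples, where the fraction passing
the FDR stage must stay within Monte-Carlo error of the nominal 0.05. The
alignment, Wilcoxon, and BH implementations are compared against brute-force
enumeration oracles on hundreds of small random instances; these sizes keep
the whole suite in the minutes range on a single CPU while leaving the
asymptotic behavior to the analytical arguments above.

## Known limitations

* The mapper is ungapped after seeding; a read whose best protein-space
  alignment to a peptide requires an indel will not map. For 100-nt reads
  against 31–50-residue peptides this is the same regime in which
  ungapped protein-space aligners are routinely used.
* CPM is count-based, not per-base coverage; peptides of very different
  lengths attract proportionally different read counts
  (`length_normalize = TRUE` addresses this when comparing across
  peptides).
* The funnel treats samples as exchangeable within groups: no covariates,
  no per-cohort stratification, no compositional transforms.
* Reported p-values for physicochemical contrasts depend on the reference
  sets supplied; the package does not ship any external reference
  database.
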