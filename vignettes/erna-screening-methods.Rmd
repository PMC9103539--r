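---
title: "Methods: screening a locus for candidate enhancer RNAs"
author: "ernascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening a locus for candidate enhancer RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernascreen)
```

## The problem and the model

Active enhancers are transcribed, and the resulting enhancer RNAs (eRNAs)
can participate in the regulation of the genes their enhancer contacts.
When a translocation hijacks a strong enhancer cluster — the motivating
case is an immunoglobulin heavy-chain (IGH) locus driving a translocated
oncogene in B-cell lymphoma — an eRNA transcribed from that cluster is a
candidate tumour-selective target, provided an siRNA can be designed
against unique sequence. The screen implemented here formalizes that
search as a funnel over a single locus:

candidate windows → transcribed windows → merged regions → densely
covered sub-regions → repeat-free sub-regions → annotation-supported
candidates.

The package treats the locus as a closed universe (no whole-genome
indexing) and all coordinates as 0-based half-open; conversion to the
1-based conventions of GTF and SAM happens only at the I/O boundary.
This removes a whole class of off-by-one errors: every stage speaks one
dialect, and the converters are round-trip tested.

## Read placement: the ungapped one-mismatch contract

Reads are placed wherever the Hamming distance between the (possibly
reverse-complemented) read and the locus substring is at most k, with
k = 1 by default. The contract is deliberately ungapped — substitutions
only, no indels or splicing — because it is exact and oracle-checkable:
an exhaustive scan over every offset of both strands defines the correct
answer, and the production mapper must reproduce it identically.

The production path finds candidates by the pigeonhole principle: split
the read into k + 1 contiguous blocks; any placement with ≤ k mismatches
contains at least one block that matches exactly. Blocks are
exact-matched against the locus (in bulk, one dictionary pass per block
width across all reads), and every candidate offset is verified by a full
Hamming comparison. An `N` in read or locus matches nothing: it counts as
a mismatch at its own position, so N-rich reads cannot seed spurious
coverage. Reads shorter than 2(k + 1) bases are rejected (the split
degenerates) with a warning rather than an error, so one bad read never
aborts a batch.

Multi-mapping policy is explicit rather than implicit: the default
`all_hits` reports every placement with the `is_multi` flag set, and
`best_only` restricts to minimum-mismatch placements. Ties are ordered by
position then strand, making output bit-reproducible.

## The funnel's formal rules

**Zero-read elimination** keeps a candidate window iff at least one
alignment overlaps it by ≥ 1 bp. It runs *before* merging, so only
covered windows are combined — merging first would let an empty window
bridge two covered ones.

**Merging** combines overlapping windows into their union hull.
Bookended windows (end touching start) also combine by default
(`merge_touching = TRUE`): adjacency is treated as continuity of the
covered territory, the more inclusive reading, and the flag makes the
alternative selectable. Merging is idempotent and order-invariant, and
conserves covered bases — all property-tested against a per-base
occupancy oracle.

**Dense sub-regions** make "densely covered" precise with three
parameters: minimum per-base depth c (default 5 reads), minimum length
L (default 100 bp — shorter stretches are poor siRNA design territory
and likelier depth noise), and maximum bridged gap g (default 50 bp, one
read length, so a single missing read inside a transcript does not split
it). The rule: take maximal runs of bases with depth ≥ c, bridge internal
sub-threshold runs of length ≤ g, and keep runs of final length ≥ L.
Because only *internal* gaps are bridged, every sub-region begins and
ends on a base at or above threshold — no trailing low-coverage flanks.
There is no canonical published threshold set for this step; these are
the package's own defaults, all exposed in `dense_params()`.

**Repeat filtering** removes a sub-region when the fraction of its bases
covered by the union of repeats in the filtered classes (SINE, LINE,
LTR, DNA) exceeds `max_overlap_frac`, default 0 — any overlap
disqualifies, the strict reading of "absence of repeats", appropriate
when the goal is a uniquely targetable sequence. Repeat classes are
parsed, never guessed, and unknown classes ("other") never trigger
filtering. A merged region survives (the uniqueness verdict) iff at
least one of its sub-regions does.

**Annotation** requires ≥ 1 bp overlap with an annotated *exon*, not the
transcript's genomic span: exonic read support is what evidences a
spliced, processed eRNA, while intron-only overlap is weak evidence and
is deliberately not counted (the exon tables are available, so a span
rule is a one-line change for users who want it). Unmatched survivors
are reported as novel rather than discarded — absence of annotation is a
finding, not a failure.

The funnel report records count and identifiers after every stage, and
both the merged count and the with-dense-sub-region count are reported
separately, since published funnels do not always say which of the two a
"merged regions" figure refers to.

## Co-expression screen

Spearman's ρ is the Pearson correlation of midranks (tie-aware). The
p-value policy switches by sample size: the t approximation with n − 2
degrees of freedom for n ≥ 10; exact enumeration of all n! rank
permutations for n ≤ 8; seeded Monte-Carlo (≥ 10⁴ permutations, add-one
corrected) for n = 9. With the large sample sizes of tissue expression
panels the t path is the one exercised in practice; the exact path exists
so small pilot panels are not at the mercy of the asymptotics. Genes are
ranked by ascending p, ties broken by |ρ| descending then gene
identifier — a total, deterministic order — and the top K (default 500)
are exported as plain TSV for external enrichment services. No
multiple-testing correction is applied before the top-K cut: the
selection is a rank cut, and any monotone correction of raw p leaves the
ranking unchanged. Zero-variance genes are flagged and skipped, never
reported as ρ = 0.

## Expression statistics

ΔΔCt: per sample, replicate Ct values are averaged and
ΔCt = Ct_target − Ct_reference formed; ΔΔCt subtracts the *median*
control ΔCt (robust to one outlier control; the mean is available by
argument); fold change is E^−ΔΔCt with amplification efficiency E = 2
unless configured. Reference subtraction makes the result invariant to
any constant added to a sample's Cts, which is property-tested.

The Wilcoxon tests follow an explicit exactness contract: for effective
n ≤ 12 (after dropping zero differences, whose count is reported) the
two-sided p comes from full enumeration — all 2ⁿ sign assignments for
the signed-rank test, all group assignments for the rank-sum test —
using the tie-adjusted rank vector; beyond that, a normal approximation
with tie and continuity corrections. When every paired difference is
zero the result is flagged undefined rather than forced to a number. The
default flavour for knockdown data is the one-sample signed-rank test of
control-normalized fold changes against 1, matching a paired
design normalized within experiment; rank-sum mode is provided since
tabulated data do not always preserve the pairing. Student's t is the
pooled-variance two-sided test (delegated to `stats::t.test`), with
degenerate zero-variance inputs given defined, flagged behaviour.
Viability normalization divides each measurement by the mean drug-free
value of its own (cell line, arm) group.

## What the synthetic generator emulates — and what it does not

`simulate_locus()` is *structural by construction*: the configuration
fixes how many peak windows are transcribed (default 5 of 12), that
exactly one transcribed pair overlaps (so merging collapses 5 → 4), how
many covered groups are fully repeat-masked (default 2), and that one
surviving group carries a two-exon lncRNA. Positions, spacing, and
sequence are seeded-random; the *counts* are invariants. The expected
funnel — 12 → 5 → 4 → 4 → 2 → 1 under defaults — is therefore
recomputable from the recorded ground truth alone, for any seed, by an
independent recount, which is exactly how the end-to-end tests validate
the pipeline. Reads start uniformly within transcribed intervals (lying
fully inside them), with count `depth × length / read_len` per interval
and independent per-base substitution errors (default 1%, read length
50 bp, depth 20×: with k = 1, a binomial calculation says ~9% of reads
carry ≥ 2 errors and go unplaced, leaving ~18× effective coverage, well
above the c = 5 threshold).

The expression generator draws the target and its planted partners from
a shared latent Gaussian (correlation `effect`), exponentiated to
log-normal expression: a monotone transform, so `effect = 1` yields
Spearman ρ exactly 1 and `effect = 0.8` a rank correlation of ≈ 0.78.
The knockdown generator shifts the treated ΔCt by −log_E(true_fold)
around a 5-cycle baseline with Gaussian technical noise (default SD
0.3 cycles, typical qPCR technical variability; 3 replicates).

Deliberately not modelled: splicing and gapped alignment, strand-specific
libraries, PCR duplicates, repeat-*like sequence content* (repeats are
planted as annotation intervals, since the screen filters by annotation
overlap, not sequence self-similarity), expression-unit normalization and
covariates in the co-expression matrix, and biological (as opposed to
technical) qPCR variance components. Passing tests on this generator
therefore demonstrate the pipeline's logic and calibration, not
robustness to real-library artefacts; real-data runs enter through the
same BED/GTF/FASTQ/SAM readers, including externally produced ungapped
SAM that bypasses the internal mapper.

## Numerical and engineering choices

* Exact enumeration cut-offs (n ≤ 8 for Spearman permutations, effective
  n ≤ 12 for Wilcoxon) keep worst cases at 40320 permutations and 4096
  sign patterns — milliseconds — while covering the sample sizes where
  asymptotics are poorest.
* Comparisons against enumerated distributions use an absolute tolerance
  of 1e-9 on the statistic to make ties in the null distribution
  deterministic across platforms.
* Monte-Carlo p-values use the add-one correction, so a reported p is
  never exactly 0.
* Interval algebra (merge, overlap, coverage) is delegated to IRanges;
  exact block seeding to Biostrings; GTF parsing to rtracklayer. The
  screen's own rules (pigeonhole verify, dense-run bridging, repeat
  fraction, funnel bookkeeping) are implemented in the package and each
  is tested against an independent naive oracle.
* A single global seed fans out to per-module seeds by fixed offsets;
  every command writes a manifest (configuration, input MD5s, funnel)
  and re-running a seeded command reproduces every output file hash.

## Problem sizes

The shipped validation uses a 100 kb locus with 2000 simulated 50-mers
(≈ 20× over five 1 kb transcripts), 200 random 36-mers against a 10 kb
locus for mapper–oracle equivalence, 10-seed replicates for the
stochastic checks (localization Jaccard, co-expression recovery and
null calibration), and 1000-replicate null simulations for test
calibration. These sizes give stable pass/fail behaviour at interactive
runtimes; all are configuration, not constants.

## Known limitations

* The mapper is quadratic in the worst case (a read of one repeated
  letter against a matching homopolymer locus); for the intended
  single-locus universe this is immaterial.
* Funnel counts from real data depend on the upstream peak set, aligner
  choice for externally supplied SAM, and annotation versions; the
  package validates funnel *behaviour*, not any particular published
  count.
* The Wilcoxon normal approximation is used above effective n = 12 even
  though enumeration would still be feasible for a while; the cut-off is
  configurable (`exact_n_max`).
* `overlap_fraction()` and the repeat filter assume intervals on the one
  locus chromosome; multi-chromosome inputs are rejected, not partitioned.
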