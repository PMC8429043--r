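---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepreprog)
```

# Scope

`hepreprog` implements the computational stages used when human fibroblasts
are reprogrammed to induced hepatocytes (iHeps) and transformed into
liver-cancer-like cells: single-molecule methylation analysis of nanopore
methyltransferase-footprinting (NOMe-type) data, detection of lentiviral
transgene integration sites from long reads, negative-binomial differential
expression feeding gene-signature construction, ranked gene-set enrichment,
and single-cell QC with cell-cycle phase scoring. Every stage can be
exercised on synthetic data with known truth; the generators are first-class,
tested code, not throwaway fixtures.

# Dual-context methylation model

In a GpC methylase footprinting experiment, accessible chromatin is marked
enzymatically at GpC dinucleotides while endogenous methylation lives at CpG
dinucleotides. The two signals are separated by the trinucleotide context of
each cytosine, read 5'→3' on the strand carrying the cytosine:

* **GCH** (preceded by G, not followed by G) — enzymatic mark, chromatin
  accessibility;
* **HCG** (followed by G, not preceded by G) — endogenous CpG methylation;
* **GCG** — satisfies both patterns, ambiguous between the two sources, and
  therefore cataloged but excluded from both tracks;
* **HCH** — carries neither signal.

Sites are cataloged on both strands and contexts computed on the site's own
strand; GpC footprinting is strand-symmetric only at palindromic sites, so
strands are kept separate rather than merged. Coordinates are 0-based
half-open throughout, converted to 1-based only at the wiggle boundary. The
TSS window used by `promoter_profile()` is the one deliberate exception: it
is the inclusive interval `|pos − tss| ≤ flank` with `flank = 1500` bp,
matching the windows in which promoter accessibility is conventionally
summarized.

## Emission model and calling

`train_emission_model()` fits, per k-mer and label, a Gaussian to signal
events from two control runs of known state (a PCR-amplified, fully
unmethylated run; the same product treated with the GpC methylase, fully
methylated at GC). `score_site()` then accumulates per-event log-density
differences into a natural-log likelihood ratio — a per-site naive-Bayes
read-out, not a signal-space HMM with transitions. This is a deliberate
desk-scale simplification that preserves the learn-from-labeled-runs
structure of the full caller; it ignores event-to-reference alignment and
neighboring-site dependence. Defaults: k = 6 with the target cytosine at
offset 2 (typical pore context length), at least 20 events per (k-mer,
label), standard deviations floored at 1e-6 with a warning.

`call_methylation()` uses the conventional LLR cut of 2 nats, boundary
inclusive on both sides, with an ambiguous band in between; the cutoff is
configurable because upstream callers vary.

## Contaminant filter

Cell-free DNA entering the library after methylase treatment is methylated
along its entire length. A read is discarded when any window of exactly 80
consecutive GC-context calls (GCH and GCG, in read order) contains at least
`ceiling(0.75 × 80) = 60` methylated calls. Evaluating windows of exactly 80
makes the rule checkable and monotone: any longer qualifying stretch
contains a qualifying 80-window. Ambiguous calls are excluded from both the
window membership and the numerator — whether the original rule counted them
is not documented, and excluding them is the conservative reading (it never
manufactures a qualifying window out of weak evidence). Reads with fewer
than 80 GC calls are always kept. The filter acts only on read membership:
proportions computed from the surviving reads are unchanged by the filter's
presence, a property the test suite asserts.

## Aggregation and smoothing

Per-site proportions are `n_meth / (n_meth + n_unmeth)` over unambiguous
calls, reported only for sites covered by at least 4 such calls. Tracks are
smoothed with a triangular kernel 5 sites wide (weights 1,2,3,2,1),
renormalized over in-range sites at track edges so constants are preserved
and the output stays within the input's range.

# Insertion mapping

Reads carrying lentiviral sequence are found by local alignment against each
construct's backbone and insert. A read counts as genuine vector-derived
evidence only when it aligns to **both** backbone and insert for at least
30 bp each (boundary inclusive). Host-flank segments of dual reads are
aligned to the host genome; the host coordinate at the flank/construct
junction is the anchor; anchors within 50 bp cluster into events.

Two exclusions mirror how integration evidence is vetted: events supported
by a single read are rejected (`rejected_singleton`), and events falling in
the insert gene's own genomic locus are rejected (`rejected_native`) — the
inserts are cDNAs of host genes, so a read anchored at the native gene is
not integration evidence. Because breakpoints are resolved only to the
cluster radius, and a read genuinely integrating *inside* the native gene
anchors exactly at the gene boundary (its interior is indistinguishable from
insert sequence), the native interval is padded by the same 50 bp radius.
The cluster radius itself reflects long-read endpoint jitter; chance base
matches at a junction can extend an alignment a few bases past the true
breakpoint.

The aligner is a small seed-and-extend design: exact 11-mer seeds grouped by
diagonal, then exact ungapped local alignment along each seeded diagonal
(best-scoring segments under match +2 / mismatch −4). Gap parameters are
accepted for interface completeness but no gapped extension is performed:
the synthetic reads this package aligns are exact concatenations (sequencing
error models are out of scope), so gaps add nothing at this scale, and the
test suite cross-checks scores against a full Smith–Waterman implementation.
Orientation is recorded but not used for filtering.

# Differential expression and signatures

Counts are normalized with median-of-ratios size factors (geometric-mean
pseudo-reference). The two-group test is a compact NB Wald test: log2 fold
change from group means of normalized counts with pseudocount 0.5; gene-wise
dispersion by method of moments from the pooled within-group variance
(`var(q) = ξ·μ + α·μ²` with ξ the mean reciprocal size factor), floored at
1e-8; the standard error follows by the delta method; Benjamini–Hochberg
adjustment over tested genes. No dispersion or fold-change shrinkage across
genes is applied, and exact replication of a full empirical-Bayes DE
package's gene lists is explicitly not promised — the signature rules, not
the test internals, are the defined computation here.

One numerical choice deserves emphasis: the Wald statistic is referred to a
**t distribution with n₁ + n₂ − 2 degrees of freedom**, not a normal. With
triplicates the dispersion estimate carries only 4 residual degrees of
freedom, which makes a normal-reference Wald test markedly anti-conservative
(simulated type-I error ≈ 0.10–0.12 at nominal 0.05 across dispersions
0.01–0.2); the t reference restores calibration (≈ 0.03–0.05), in line with
small-sample practice in quasi-likelihood DE frameworks.

Signature rules follow the stated thresholds verbatim and strictly:
`baseMean > 50`, `FDR < 0.01`, `|log2FC| > 2`. "Top N" is operationalized as
adjusted p ascending, ties by |log2FC| descending, then gene identifier; the
ranking key is configurable (`rank_by = "lfc"`) because "top" is not further
specified in common usage. The hepatocyte signature intersects per-direction
top-500 lists of two primary-hepatocyte comparisons (intersection after the
per-direction cut); the HCC signature caps the up set at 500 but never caps
the down set; the consensus signature keeps genes supported in at least 3 of
5 studies per direction, with genes qualifying in both directions excluded
and reported.

# Ranked gene-set enrichment

Genes are ranked by `−log10(p) · sign(log2FC)`; zero p values are clipped to
the smallest positive double; the nominal (not adjusted) p feeds the metric
by default, configurable. The enrichment score is the classic weighted
Kolmogorov–Smirnov running-sum extremum (hit increments `|metric|^p`
normalized over hits, miss increments `1/(N − N_hits)`, weight p = 1).

The null is built by **gene-label permutation** at matched set size: with
three samples per group, phenotype permutation is degenerate, so gene
permutation is the only null with enough resolution. NES divides the
observed score by the mean |null score| of matching sign; the nominal p is
`(1 + #{same-sign nulls at least as extreme}) / (1 + #same-sign nulls)`,
which can never report zero; the FDR compares each NES to the pooled
sign-matched null NES distribution across sets. A degenerate null (no
same-sign null scores) floors p at `1/(n_perm + 1)` and flags the row.

# Single-cell QC and cell-cycle scoring

QC thresholds are per sample class and strict, exactly as worded: iHep-type
cells are excluded below 50,000 mapped reads, below 4000 detected genes, or
above 6% mitochondrial UMI fraction; HFL_CMT-type cells below 2500 genes or
above 10% mito, with no read threshold. Boundary cells (exactly 4000 genes,
exactly 6% mito) are kept. Genes must be detected in at least 5 cells; each
sample is down-sampled to 500 cells (seeded, without replacement; smaller
samples pass through whole); normalization is `ln(1 + 10^4 · x / total)`.

Phase scores average marker-gene expression per phase across the five phases
G1/S, S, G2/M, M, M/G1. "Averaged normalized expression" is ambiguous
between raw and standardized means; the default **z-scores each marker
across cells before averaging** so highly expressed markers do not dominate
the phase score, with `standardize = FALSE` available for the raw-mean
reading. Constant genes contribute z = 0. The assigned phase is the argmax
with ties resolved in the fixed phase order, so an all-constant matrix
deterministically yields G1/S. Mitochondrial genes are identified by a
configurable identifier-prefix list (`MT-` by default), keeping the module
annotation-agnostic.

# What the synthetic data emulates — and what it does not

The generators are pure functions of their arguments and a seed, and every
dataset ships with the truth needed to score the downstream stage:

* **Methylome/reads**: binary per-site truth with promoter-accessibility
  structure (GCH methylated with probability 0.9 inside promoters, 0.1
  outside; HCG at 0.7); per-site LLRs drawn from Normal(±effect, sd) around
  the truth, default effect 4, sd 1, coverage 20 — separations at which a
  real caller operates comfortably; contaminant reads synthesized by setting
  GC-site states methylated with probability 0.9, so the filter sees both
  boundary-passing and (rarely) boundary-failing windows. The 0.9 is a
  fixture parameter, not a claim about real contaminant methylation levels.
* **Bulk counts**: log-normal gene means, NB counts with gene-wise
  dispersion centered on 0.05 (typical of cell-line triplicates), library
  factors in [0.75, 1.33], planted |log2FC| = 3 in 10% of genes — the
  magnitude the signature thresholds are designed around.
* **Single-cell matrices**: five planted phases with 4-fold marker
  overexpression, ~2–3% baseline mitochondrial fraction, and 10% planted
  low-quality cells failing one QC rule each (thinned genes, boosted mito,
  or low mapped reads).
* **Insertion reads**: exact chimeric concatenations
  host-flank + backbone + insert + host-flank with ±20 bp flank jitter,
  native-locus reads (insert sequence, no backbone) and pure host
  background.

None of the generators model basecalling error, squiggle-level noise,
adapter artifacts, amplification bias, doublets, or ambient RNA. Passing
tests therefore demonstrate correctness of the *rules and statistics* on
data matching their stated assumptions, not robustness to every artifact of
real instruments.

# Validation problem sizes

The test suite validates at sizes chosen to make the statistical assertions
sharp while staying desk-scale: 6 kb genomes at coverage 20 over 10 seeds
for methylome recovery (mean absolute error of proportions < 0.05); 2,000
planted reads for the contaminant filter (sensitivity = specificity = 1 at
≥62/80 vs ≤40/80, with 60/80 vs 59/80 boundary cases); 5,000-gene null and
planted simulations for DE calibration and recovery; 200 random gene sets
for enrichment-p uniformity and 1,000 permutations for the planted-set
detection; 500-cell matrices for QC tallies and ≥90% phase recovery; and 20
seeded insertion datasets for perfect precision/recall. The shipped demo
pipeline (40 kb genome, 2,000 genes, 300 cells) completes end-to-end in
about half a minute on one CPU.

# Known limitations

* The emission model is per-site naive Bayes; it cannot capture
  neighboring-site signal dependence, and LLRs from real callers are better
  calibrated at high coverage than at the edges of long homopolymers.
* The DE test's method-of-moments dispersion is noisy at n = 3; the t
  reference fixes calibration but power trails empirical-Bayes machinery
  with information sharing across genes.
* The aligner is ungapped and exact-seeded; it is not suitable for raw
  error-prone long reads, only for the package's synthetic scale (real
  datasets would be aligned upstream with a production long-read aligner).
* Breakpoints are resolved to the cluster radius, not base-pair exact.
* Phase scoring assumes marker lists are informative in the analyzed cells;
  regression of phase scores against technical covariates is out of scope.
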