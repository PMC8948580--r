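---
title: "Methods: clonality, provenance and signature scoring for tissue Tregs"
author: "TregTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, provenance and signature scoring for tissue Tregs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TregTrace)
```

## Scope and model

Tissue Tregs — for example the regulatory T cells that accumulate in an
aneurysmal aorta — are characterized by three independent quantitative
readouts, and this package implements exactly those three, plus the
synthetic-data generators needed to test them without external data.

### Paired-chain clonotypes

A T cell's antigen receptor is defined by its rearranged TCRα and TCRβ
chains. Only cells with **both** a productive α and a productive β chain are
analyzed; a cell missing either chain cannot be assigned a paired receptor
and is dropped (counted in the filter report). Two cells are the same
clonotype iff their α components are equal **and** their β components are
equal.

The receptor-identity key is a configuration, because "the same sequence" is
ambiguous in practice:

- **sequence level**: CDR3 nucleotide (default) or amino acid. Nucleotide
  identity implies amino-acid identity, never the converse, so amino-acid
  keys can only merge nucleotide-level clonotypes — a property the test
  suite asserts.
- **V/J gene calls**: included by default (the 10x convention and the
  strictest interpretation, avoiding spurious merging of convergent CDR3s);
  excludable for cross-platform comparisons.

Cells with multiple productive contigs of one locus (doublets, secondary
α rearrangements, assembly artifacts) are resolved by keeping the dominant
chain: highest UMI count, ties by read count, then lexicographically by CDR3
nucleotide sequence so the result never depends on row order. The
alternative `drop-multi` policy removes such cells instead; dominant-chain is
the default because it retains cells while staying deterministic. Barcode
suffixes like `-1` are stripped, and sample identity always comes from a
declared sample label, never from the barcode.

### Clonality statistics

For clonotype sizes $x_1,\dots,x_n$ over $N$ cells:

- **Expansion ratio** $=\sum_{x_i\ge 2} x_i / N$. The threshold "two or more
  cells" is fixed, not configurable: it is the definition of an expanded
  clonotype, not a tuning knob.
- **Gini coefficient**, population (uncorrected) form
  $G=\sum_i\sum_j |x_i-x_j| / (2n^2\bar x)$, computed via the equivalent
  rank formula $G = 2\sum_i i\,x_{(i)}/(n\sum_i x_i) - (n+1)/n$ on the
  sorted sizes. $G=0$ for perfect evenness; the exact finite-$n$ upper
  bound is $(n-1)/n$, approached when a single clone dominates. No
  small-sample bias correction is applied — the uncorrected form is the one
  that matches the 0-to-1 description of the coefficient, and corrections
  change the comparison between samples of different clonotype counts.
- **Lorenz curve**: sizes sorted ascending (ties broken by key string so
  curves are bit-reproducible), cumulative proportions prepended with
  $(0,0)$. The trapezoid-area Gini from this curve equals the pairwise form
  to numerical precision ($<10^{-9}$), and the tests cross-check both
  against a literal double-loop oracle.
- **Overlap and sharing** are set algebra over distinct clonotype keys; both
  repertoires must carry the same key configuration, and a mismatch is an
  error rather than a silent miscomparison.

Statistics are computed per sample (per mouse) and aggregated as mean ± SEM
across samples; hypothesis testing between groups is out of scope.

One tempting invariant is false and deliberately not asserted: merging two
singleton clonotypes into one size-2 clone always raises the expansion
ratio, but it can *lower* the Gini (e.g. sizes $[5,1,1] \to [5,2]$ drop $G$
from 0.381 to 0.214), because the merge removes a clonotype and evens the
distribution. The test suite pins this counterexample.

### Parabiosis recruitment

In a parabiosis experiment two congenically marked mice share circulation;
the fraction of partner-derived cells ("chimerism") in blood sets the
ceiling for what recruitment from blood could deliver to a tissue. Per
mouse, recruitment $= 100\times$ tissue chimerism / blood chimerism. Three
numerical conventions matter and are fixed as follows:

- **Mean of ratios, not ratio of means.** The cohort mean is the unweighted
  arithmetic mean of per-mouse normalized values (a blood-chimerism-weighted
  mean is available behind a flag). A test asserts the two conventions on a
  cohort where they differ.
- **Rounding order.** Intermediates are carried at full precision; the
  recruited count is rounded half-up to the nearest cell *before* the final
  fraction-of-total, and display percentages are rounded half-up to one
  decimal. With cohort mean 78.6%, steady-state 20 and post-injury 5375
  cells this chain yields accumulated 5355, recruited 4209 and 78.3% of the
  total pool — reproducing each printed intermediate exactly; any other
  order does not.
- **Values above 100%** (tissue chimerism exceeding blood, possible under
  measurement noise) are returned unclipped with a warning: truncation
  would bias the cohort mean downward-asymmetrically.

Because a single headline "recruitment percentage" is ambiguous, the
estimate reports all three labeled quantities — the per-mouse mean, the
recruited share of the *accumulation*, and the recruited share of the
*total pool* — rather than choosing one. A percentile bootstrap CI over mice
(2000 draws, seeded) is offered as an extension.

### Photoconversion migration ratio

Cells photoconverted in one lymph node are tracked to other organs; the
fraction of converted cells in an organ divided by the fraction in a
nondraining lymph node (systemic-circulation reference) is the migration
ratio. Exactly one reference organ is required and its fraction must be
positive; the reference's own ratio is 1 by construction. No modeling of
photoconversion decay or blood-sharing kinetics is attempted.

### Signature concordance

A signature gene is concordant iff present and expressed in the DE table and
changed in the anticipated direction beyond `min_fold`. Two ambiguities are
surfaced as explicit configuration rather than hidden defaults:

- **Threshold**: the default `min_fold = 1` counts any strictly
  correct-direction change; the 2-fold volcano threshold is available and
  both can be reported side by side.
- **Denominator**: signature genes *present in the table* (default) or the
  *full signature* (absent genes then count against the score).

Gene matching is case-insensitive, with no ortholog mapping. DE estimation
itself (dispersion modeling, shrinkage, FDR) is consumed, never computed.

## Synthetic data: what it emulates, what it does not

Each generator is seeded independently and restores the caller's RNG state,
so adding one never shifts another's output; identical model + seed gives
byte-identical files (LF endings, fixed column order).

- `simulateRepertoire()` draws clone sizes from a symmetric Dirichlet
  (concentration → evenness), a power law (rank$^{-\gamma}$), or an explicit
  size list, then writes one productive TRA + TRB contig per cell in both
  the 10x CSV and AIRR TSV dialects. CDR3s are uniform-random sense codons
  of 30–48 nt (multiples of 3) between a fixed TGT…TTT (Cys…Phe) boundary;
  clonotype uniqueness is guaranteed by rejection sampling at the amino-acid
  CDR3-pair level, which implies uniqueness under every key configuration.
  Decoy cells exercise the filter: unpaired cells carry one chain,
  multi-chain cells an extra lower-UMI β contig. **Not** emulated: real
  V(D)J recombination statistics, sequencing error, UMI collisions, dual-TCR
  biology — so passing tests demonstrate the *arithmetic* on clean input,
  not robustness to assembly noise.
- `simulateParabiosis()` draws blood chimerism from a Gaussian truncated to
  (0, 100] and sets tissue chimerism $=$ blood $\times$ true fraction $+$
  Gaussian noise (floored at 0). Defaults mirror the worked experimental
  conditions: blood mean 35.7%, sd 5; tissue noise sd 5 percentage points;
  true recruitment fraction 0.786; counts 20 → 5375. The estimator is
  unbiased under this model since the noise is independent of blood
  chimerism; recovery is verified at n = 50 mice × 200 replicates (grand
  mean within one Monte-Carlo SE of the planted 60% in the fixed-seed test).
- `simulatePhotoconversion()` plants organ fractions as reference ×
  enrichment (defaults: reference 1% in the nondraining node, enrichments
  3× and 5× — realistic magnitudes for a draining node and an injured
  tissue); noise-free mode recovers enrichments exactly.
- `simulateDETable()` plants `round(fraction × n_signature)` concordant
  genes at ±effect (default 3 log2 units) with optional Gaussian noise;
  background genes center at 0. Noise-free mode recovers the planted
  fraction exactly (e.g. 0.74 → 74.0%).

## Numerical choices and degenerate inputs

- Empty repertoire: statistics raise an error rather than returning NaN;
  `callClonotypes()` on zero cells returns `NULL` as an explicit empty
  marker (a `Repertoire` with 0 cells is invalid by construction).
- All-zero or negative size vectors are rejected; zero-size entries are
  tolerated in the statistics (they arise in closed-form limits such as the
  $(n-1)/n$ bound) but never produced by the clonotype caller.
- Half-up rounding (`roundHalfUp()`) is used for all display values; base
  R's banker's rounding would turn e.g. 0.5-tied recruited counts
  irreproducible across platforms.
- JSON reports serialize at full precision; rounding appears only in
  explicitly labeled `display` fields.

## Problem sizes

The shipped tests run repertoires of 8–400 cells, 500 brute-force oracle
instances of ≤ 12 cells, 200 × 50-mouse parabiosis replicates and DE tables
of up to 2000 genes — sizes at which every oracle is exactly enumerable
while still exercising each code path; the full suite completes in well
under a minute on one CPU.

## Known limitations

- The package consumes annotated contigs; it does not assemble contigs or
  call V(D)J genes, and it ignores γδ T cells and B-cell receptors.
- Diversity indices beyond the Gini coefficient (Shannon, Simpson, Chao1)
  are not implemented.
- The canonical Treg signature gene list itself is not shipped — only the
  two-column format; published signatures differ between laboratories.
- Cross-sample clonotype identity is exact key equality; no allowance for
  sequencing errors within CDR3s.
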