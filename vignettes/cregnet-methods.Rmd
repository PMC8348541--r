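---
title: "Methods: cancer-specific enhancer regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cancer-specific enhancer regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregnet)
```

# Scope and model

cregnet implements an integrative desk analysis of regulatory change in
cancer genomes. Its inputs are the standard products of upstream
processing — per-sample H3K27ac peak files, HiChIP interaction loops
(BEDPE with a per-loop contact count), two TAD segmentations (BED), a
TSS annotation and a gene-by-sample expression table — and its outputs
are four linked results: a tissue-specific enhancer catalogue with super
enhancers, variant-enhancer-locus profiles and sample distances, a
six-category classification of TAD boundary changes, and a table of
enhancer target genes supported jointly by chromatin loops and
differential expression. Peak calling, loop calling and TAD calling are
deliberately out of scope: those tools' outputs are this package's
inputs.

All coordinates are 0-based, half-open (the BED convention), chromosome
names compare as exact strings (a `chrom_prefix` option normalizes
`"chr"` at read time), and "overlap" means at least one shared base
pair unless a function exposes `min_overlap_bp`. Every user-facing
function takes a data frame and returns a tibble, so stages compose
with the pipe; the interval engine underneath is
GenomicRanges/IRanges.

# Stage 1: tissue-specific enhancers

A tissue-specific enhancer is a distal H3K27ac peak region that is
reproducibly present in every target-class sample and absent from every
background-class sample:

1. per target sample, peaks overlapping any window of ±2.5 kb around an
   annotated TSS are removed (promoter H3K27ac marks transcription, not
   distal enhancer activity);
2. a peak is kept only when an overlapping peak exists in every target
   sample (`min_target_samples` relaxes unanimity to a vote — the
   default is unanimity because reproducibility across all tumor
   samples is the defining property of the catalogue);
3. survivors are merged across samples (`gap = 0`, so abutting
   half-open peaks join);
4. any merged region overlapping any background sample's peak — by even
   one base pair — is discarded. Background peaks are used raw, not
   TSS-filtered: a promoter peak in a normal sample is still evidence
   the region is active in normal tissue.

The result satisfies two properties that tests verify by brute force:
no reported enhancer shares a base pair with any background peak, and
enlarging the background set can only shrink the catalogue.

## Super enhancers

Super enhancers are called with the classic rank-ordering procedure:
enhancers within 12.5 kb are stitched into regions whose signal is the
sum of member scores (total stitched signal, not the mean, is what
separates large clusters from isolated peaks); regions are ranked by
ascending signal; rank and signal are each rescaled to [0, 1]; the
cutoff is the first rank position at which the discrete slope of the
scaled curve exceeds 1 — the point where signal starts growing faster
than rank. Regions above it are super enhancers. Score ties are broken
by (chromosome, start) so the cutoff is deterministic, and the flag
vector is invariant under any positive rescaling of the raw scores
(both axes are normalized). A flat curve has no inflection: all scores
equal yields zero super enhancers, reported as a degenerate case rather
than an error.

# Stage 2: density profiles, VELs and sample distances

The density matrix assigns cell (locus, sample) the sum of overlapping
peak scores, each weighted by the fraction of the peak's base pairs
inside the locus, then rescales every sample column to unit total.
Unit-total scaling was chosen because the inputs are arbitrary-unit
enrichment densities from libraries of different depth; a
counts-per-million-style `scale_factor` is exposed for users who prefer
that convention. Absent overlap is a true zero, not missing data.

Variant enhancer loci (VELs) are the `n` rows with the largest median
absolute deviation across samples — the loci that discriminate
tissues. MAD ties are broken by (chromosome, start); `n` is a free
parameter because the interplay between clustering and retention in the
motivating analyses is not specified beyond the retained count.

Sample distances are `1 − correlation` over VEL profiles: Pearson for
average-linkage hierarchical clustering (average linkage is the common
choice for correlation distances and is config-exposed), Spearman with
mid-rank ties as the input to embedding methods. A zero-variance sample
has undefined correlations; its off-diagonal distances are set to 1
with a warning rather than propagating `NaN`. The embedding itself
(e.g. t-SNE) is cosmetic and out of contract; only the distance matrix
is tested.

# Stage 3: loop annotation and span structure

A loop is labeled `specific_enhancer` when either anchor overlaps any
specific enhancer, else `nonspecific_enhancer` when either anchor
overlaps the non-specific enhancer set, else `other` — mutually
exclusive in that priority order. Loop span is the distance between
anchor midpoints (floored to integer bp): symmetric in the anchors and
insensitive to anchor width, which loop callers choose somewhat
arbitrarily. Inter-chromosomal loops are retained with undefined span
and excluded from span statistics.

Span distributions are compared between classes and against a seeded
uniform subsample of all loops (the "random loop" reference — the
randomization is a plain subsample because no more specific scheme is
implied by the comparison). Binned proportions use edges at 20 kb and
100 kb with log2-spaced bins above, and class pairs are tested with the
two-sample Kolmogorov–Smirnov statistic (Mann–Whitney as an option);
proportions are loop-weighted by default with the contact-weighted
variant left to the caller via `count`.

# Stage 4: TAD boundary changes

Two segmentations are matched per chromosome by a bipartite graph: an
edge joins a normal and a cancer domain when their overlap is at least
`min_overlap_frac` (default 0.1) of the shorter domain — the fraction
suppresses boundary-touching slivers from creating spurious edges.
Connected components partition all domains and classify as:

| component (normal, cancer) | category |
|---|---|
| (0, 1) | appear |
| (1, 0) | disappear |
| (≥2, 1) | fusion |
| (1, ≥2) | split |
| (1, 1), displacements ≤ `boundary_tol` | unchanged |
| (1, 1), otherwise | expand if cancer span ≥ normal span, else narrow |
| (≥2, ≥2) | complex |

`boundary_tol` defaults to 40 kb, about one Hi-C bin at the common
resolutions used for TAD calling. Equal-span shifted (1, 1) pairs fall
to expand by the span tie-break; there is no separate "shifted"
category. Many-to-many components are labeled `complex` and excluded
from the six-category fractions rather than force-fit.

Swapping the two inputs mirrors the labels (expand↔narrow,
fusion↔split, appear↔disappear) — a property tests assert on arbitrary
inputs. The summary reports per-category fractions of changed domains
and the fraction of each category whose footprint (cancer-side domains;
normal-side for disappearances) contains at least one specific
enhancer, where "contains" is ≥ 1 bp overlap, not full containment.
Because domain-level and boundary-level counting of "changed" differ,
the summary reports the domain-level changed fraction and, separately,
a boundary-turnover rate (fraction of condition-1 boundary positions
not reproduced within tolerance) without equating the two.

# Stage 5: differential expression and target genes

Differential expression is a per-gene two-sided Welch t-test on
`log2(x + 1)` with Benjamini–Hochberg adjustment across all genes; the
reported fold change is `(mean_cancer + 1) / (mean_normal + 1)` on the
abundance scale. The pseudocount stabilizes ratios for weakly expressed
genes; Welch avoids assuming equal variances between cohorts of
different sizes. The whole DE stage sits behind one function so a
count-model alternative can be swapped in. Genes that are all-zero in
both groups get fold change 1 and p 1. Significance is up when
`fold_change > 1.5` and `q < 0.01`, down for the reciprocal.

A loop supports gene *g* when one anchor overlaps a specific enhancer
and the other overlaps the promoter window `[tss − 2.5 kb, tss + 2.5 kb)`.
A gene is a target when the summed contact count over its supporting
loops is ≥ 5 — summed counts, not loop numbers, because the contact
count is the evidence strength; a loops-only mode is a one-line change
via `count = 1` — and the gene is significantly upregulated. The
long-range fraction is computed over all supporting loops of all
targets with the ≥ 20 kb threshold inclusive: a loop of exactly 20 kb
is long-range. Distances are loop spans (anchor midpoints), not
enhancer-to-TSS distances, so one definition of length serves the whole
package.

# The synthetic-data generator

Every stage is tested against seeded generators that plant ground
truth, because the analyses the package implements were originally run
on consortium-scale accessions that cannot be reproduced at desk scale.
The generator emulates the statistical structure of those inputs:

* **Peak landscapes** — a placement grid (30 kb pitch, jittered) over 4
  chromosomes of 100 Mb carries shared enhancers (in every sample),
  target-specific enhancers (target samples only) and background-only
  enhancers, with 7 target and 10 background samples mirroring a
  multi-cohort design. Peak widths and signal are log-normal; each
  sample re-draws scores and jitters boundaries by up to 200 bp so the
  any-overlap logic, not exact matching, is exercised. A planted
  fraction (5%) of specific enhancers get 50-fold heavy-tail signal —
  the planted super enhancers. Decoy peaks planted inside the ±2.5 kb
  window of decoy genes appear in every target sample and must be
  removed by the TSS filter, not the reproducibility filter. Enhancer
  placements keep ≥ 15 kb spacing, so 12.5 kb stitching is the identity
  on synthetic data — stitching itself is exercised by dedicated
  fixtures instead.
* **TAD pairs** — each chromosome is tiled with domain blocks (~400 kb
  domains, 200 kb inter-block gaps, well above the 40 kb tolerance) and
  each planted category is applied a configured number of times with
  120 kb boundary shifts (3× tolerance), so recovery is exact by
  construction and any classification error is a code defect.
* **Loops and expression** — wired loops connect a planted specific
  enhancer to a gene promoter. Spans follow a truncated Pareto on
  [10 kb, 2 Mb] whose exponent is solved numerically so that
  `P(span ≥ 20 kb)` equals the configured long-range probability (0.8
  by default); that same calibration leaves the median span below
  100 kb, matching the qualitative shape of enhancer–promoter loop
  length distributions (mostly short-range with a heavy long-range
  tail). Contact counts are negative binomial (overdispersed, as PET
  counts are); genes planted to pass the count filter draw counts
  conditioned ≥ 5, low-count decoys draw 1–4. Expression is log-normal
  with multiplicative log-normal noise at CV 0.3 and planted fold
  changes (drawn from 2–6) applied to the cancer group; cohort sizes
  default to 349 normal and 275 cancer samples. Planted-effect genes
  are kept at detectable abundance (≥ 5 TPM-like units) so the
  pseudocount fold change reflects the planted effect.

Decoy genes fail exactly one filter each — low contact count, fold
change 1, or upregulation without any loop — so target identification
is tested for precision and recall separately. Noise and
shared-enhancer loops avoid specific-enhancer anchors by construction,
which is what makes exact precision a fair expectation; on real data,
anchor coverage biases would blur this.

One global seed derives per-stage seeds (seed + 1, + 2, + 3), so stages
regenerate independently and byte-identically.

## What passing tests do and do not show

The generator plants clean, well-separated structure: enhancers far
apart relative to every window and stitch distance, TAD shifts far
above tolerance, planted effects far above noise. Passing tests
therefore demonstrate that the set operations, classification logic and
filters are implemented exactly — not that the pipeline is robust to
marginal real-data phenomena such as overlapping enhancer clusters,
sub-tolerance TAD drift, anchor-width artifacts, copy-number-driven
expression shifts or batch effects. The headline counts of the
motivating analyses depend on consortium inputs and upstream tool
versions and are not reproduction targets here.

# Numerical and degenerate-input choices

* Merging with `gap = 0` joins abutting half-open intervals; a shared
  boundary is not overlap for subtraction.
* The super-enhancer cutoff on an all-equal score curve is the region
  count (zero supers), logged as degenerate.
* Zero-signal density columns stay all-zero with a warning; zero
  changed TADs yield `NA` fractions, not zeros; an empty target set
  yields an `NA` long-range fraction.
* Welch degenerate cases: zero variance in both groups gives p = 1 for
  equal means and p = 0 otherwise.
* The random loop reference restores the caller's RNG state, and
  `n_random` above the loop count is capped with a warning.

# Problem sizes

The shipped tests run the full suite in about a minute on one core:
landscapes of 500 peaks per sample across up to 17 samples, 240 planted
TAD events over four 100 Mb chromosomes, a 2,000-loop span-calibration
run, and a 200-replicate null simulation (1,000 genes, 20 + 20 samples)
for FDR control. These sizes were chosen as the smallest at which each
property is sharp (binomial error on the long-range fraction ≈ 0.009;
mean null FDR estimated to three decimals).
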