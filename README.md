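# cregnet

Integrative analysis of **cancer-specific enhancer regulatory
networks** from H3K27ac ChIP-seq peaks, HiChIP interaction loops, Hi-C
TAD segmentations and expression data.

Tumor genomes activate enhancers that are silent in the matched normal
tissue. These cancer-specific enhancers rewire gene regulation through
chromatin loops and altered topologically associating domain (TAD)
structure, and the genes they contact are candidate drivers and drug
targets. cregnet turns that analysis — originally assembled from
one-off scripts around consortium datasets — into a tested, reusable
pipeline for anyone with per-sample peak files, a loop list, two TAD
segmentations and an expression matrix.

## What it computes

Given target (cancer) and background (normal) peak sets, the package
derives, stage by stage:

1. **Specific enhancers** — non-promoter peak regions present in every
   target sample (±2.5 kb TSS exclusion, unanimity across samples,
   merge, then removal of anything overlapping any background peak).
2. **Super enhancers** — 12.5 kb stitching, ranking by summed signal,
   both axes scaled to [0, 1]; regions above the first point where the
   curve's slope exceeds 1 are super enhancers (the ROSE rank-curve
   inflection rule).
3. **Enhancer profiles** — an overlap-fraction-weighted, depth-normalized
   signal matrix over enhancer loci; variant enhancer loci by largest
   median absolute deviation; `1 − Pearson` / `1 − Spearman` sample
   distances for clustering and embedding.
4. **Loop annotation** — each HiChIP loop labeled by whether an anchor
   touches a specific enhancer, with midpoint-to-midpoint span and
   Kolmogorov–Smirnov comparison of span distributions against a seeded
   random loop reference.
5. **TAD boundary changes** — bipartite overlap matching of the two
   segmentations, classified into six categories (expand, narrow,
   fusion, split, appear, disappear) plus unchanged and complex, with
   the fraction of each category containing a specific enhancer.
6. **Target genes** — genes whose promoter (±2.5 kb) is looped to a
   specific enhancer with summed contact counts ≥ 5 and that are
   significantly upregulated (Welch on log2(x+1), BH q < 0.01, fold
   change > 1.5), plus the fraction of supporting interactions that are
   long-range (≥ 20 kb).

A seeded synthetic-data generator (`sim_config()`,
`generate_landscape()`, `generate_tad_pair()`,
`generate_loops_and_expression()`) plants ground truth for every stage,
so the whole pipeline is testable end to end without downloads.

## Worked example

Everything runs on simulated data with planted truth:

```r
library(cregnet)

cfg  <- sim_config(seed = 7)
land <- generate_landscape(cfg)

spec <- call_specific_enhancers(land$peaks, land$targets,
                                land$backgrounds, land$tss)
head(spec, 3)
#> # A tibble: 3 × 4
#>   chrom    start      end score
#> 1 chr1   5492415  5493805  2.68
#> 2 chr1   6992674  6994231  3.29
#> 3 chr1  11821760 11823981  2.65
```

150 planted cancer-specific enhancers come back exactly; the `score` is
the mean per-sample summed H3K27ac signal. The rank curve flags the
planted heavy-tail regions:

```r
glance(stitch_and_rank_super_enhancers(spec))
#> # A tibble: 1 × 5
#>   n_regions n_super cutoff_index stitch_gap total_signal
#> 1       150       8          142      12500        1507.
```

TAD change classification recovers all 240 planted boundary changes and
reports which categories contain specific enhancers:

```r
tads <- generate_tad_pair(cfg)
ch   <- classify_tad_changes(tads$normal, tads$cancer)
summarize_tad_changes(ch, spec[, 1:3])
#> # A tibble: 8 × 4
#>   category      n fraction_of_changed enhancer_fraction
#> 1 unchanged    40              NA                 0.2
#> 2 expand       40               0.167             0.075
#> 3 narrow       40               0.167             0.175
#> 4 fusion       40               0.167             0.35
#> ...
```

Loop evidence plus differential expression yields the target table —
exactly the 50 genes wired to pass both filters, none of the 50
planted decoys:

```r
le <- generate_loops_and_expression(cfg, land)
de <- differential_expression(le$expression, le$groups)
tg <- identify_target_genes(le$loops, spec[, 1:3], land$tss, de)
head(dplyr::select(tg, -supporting_loops), 3)
#> # A tibble: 3 × 7
#>   gene_id   n_loops evidence_count max_span is_long_range fold_change   q_value
#> 1 gene_0026       1             16  1279158 TRUE                 4.76 2.24e-288
#> 2 gene_0037       1             13    68704 TRUE                 3.83 2.08e-252
#> 3 gene_0009       1             12    76690 TRUE                 4.41 4.43e-267
long_range_fraction(tg)
#> [1] 0.88
```

`evidence_count` is the summed contact count over a gene's supporting
loops; `is_long_range` marks genes with a supporting loop of ≥ 20 kb.
`run_pipeline(run_config(...))` chains all stages (simulate mode or
file inputs) and `inst/scripts/cregnet.R` wraps it for the shell;
`autoplot()` methods draw the rank curve, span distributions and TAD
category counts, and `tidy()`/`glance()` give broom-style summaries.

## Vignette

`vignettes/cregnet-methods.Rmd` documents the model behind each stage,
every tunable threshold with its default and rationale, what the
synthetic generator does and does not emulate, and the package's
numerical and degenerate-input choices.
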