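# chromex

Does spatial proximity of genes in the nucleus go along with their
co-expression? `chromex` implements a genome-scale analysis of that question
for intra-chromosomal gene pairs: it relates Hi-C chromatin contact
intensity to co-expression mutual ranks while controlling for shared
transcription-factor regulation and for linear genomic distance, and adds GO
functional similarity as a third axis. Because the original external
resources (Hi-C depositions, co-expression databases, TF-target catalogues)
are large and versioned, the package ships a fully seeded synthetic-data
generator with the same statistical structure, so every stage of the
pipeline is testable offline.

It is aimed at computational biologists who want a transparent, tested
reference implementation of the bespoke statistics involved rather than a
black-box pipeline.

## The statistics

For bins *i*, *j* of a per-chromosome contact matrix *O* (observed Hi-C
counts, "OH") at fixed resolution:

- **Expected by distance**: e(d) = mean of O[i, i+d] over the matrix
  diagonal at offset d; the **O/E matrix** is O[i,j] / e(|i−j|).
- **PC matrix**: Pearson correlation of O/E rows over mutually defined
  columns; an indicator of shared chromatin structure (compartments).
- **Gene-pair interaction**: for genes a, b with overlap-proportional bin
  weights w_a, w_b (weight of bin k = fraction of the gene body in bin k),
  the weighted average Σ_k Σ_l w_a[k] w_b[l] M[k,l] of OH or PC cells.
- **TCS** (transcription control similarity) of TF sets A, B:
  1 − |A △ B| / (|A| + |B|) — 1 for identical regulator sets, 0 for
  disjoint ones.
- **Normalized distance**: |midpoint(a) − midpoint(b)| / chromosome length.
- **Mutual rank** (MR): geometric mean of the reciprocal ranks of two genes'
  expression correlation in each other's ranked partner lists; smaller =
  more strongly co-expressed.
- **Wang GO similarity**: semantic contributions S_A(t) propagated through
  ancestor edges (is_a weight 0.8, part_of 0.6), combined between genes by
  best-match average (BMA).

The pipeline restricts to genes present in both the co-expression table and
the TF network, forms all intra-chromosomal pairs, keeps pairs whose OH
percentile ranks in the two cell types differ by < 5% (so the single
expression compendium is comparable across cell types), and then, within
strata (all pairs; normalized distance > 0.2; TCS = 0 / TCS ≠ 0; MR ≤ 50),
divides pairs into 20 equal-size groups by mutual rank — never splitting
tied x values, so groups can be empty — and tests the Pearson correlation of
the group means of interaction against mutual rank. The four panels
(OH/PC × two cell types) form one Bonferroni family: p < 0.05/4 = 0.0125 is
significant. A Welch t-test compares interaction between co-expressed pairs
(MR ≤ 50) and all remaining pairs.

Because smaller mutual rank means stronger co-expression, a positive
biological association appears as **negative** r.

## Worked example

```r
library(chromex)

cfg    <- sim_config(seed = 42, beta = 0.9)   # strong contact-coexpression coupling
bundle <- simulate_bundle(cfg)
tab    <- build_pair_table(bundle$ann, bundle$contacts, bundle$coexpr, bundle$net)
res    <- analyze_pair_table(tab)

str(res$counts)
#> List of 7
#>  $ genes            : int 272
#>  $ pairs_total      : int 18361
#>  $ pairs_all        : int 9283
#>  $ pairs_distant    : int 4264
#>  $ pairs_tcs_zero   : int 8066
#>  $ pairs_tcs_nonzero: int 1217
#>  $ pairs_coexpressed: int 3687
```

Of the 18,361 intra-chromosomal pairs among the 272 retained genes, 9,283
survive the cross-cell-type rank matching; 4,264 of those are
sequence-distant (normalized distance > 0.2) and 3,687 are co-expressed
(MR ≤ 50). The main panel:

```r
p <- res$strata$all$panels$oh_cellA
sprintf("r = %.3f, p = %.3g", p$r, p$p)
#> "r = -0.962, p = 1.37e-11"      # significant at 0.0125
```

Group-mean OH falls steeply with mutual rank — spatially proximal genes
co-express — and the effect survives in the distant stratum
(`res$strata$distant$panels$pc_cellB`: r = −0.885, p = 2.19e-07). The
co-expressed pairs also carry more raw contact:

```r
t <- res$ttests$oh_cellA
sprintf("t = %.1f, p = %.3g (means %.1f vs %.1f)",
        t$statistic, t$p, t$mean_coexpressed, t$mean_rest)
#> "t = 23.6, p = 3.67e-118 (means 89.1 vs 52.1)"
```

With `beta = 0` (the null world) the same code shows no systematic
significance — that calibration is asserted in the acceptance tests.

File-based runs use a JSON config (`?run_full_analysis`); a simulated bundle
writes one ready to use:

```sh
Rscript inst/cli/chromex simulate --seed 3 --beta 0.9 --out bundle/
Rscript inst/cli/chromex run --config bundle/analysis_config.json --out out/
```

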