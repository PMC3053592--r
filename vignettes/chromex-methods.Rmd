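---
title: "Methods: chromatin contacts, co-expression, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin contacts, co-expression, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Chromosomes fold so that loci far apart in sequence can be close in space,
and mechanisms such as transcription factories suggest that spatially
clustered genes are co-transcribed. `chromex` asks whether, genome-wide for
intra-chromosomal gene pairs, chromatin contact intensity (from Hi-C)
associates with gene co-expression once two confounders are controlled:
shared transcription-factor regulation, and plain linear proximity along the
chromosome.

The analysis works on gene pairs. Each pair carries:

* **OH** — the weighted average of observed Hi-C contact counts between the
  1 Mb bins the two gene bodies occupy, a proxy for spatial distance;
* **PC** — the same weighted average taken over the bin-bin Pearson
  correlation matrix of the observed/expected-normalized contacts, a proxy
  for shared chromatin structure (open/closed compartments);
* **MR** — the mutual rank of co-expression (geometric mean of reciprocal
  correlation ranks); *smaller* MR means *stronger* co-expression;
* **TCS** — transcription control similarity, `1 - |A xor B| / (|A| + |B|)`
  for TF sets A and B; undefined (and the pair excluded from TCS strata)
  when both sets are empty, since the expression is 0/0 there;
* **normalized distance** — distance between gene-body midpoints divided by
  chromosome length. Midpoints, not TSSs, anchor the distance: a TSS anchor
  would import strand dependence that no downstream statistic uses.

## Procedure and its assumptions

1. **Cohort.** Genes must appear in the co-expression table and as targets
   in the TF network. Gene identifiers are opaque strings assumed
   pre-unified across resources.
2. **Rank matching.** Co-expression compendia average over many tissues,
   while Hi-C is cell-type specific. Pairs are kept only when their OH
   percentile ranks in the two cell types differ by strictly less than 5%,
   so "contact" is a property the two assayed cell types agree on.
   Percentile ranks are computed genome-wide across all intra-chromosomal
   pairs within a cell type (not per chromosome), matching a single pooled
   threshold. OH at the coarse (1 Mb) resolution drives the matching; the
   measure is switchable (`rank_measure = "pc"`).
3. **Strata.** All matched pairs; sequence-distant pairs (normalized
   distance strictly > 0.2 — the figure convention; the measure-zero
   boundary makes the ≥/> distinction immaterial for continuous positions);
   TCS = 0 and TCS ≠ 0 (a coarse two-group control because most pairs share
   no TF); and co-expressed pairs (MR ≤ 50, the conventional network-building
   cut-off of the emulated co-expression resource).
4. **Binned correlation.** Within a stratum, pairs are sorted by mutual rank
   and divided into 20 groups of near-equal size. All samples sharing an x
   value land in one group (the group of the tie block's first sorted
   position), so heavily tied x values leave some group indices empty —
   deliberately reproduced, not papered over. Pearson correlation and its
   two-sided test are applied to the nonempty groups' (mean x, mean y)
   points; at least 3 nonempty groups are required. The test on *group
   means* (not raw pairs) is the design choice here; raw-pair correlation
   would be dominated by the enormous, heteroscedastic scatter. A Spearman
   option exists because the exact statistic applied to the group means is
   an open choice; Pearson is the default and is recorded in the metadata.
5. **Multiplicity.** The four panels (OH, PC × two cell types) of one figure
   form one Bonferroni family: per-test threshold 0.05 / 4 = 0.0125.
   Families are per figure, not global.
6. **Co-expressed vs all.** A Welch (unequal-variance) two-sided t-test
   compares the interaction measure between the MR ≤ 50 stratum and its
   complement. Welch because the groups are grossly unequal in size and
   variance; the complement (rather than the full table) because a
   two-sample test needs disjoint groups — this deviation from a literal
   "co-expressed vs all pairs" reading is recorded in the metadata.
7. **Direction.** Since small MR = strong co-expression, a positive
   biological association manifests as negative r of interaction against
   mutual rank.

GO functional similarity uses the Wang graph-based measure: semantic
contributions S_A(t) decay through ancestor edges with relation weights
(is_a 0.8, part_of 0.6 — the method's published constants, configurable),
term similarity is the shared-ancestor mass over the two semantic totals,
and gene-level similarity is the best-match average (BMA) of the term
matrix. BMA is the default combine rule of the reference implementation of
this measure; the choice is recorded in output metadata. Only the
biological-process namespace is accepted at load.

## Numerical choices

* O/E cells on offsets whose expected value is zero become missing, not
  zero: a zero expectation means no information, and a 0 would masquerade as
  depletion.
* PC entries need ≥ 3 shared defined columns and nonzero variance; below
  that they are missing. Missing values exclude a pair from the affected
  panel only, never from the table.
* Gene-pair interaction over cells with missing values renormalizes the
  weights over the defined cells; all-missing gives missing.
* Percentile ranks average ties and divide by the number of non-missing
  values, giving values in (0, 1].
* Rank matching uses strict inequality (`< 0.05`), as does the distant
  stratum (`> 0.2`); the co-expressed stratum is inclusive (`<= 50`).
* Ties in equal-size binning are resolved toward the group of the first
  sorted position of the tie block; with all-distinct x, group sizes differ
  by at most 1.

## The synthetic world

The generator replaces four external resources with one coherent generative
model, fixed once:

* **Genome**: 2 chromosomes × 30 Mb at 1 Mb bins; 300 genes with log-uniform
  lengths in [5 kb, 200 kb], placed uniformly without overlap (sorted
  uniform gaps plus cumulative lengths — exact, no rejection loop).
* **Compartments**: 6 contiguous segments per chromosome, each labelled
  open/closed at random — a block stand-in for A/B compartments that gives
  the PC matrix its plaid structure without implementing eigenvector
  compartment calling. A second cell type keeps each segment's label with
  probability `shared_fraction` (default 1).
* **Contacts**: Poisson counts with mean
  `100 * (1 + d)^(-1) * kappa^[same label]`, `kappa = 3`. The power-law
  exponent 1 is the canonical intra-chromosomal decay; 100 counts at the
  diagonal gives realistic signal-to-noise for 1 Mb bins; `kappa = 3` is at
  the strong end of observed compartment enrichment, chosen so the block
  structure is unambiguous at this small matrix size. Poisson noise is the
  simplest generative model consistent with count data.
* **Expression**: gene g's profile is
  `sqrt(beta) * f[compartment of g] + sqrt(1 - beta) * sigma * noise` over
  60 conditions, one standard-normal factor per (chromosome, label). The
  expected correlation of same-compartment genes is
  `beta / (beta + (1 - beta) sigma^2)` = `beta` at the default `sigma = 1`;
  unrelated genes are uncorrelated. `beta = 0` defines the null regime;
  `beta = 0.9` is the documented strong-coupling preset. Mutual ranks are
  rebuilt from these profiles exactly as the emulated co-expression resource
  defines them (double ranking, geometric mean).
* **TF network**: 40 TFs with out-degree `max(1, Poisson(17))` — 17 being
  the edge/TF ratio of the emulated TF catalogue — and uniformly random
  targets; an optional `tf_block_bias` concentrates a TF's targets in one
  compartment.
* **GO**: a rooted tree (depth 4, branching 3) with 20% of edges relabelled
  part_of; genes get 1–3 random leaves, and with probability `gamma` a gene
  adopts its compartment's canonical leaf (the first annotated gene's first
  leaf), so same-compartment pairs share a term with probability about
  `gamma^2`. `gamma = 0` is the functional null.

Every component seeds the RNG from the configuration seed plus a fixed
per-component offset, so individual artifacts and whole bundles are
byte-reproducible.

**What a green test does and does not establish.** The generator reproduces
the *statistical couplings* the analysis is designed to detect — distance
decay, compartment blocks, contact-coupled co-expression, proximity-coupled
function — but none of the artifacts of real data: restriction-fragment and
mappability bias, translocations in cancer lines, realistic GO topology and
annotation depth, TF motif structure, or expression compendia heterogeneity.
Passing recovery tests shows the pipeline detects the modelled effect at the
stated strength and respects its null; it does not validate conclusions
about any real genome.

## Scope and known limitations

* Intra-chromosomal pairs only; inter-chromosomal contacts are far sparser
  and are out of scope by design.
* No iterative matrix balancing (ICE/KR), TAD calling, or eigenvector
  compartment analysis — the statistics here predate and do not require
  them.
* The published headline counts and p-values of the motivating study depend
  on frozen external snapshots and are intentionally not reproduced; the
  in-package constants verified exactly are the methodological ones (the
  0.0125 Bonferroni threshold, the MR ≤ 50 boundary, the 5% and 0.2
  cut-offs, the 20-group design).
* The file config is JSON rather than YAML: the deployment environment
  pins the available R stack, which has no YAML parser, and JSON carries
  the identical structure.
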