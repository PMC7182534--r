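---
title: "Tile-based differential methylation and locus-set depletion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based differential methylation and locus-set depletion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtiler)
```

methtiler answers a locus-set question about whole-genome bisulfite
sequencing (WGBS) methylomes: when one condition (here, EBV-transformed B
cells, "LCLs") loses methylation across large genomic blocks relative to a
reference condition (activated or resting B cells), is a given set of loci
— disease-risk SNPs, eQTLs, MHC variants — over- or under-represented in
the changed regions? This vignette documents the model and procedure, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## The procedure

**Units of analysis.** The genome is cut into fixed-width tiles (default
1 kb, the scale over which CpG methylation is locally correlated). Two
tile families exist: the genome-wide grid (`make_grid_tiles()`, tiles
`[0, w)`, `[w, 2w)`, ... with a truncated terminal tile), and SNP-centred
windows (`make_snp_tiles()`, `[p - w/2, p + w/2)` clipped at chromosome
bounds). For even `w` the centre base is the first base of the right half
— a half-open-symmetry choice the source material leaves unspecified.
Overlapping SNP windows are deliberately *not* merged: each locus is its
own unit, so locus-set DMR counts have the locus list as denominator.

**Regional methylation.** Per tile, methylation is total methylated reads
over total reads across the symmetric CpGs anchored inside it:
coverage-weighted, so a 2x-covered CpG cannot swamp a 40x one. Inputs are
symmetric-merged sites: a `+` CpG at `p` and its `-` partner at `p + 1`
are one dyad, pooled by coverage (`merge_symmetric()`), after biological
replicates have been pooled the same way (`merge_replicates()`). An
unweighted per-CpG mean is available (`weighted = FALSE`) because the
regional-statistics tools this format comes from can be run either way
and the weighted reading is our default interpretation.

**Tiles with data.** A tile enters a comparison only if it has at least
one covered CpG in *both* conditions. This both-condition rule is a design
decision: a methylation difference does not exist otherwise, and the
"tiles with data" count is the denominator of every reported percentage,
so the rule is applied once, centrally, in `call_dmrs()`. Tiles lacking
data are counted and reported, never silently dropped.

**DMR calls.** A tile is a differentially methylated region when the
absolute difference of its two regional methylation values exceeds 0.2 —
a pure threshold on means, strict at the boundary (a delta of exactly 0.2
is not a DMR). There is deliberately no smoothing and no beta-binomial
test: the method under study is a threshold caller, and the package
reproduces it faithfully rather than improving it. The sign convention is
`delta = reference - test`, so hypomethylation in the test condition is
positive. Reported percentages are rounded half-up to two decimals, the
convention of the tables this output mirrors; note that half-up differs
from R's `round()`.

**Depletion test.** Whether a locus set has fewer DMRs than chance is
decided by resampling: each of `n_resample_draws` (default 100) draws
samples `n_query` tiles *without replacement* from the background
catalogue's tiles-with-data and counts DMRs. Without replacement because a
draw stands for a pseudo locus set, and a locus set contains distinct
loci. The empirical p-value uses the add-one estimator
`(1 + #{draws <= observed}) / (1 + n_draws)`, which can never report 0
from finitely many draws. The test is one-sided (lower tail) by default —
the scientific claim is underrepresentation — with an upper-tail mode for
completeness. For discrete draw distributions the estimator is
conservative (sub-uniform under the null), which the calibration test
accounts for. `binomial_lower_tail()` is provided for back-of-envelope
threshold arguments; it sums exact terms in log space rather than relying
on normal approximations.

**Annotation.** Loci (or tile midpoints — the midpoint convention is used
for proximal-gene lookup, and extended to class assignment for
consistency) receive exactly one class with precedence
promoter > exon > intron > intergenic. Precedence is a package decision:
the classes overlap in any real gene model and the source material states
no tie rule; promoters win because they are the regulatory class whose
behaviour the analysis singles out. The order is configurable. Intervals
are merged within each class before assignment, making results
independent of how input intervals were split or ordered. Closest-gene
distance is the bp gap (0 on overlap, 1 when bookended — the bedtools
convention), with exact ties broken by a seeded uniform choice so reruns
are identical. Class-distribution comparisons use the Pearson chi-square
without continuity correction (df = k − 1 for a 2 × k table); Fisher's
exact test for tables wider than 2 × 2 runs as seeded Monte-Carlo
resampling with margins fixed (default 1e5 tables), trading exactness for
bounded memory and reproducibility.

**Expression integration.** Genes split at |log2 FC| > 1 (strict) into
high/low differential-expression classes; "one log-fold" is read as log2,
the RNA-seq convention. Per annotation interval, the methylation
difference is paired with the proximal gene's logFC; the association is
summarised as a Pearson correlation per class (Spearman available) and as
DMR rates by expression class with a chi-square test. Positive logFC
means higher expression in the test condition.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tile_width` | 1000 | bp | methylation is locally correlated at this scale |
| `dmr_threshold` | 0.2 | methylation fraction | the threshold the caller is defined by; strict `>` |
| `logfc_threshold` | 1 | log2 units | "single log-fold" split; strict `>` |
| `n_resample_draws` | 100 | draws | the study's resampling depth; raise for finer p resolution |
| `rng_seed` | 1 | — | every randomized step derives its stream from this |

Excluded chromosomes default to `{chrX, chrY, chrM}` — sex, mitochondrial
and haploid sequence have different effective ploidy and are left out of
diploid methylation comparisons. Chromosome names are matched exactly;
`normalize_chroms()` performs explicit `chr`-prefix harmonization, and
nothing renames silently, because silent renaming is how cross-file
mismatches go unnoticed.

## The synthetic-data generator

`generate_methylomes()` and its companions produce complete, truth-tagged
inputs so that every stage can be tested against known answers:

- **Baseline methylome.** Symmetric CpG positions with exponential
  spacing (mean 100 bp); per-CpG true methylation drawn from
  Beta(8.5, 1.5), mean 0.85 — matching the highly methylated baseline of
  activated B cells.
- **Planted blocks.** Non-overlapping 20-kb blocks totalling a genome
  fraction `f` (apportioned across chromosomes by largest remainder so
  per-chromosome rounding cannot distort `f`); inside blocks the *test*
  condition's true methylation drops by `d`, floored at 0. Blocks are
  condition-asymmetric — only the test condition shifts — because
  observed hypermethylation is negligible in this system (~0.07% of
  tiles).
- **Observation model.** Coverage is Poisson with mean
  `coverage_lambda / (2 * n_replicates)` per strand per replicate
  (defaults: 6x total across 3 replicates, the shallow regime of the
  motivating data at ~5.7x); methylated reads are Binomial in the true
  methylation. Beta baseline + Binomial reads gives realistically noisy
  tile means at low coverage. Data are emitted strand-split so the
  reader-side symmetric merge is genuinely exercised.
- **Locus sets.** Background loci are uniform; the "depleted" set accepts
  in-block proposals with probability `rho`, so its expected in-block
  fraction is `rho*f / (rho*f + 1 - f)`; `rho = 1` reproduces the
  background law and is the calibration null.
- **Genes and expression.** A deterministic layout (1-kb promoter aligned
  to the tile grid, four 500-bp exons alternating with 2-kb introns,
  genes every `gene_spacing` bp) shared between the methylome and
  annotation generators — it must be, because promoters are exempt from
  the block shift, mirroring the observed resistance of promoter
  methylation to transformation. Gene logFC is
  `expr_slope * delta_true + N(0, expr_noise)` where `delta_true` is
  `d` times the fraction of the gene body in blocks; promoters then carry
  no methylation signal, so their correlation with expression is null by
  construction while exons/introns correlate positively.

Two presets bundle the study conditions: `"paperlike"` (`f = 0.46`,
`d = 0.25`, 6x) reproduces the shallow, noisy regime; `"crisp"`
(`d = 0.4`, 20x) is the high-signal regime used by the deterministic
recovery tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artefacts (bisulfite conversion
failure, mapping bias, PCR duplicates — generation starts at the
methylation-call level), CpG islands and other non-uniform CpG spacing,
chromosome-scale covariates, graded block boundaries (planted blocks are
sharp), between-replicate biological variance (replicates differ only by
sampling noise), and any dependence structure between neighbouring tiles
beyond shared blocks.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open end to end; conversion to the 1-based
  interval containers used internally happens at one boundary.
- Zero-coverage CpGs are retained by readers (they mark
  assayed-but-uncovered positions) but stored with missing methylation
  and contribute zero weight everywhere; a `drop_uncovered` flag discards
  them at read time for users who prefer the other convention.
- A tile, class or locus set with no data reports missing summaries
  (`NA`), never 0 — an empty percentage is not a zero percentage.
- `binomial_lower_tail()` sums log-space terms with a max-shift, exact to
  ~1e-12 against enumeration for n ≤ 30.
- Every reported percentage is recomputable from the reported counts; the
  pipeline tests assert this self-consistency for all emitted summaries.
  Applied to published genome-wide counts for the resting-B-cell
  comparison, the arithmetic gives 49.88% where 49.93% was printed; the
  package reports the value its own counts imply.
- Chi-square statistics come from `stats::chisq.test(correct = FALSE)`
  and are verified against the textbook formula to 1e-9 in the test
  suite; Monte-Carlo Fisher p-values come from seeded
  `stats::fisher.test(simulate.p.value = TRUE)`.

## Problem sizes used in tests

The recovery and calibration suites run on 1-Mb two-chromosome genomes
(1,000 grid tiles, ~10,000 CpGs) at the `"crisp"` preset: large enough
that the genome-wide DMR fraction estimates the planted `f = 0.46` within
±3 percentage points and the promoter class stays under a 2% DMR rate,
small enough for a fast deterministic suite. Null calibration uses 200
simulated query sets of 50 tiles against a 2,000-tile background with 100
draws each; the exact-oracle check compares 100,000 resampling draws on a
20-tile background against the enumerated hypergeometric lower tail.

## Known limitations

- The DMR caller is the thresholded-difference method it sets out to
  reproduce; it has no error control and is sensitive to coverage through
  the noise in tile means. Use the synthetic presets to gauge the
  false-positive rate at your depth before interpreting small locus sets.
- The depletion p-value's resolution is bounded by `1 / (1 + n_draws)`;
  at the default 100 draws, `p = 0.0099` is the floor.
- `assign_annotation()` assigns by point (locus or midpoint), not by tile
  overlap fraction; a tile straddling a class boundary is represented by
  its midpoint alone.
- Monte-Carlo Fisher p-values carry simulation error of order
  `1/sqrt(n_tables)`; raise `n_tables` when p sits near a decision
  boundary.
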