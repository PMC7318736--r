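---
title: "Genetic dissection of CSSL populations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic dissection of CSSL populations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssltools)
```

## The problem

A chromosome segment substitution line (CSSL) carries one or a few donor
genome segments in an otherwise recurrent-parent background. In interspecific
cotton panels the donor is *Gossypium barbadense* (Sea-island cotton, superior
fiber) and the recipient *G. hirsutum* (Upland cotton, high yield). Dissecting
such a panel means answering four questions: where exactly are the donor
segments in each line; how much of the donor genome does the panel cover;
which segments move which traits (QTL); and how do the per-trait effects
combine into an overall judgement of a genomic region's value. `cssltools`
implements the full chain for two kinds of evidence — sparse SSR marker
graphical genotypes (the "MM map") and dense re-sequencing SNPs (the "GR
map") — plus a synthetic population generator so that every stage can be
tested against known truth.

## Segment reconstruction from SSR graphical genotypes

Marker calls are `DD` (homozygous donor), `DR` (heterozygous), `RR`
(homozygous recipient) or missing. `call_marker_segments()` applies the
100/50/0 rule: the span between the outermost `DD` markers of a run counts
fully as donor; each flank between that core and the nearest `RR` marker
counts at half its span, because the true breakpoint is uniformly
unidentifiable inside it; `RR`-to-`RR` stretches count zero. A run with only
`DR` calls is reported heterozygous, with the outermost `DR` markers as core.

Two conventions the rule itself does not fix:

* **Chromosome ends.** A run touching a chromosome end has no outer `RR`
  anchor; the segment is extended fully to the end. The symmetric alternative
  (half the distance) systematically shortens terminal segments that marker
  data cannot bound; full extension errs on the side of the same estimator
  used in the interior core.
* **Missing calls are transparent.** They never break a run; continuity is
  the conservative reading and the affected spans are visible in the output
  (`n_dd`, `n_dr` against the marker count).

The estimator's error is bounded by half a marker interval per flank, which is
why the test suite asserts recovery within one (local) marker interval on
simulated lines with 2 cM spacing.

## Segment reconstruction from SNPs: the sliding-window bin map

`call_windows()` slides a 50 kb window in 5 kb steps along each chromosome of
each line. Within a window, SNP calls coded against the parents are counted
and the window is called homozygous-donor (or homozygous-recipient) when more
than 80% of its informative SNPs carry that parent's genotype, heterozygous
otherwise, and `NA` when fewer than `min_snps` (default 5) informative SNPs
are present.

**Denominator of the 80% rule.** The fraction is computed over *all*
informative (non-missing) calls; heterozygous calls count toward the
denominator but toward neither parent. The alternative — a fraction over
homozygous calls only — is unstable exactly where it matters: inside a truly
heterozygous region nearly every call is heterozygous, so the handful of
error-induced homozygous calls would dominate the ratio and flip windows to
spurious homozygous states. With the all-informative denominator a
heterozygous region stays heterozygous under realistic error rates (a 1%
miscall rate contributes about 0.5% donor and 0.5% recipient calls).

`windows_to_bins()` collapses maximal runs of equal window calls into bins.
The breakpoint between two runs is placed at the midpoint of the overlap
between the last window of the left run and the first window of the right run
(`start_left + (step + window)/2`) — the symmetric choice; any point inside
the overlap is equally supported by the data. Bins therefore tile each
chromosome exactly, which the tests assert.

`merge_and_filter()` applies the clean-up rules in a fixed order: (1) two
bins of the same called genotype separated by less than 100 kb of other
called genotype are fused, the gap absorbed (iterated to a fixed point); (2)
called bins shorter than 100 kb are set to `NA` ("not available"); (3)
adjacent equal-genotype bins are re-fused. `NA` regions created by step (2)
are never re-absorbed by step (1); that ordering makes the operation
idempotent, which is also under test. Donor-homozygous and heterozygous bins
become introgression segments; recipient and `NA` bins do not, so lines whose
donor material is entirely below the 100 kb floor yield no segments — the
behaviour real panels show for lines whose introgressions are too small for
the bin map.

**Resolution.** Transition windows containing 20–80% donor material are
called heterozygous and, being shorter than 100 kb, are filtered; each
segment boundary is therefore resolved only to within about one window
(50 kb). Consequently summed segment lengths (and the fold-coverage ratio)
can deviate from the planted truth by up to two windows per segment — the
tests bound the deviation accordingly rather than asserting exact equality.

## Coverage statistics

`union_coverage()` reports, per chromosome, subgenome and genome, the union
over lines of donor intervals divided by the map length, as a percentage
rounded half-up to two decimals (the convention of published map-comparison
tables; base R's `round()` is round-half-even and reproduces published
percentages less often). Aggregate rows sum lengths before dividing.
`fold_coverage()` counts overlaps multiply: total donor material carried by
the population in genome-equivalents. `density_stats()` reports cM/marker and
SNPs/kb at one decimal. Heterozygous segments count at full length in the
SNP-map coverage; in the marker map the flank halving of the estimator
already discounts ambiguous spans.

## Block partition and the QTL scan

`partition_blocks()` cuts the genome at every segment boundary, computes each
line's donor dosage (0, 0.5, 1) on each atomic interval, merges adjacent
intervals with identical dosage vectors and drops intervals carried by no
line. Blocks are the natural testing unit in a CSSL panel: within a block,
dosage is constant along the interval for every line, so no finer mapping
resolution exists in the data. The sum of block lengths equals the union
coverage length (tested).

`scan_qtl()` is an additive-only stepwise likelihood-ratio scan. Per trait:

1. forward–backward stepwise regression of line values (BLUPs) on block
   dosages selects background cofactors (entry p ≤ 0.05, removal p ≥ 0.10 —
   conventional stepwise defaults, exposed as `p_in`/`p_out` since the
   reference implementations do not print theirs);
2. each block `b` is tested by comparing the reduced model (cofactors minus
   `b`) against the full model (plus `b`):
   `LOD = (n/2) log10(RSS_reduced / RSS_full)`, which is monotonically
   related to the 1-df F statistic (the tests assert the mapping exactly);
3. the regressor is `2x`, so the fitted coefficient is the additive effect
   `a` — half the difference between donor-homozygous and recipient classes,
   with the heterozygous class midway (additive model);
   `PVE = 100 (RSS_reduced − RSS_full) / TSS`.

Numerical guards: blocks with constant dosage among phenotyped lines are
skipped with a warning; collinear blocks are dropped from the cofactor pool
(the later one, logged) but still tested individually; a numerically zero
residual (separable case) reports the cap `LOD = 50` rather than infinity.
The default reporting threshold is LOD ≥ 2.5. Positive `a` means the donor
allele raises the trait; `sign_flip = TRUE` reports the opposite orientation,
since published colour conventions for effect direction are ambiguous.

## Phenotype statistics

`fit_blup()` fits `value ~ env + (1 | line)` by REML (via `lme4`):
environments fixed, lines random, replicates pooled into the residual. Broad-
sense heritability is reported on the line-mean basis,
`H² = σ²_g / (σ²_g + σ²_e / n_env)` — the across-environment repeatability
appropriate when downstream analysis uses line means/BLUPs; the plot basis
(`σ²_e` undivided) is a switch. Traits observed in a single environment get
`H² = NA` with a warning (variance components are not separable there). On
balanced data the REML fit coincides with the closed-form ANOVA estimator
`σ̂²_g = (MS_line − MS_error)/n_env`, which the tests use as an independent
oracle. `trait_correlations()` is plain pairwise Pearson over line BLUPs with
two-tailed p-values and the usual `*`/`**` flags.

`compute_waf()` forms, per block, the weighted mean of per-trait additive
effects with weights `r_t·H²_t`, where `r_t` is the trait's correlation with
the anchor trait. Only traits positively correlated with the anchor enter
(negatively correlated traits are excluded, not sign-flipped: flipping would
require deciding which direction of every trait is "good", a judgement the
statistic deliberately leaves out). Per block, the mean runs over the traits
with an effect estimate there; blocks with none are `NA`. As a weighted mean,
WAF is bounded by the contributing effects, scale-equivariant in them and
invariant to rescaling all weights — all property-tested.

## The synthetic population generator

`simulate_population()` plants segments directly rather than simulating the
multi-generation backcrossing that produced real panels; what it emulates is
the *statistical structure* the pipeline assumes:

* per line, 1–10 donor segments (uniform), homozygous or heterozygous
  (`het_fraction`, default 5%), with lengths log-uniform between 0.5 and 5 Mb
  at the scaled-down default genome — log-uniform because observed
  introgression lengths span three orders of magnitude (tens of kb to over
  100 Mb at full scale);
* a minimum separation (`segment_gap`, default 2 Mb) between segments of one
  line on a chromosome: independent introgressions derive from distinct
  recombination events, and two planted segments closer than a marker
  interval or the 100 kb merge distance would be unidentifiable from one by
  any method, making "truth" ill-defined for recovery tests;
* SNPs at ~5/kb (Poisson counts, uniform positions), SSR markers on a
  jittered grid; genotyping error replaces a call by one of the other two
  states uniformly (default 1%), missingness masks calls (default 5%); both
  corruptions apply identically to SNPs and markers;
* phenotypes under `y_ij = μ + env_j + Σ_b 2 a_b x_ib + g_i + e_ij` with
  fixed environment offsets, a polygenic line effect `g_i ~ N(0, σ²_g)` and
  residual `e_ij ~ N(0, σ²_e)`.

It does **not** emulate: linkage-informed segment placement or segregation
distortion, allele-frequency structure within parents (parents are fully
inbred and fully informative), read-depth-dependent genotyping error,
correlated/multivariate trait architectures, QTL-by-environment interaction,
or epistasis. Passing tests therefore demonstrate correctness of the
*procedures* under the stated noise model, not performance on any particular
real data set.

All randomness derives from a single integer seed; identical seeds give
byte-identical outputs.

## Problem sizes used by the test and acceptance suites

The suites run populations of 50 lines on two 20 Mb chromosomes at 5 SNPs/kb
(1% error, 5% missing) for segment recovery across 20 seeds; 100 lines with
2 cM markers for the SSR estimator; 500 null replicates and 100 planted-QTL
seeds at n = 300 lines for the scan's type-I rate, power and effect accuracy;
and 50 seeds of 300 lines x 5 environments for heritability recovery
(closed-form target `3/(3 + 1/5) = 0.9375`). These sizes give stable Monte
Carlo estimates for the assertions made while keeping a full run in the low
minutes on one core. The published full-scale table arithmetic (coverage
rates, marker spacing, SNP density) is recomputed exactly from the bundled
per-chromosome input table. The published correlation, QTL and heritability
*values* themselves are not reproducible without the original study's
supplementary genotype and phenotype files and are deliberately out of scope;
the property suites above stand in for them.

## Known limitations

* The bin caller's boundary resolution is one window; narrow true segments
  (< 100 kb) are invisible by design, matching the published filtering rule.
* The stepwise cofactor search is greedy; with strongly correlated blocks the
  selected background can differ between near-equivalent models (the
  per-block test is always run against the selected set minus the tested
  block, so reported LODs remain well-defined).
* `fit_blup()` treats environments as fixed and ignores replicate structure
  beyond pooling it into the residual; with strong genotype-by-environment
  interaction, H² on the line-mean basis is an upper summary, not a variance
  decomposition.
* Marker-map and SNP-map segment calls are reconciled only through their
  shared coverage statistics; no joint estimator is attempted.
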