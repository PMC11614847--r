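---
title: "Integrated differential expression with p-value combination: models and design"
author: "fuseDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated differential expression with p-value combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given a raw count matrix (genes x samples) and a two-level condition, which
genes are differentially expressed? The mature answers to that question —
exact negative-binomial (NB) tests, precision-weighted moderated t
statistics, NB generalized linear models with shrunken dispersions,
variance-component score tests — rest on different distributional
assumptions and disagree most exactly where the data are weakest: small
cohorts with three or so replicates per condition, the typical in vitro
experiment. fuseDE runs four such engines on one matrix and then *fuses*
their per-gene p-values with classical combination statistics, so that
concordant weak evidence across statistically distinct models can rise to
significance even when no single model gets there alone.

This vignette documents the statistical model of each component, the
tunable parameters and their defaults, what the bundled simulator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

# Data model

A `DEExperiment` extends `SummarizedExperiment`: one `counts` assay of
nonnegative integers with unique gene and sample identifiers, and a
two-level `condition` factor in `colData` with at least two samples per
level. The **second** factor level is always the test class: its mean goes
in the numerator of every log2 fold change. This convention is arbitrary
but must be fixed somewhere; it is enforced by the constructor rather than
inferred, so a contrast `c("ctrl", "treated")` always reports
treated-over-ctrl. Extra covariate columns are carried but ignored — the
engines model the two-class contrast only, and multi-level designs are out
of scope.

# Filtering and normalization

Three alternative low-expression filters are provided, all idempotent and
all returning subsets of the input genes:

* `filterRowSums(minTotal = 10)` — total count across all samples of at
  least 10. The general-purpose default.
* `filterByExpression()` — the group-aware rule with the standard
  defaults (`minCount = 10`, `minTotal = 15`, `largeN = 10`,
  `minProp = 0.7`): CPM above `minCount / median(lib)/1e6` in at least as
  many samples as the smallest group (softened above `largeN`). This is
  the mode the synthetic benchmark uses.
* `filterByVariance()` — variance of log2-CPM (prior count 0.5), either a
  floor or a top-N. Operating on log2-CPM rather than raw counts makes
  the ranking robust to sequencing depth.

Two normalization schemes serve the engines. `tmmFactors()` implements the
trimmed mean of M-values: reference column by upper-quartile closeness to
the mean, per-gene log-ratios doubly trimmed (30% on M, 5% on A), inverse
asymptotic binomial variance weights, factors rescaled to geometric mean 1.
`medianOfRatios()` implements the size-factor scheme: geometric-mean
pseudo-reference over genes positive in every sample, per-sample median
ratio. Genes with any zero count are excluded from the pseudo-reference
(the standard convention); when no gene is positive everywhere the function
refuses and points at TMM. Both agree with the widely used reference
implementations to floating-point precision on random matrices, which the
test suite verifies against those implementations directly.

Cook's distances are computed from the NB Wald engine's fitted GLM —
`D = r^2/p * h/(1-h)^2` with Pearson residuals and the hat values of the
weighted two-group design — and cells above the 99th percentile of
`F(2, m-2)` are *flagged, never removed*. A `cooksFilter` mode that masks
the Wald p-value of flagged genes exists but is off by default: with
three-per-group cohorts an "outlier" is indistinguishable from biology.

# The four engines

All engines receive the same filtered matrix and return the same genes in
the same order; normalization is per-engine (TMM for the exact-NB,
moderated-t and score engines; median-of-ratios for the Wald engine),
mirroring how the corresponding standalone tools behave. Each is a
documented simplification of the cited approach's core statistic;
bit-parity with any existing package is explicitly not a goal — the
contract is distributional (null calibration, power ordering), and the
test suite checks exactly that.

**NB exact (`runNBExact`).** Counts are scaled to a common geometric-mean
effective library size (a deliberate simplification of quantile
adjustment; with equal libraries the within-group NB sums are again NB). A
common dispersion maximizes the conditional likelihood summed over genes;
tagwise dispersions are within-group moment estimates shrunk toward the
common value with 10 prior degrees of freedom (`priorDf`, exposed). The
two-sided p conditions on the gene's total: all splits with probability no
larger than the observed one are summed — the same two-siding rule as
`binom.test`, to which the test provably reduces as dispersion goes to 0
(checked against the binomial tail in the tests). For large totals the
support is pruned at the 1e-13 quantile tails of either component, keeping
the computation O(sd) rather than O(total).

**Moderated t (`runVoomT`).** log2-CPM with prior count 0.5; a lowess
trend of sqrt(residual sd) against mean log2-CPM from an unweighted first
pass supplies inverse-trend^4 observation weights; weighted two-group
least squares per gene; then empirical-Bayes moderation of the residual
variances via a method-of-moments fit on the log variances, giving prior
df `d0` and prior variance `s0^2` and the moderated t with `d0 + m - 2`
df. One numerical choice deviates from the common implementation: when
the observed spread of log variances is at or below its theoretical
sampling value (no detectable heterogeneity, `d0 = Inf`), the prior
variance is the *arithmetic mean* of the gene variances rather than the
bias-corrected geometric mean, so that identical input variances are an
exact fixed point of moderation.

**NB Wald (`runNBWald`).** Median-of-ratios size factors; per-gene
dispersion MLE by a vectorized two-stage grid on log dispersion (40-point
coarse grid over [1e-6, 20], group means refit at the winner, then a
19-point local refinement — about 3% resolution, far inside any tolerance
that matters downstream, and orders of magnitude faster on one CPU than
per-gene optimizer calls); a parametric trend `a0 + a1/mu` fit by
iteratively reweighted least squares with gamma-style `1/fitted^2` weights
and exclusion of genes whose ratio to the trend leaves [1e-4, 15]; MAP
shrinkage of log dispersion toward the log trend under a normal prior
whose variance is the mad^2 of the log-residuals minus the trigamma
sampling variance (floored at 0.25), with genes more than 2 log2 units
*above* the trend left unshrunk — shrinking a genuinely wild gene would
manufacture false positives. The final two-coefficient GLM (log link,
size-factor offsets) has closed-form Wald standard errors
`sqrt(1/W1 + 1/W2)` from the per-group information sums. Group means are
floored at 0.125 normalized counts so an all-zero group yields a large but
finite fold change and a usable test rather than NaN.

**Score test (`runScoreTest`).** Centered log2-CPM against the centered
condition indicator: `Q = (sum y x)^2 / (s^2 sum x^2)` with `s^2` the
residual variance of the two-group fit (m - 2 df). The default p is the
chi-square(1) upper tail — exact only asymptotically, and visibly
anticonservative below n = 5 per group, which is precisely the regime the
permutation mode is for: with `nPerm > 0`, all distinct label
reassignments are enumerated when there are at most 10,000 (at 3 vs 3
that is 20, and because the centered statistic is invariant under label
complement the smallest achievable p is 2/20), otherwise sampled with the
run seed. The asymptotic default matches the benchmark usage, where the
calling threshold operates on BH-adjusted values and mild
anticonservatism washes out.

**Wilcoxon (`runWilcoxon`).** Per-gene rank-sum test on CPM, exact when
both groups have at most 25 samples and the gene has no ties, otherwise
the tie- and continuity-corrected normal approximation. Reported alongside
the four parametric engines (it is an alternative, not a member of the
combination set), since rank tests are attractive for large cohorts. A
fully tied gene is defined to have p = 1.

# Combination

Six combiners fuse the four engines' p-values per gene (inputs clipped to
[1e-300, 1 - 1e-16] so every transform is finite):
Fisher (-2 sum log p vs chi-square(2k)), Stouffer (normal scores, equal
weights by default), Lancaster (chi-square quantile transform with
per-engine weights; the default weight 2 for every engine makes it
*identical* to Fisher, a deliberate neutral default since no engine has a
principled claim to more weight — weights are configurable), Wilkinson
(r-th smallest p vs Beta(r, k-r+1); default r = 1), Tippett (min-p;
exactly Wilkinson at r = 1), and Bonferroni-Holm (step-down bound). BH
adjustment is applied per combiner across the full filtered gene universe,
never the called subset. The Max-P intersection keeps genes called DE by
all four engines at the configured thresholds and assigns each the largest
(least significant) raw engine p; an empty intersection is a valid result.

Two caveats are documented rather than "fixed". First, the four engines
see the same data, so their p-values are strongly positively dependent,
and chi-square/normal-based combiners treat them as independent: combined
p-values are *anticonservative* as global tests. They are used here as a
ranking and intersection device, exactly as in the workflow this package
reproduces; a dependence-adjusted combination is a non-goal. Second,
"mean fold change" is the arithmetic mean of per-engine log2FC (the
geometric mean of linear FC) because engines natively report log2FC and
linear averaging is asymmetric under sign flips; a linear-scale mean is
available behind `fcScale = "linear"`, and per-gene sign discordance
between engines is reported as a count instead of invalidating the
combined p.

The DE call rule everywhere is inclusive: `padj <= 0.05` and
`|log2FC| >= 1` by default, both configurable.

# The synthetic benchmark

`simPreset()` encodes the nine standard dataset types over 12,500 genes —
no DE; 1,250 DE split 50/50 or 100/0; 4,000 DE split 50/50 or 100/0; the
0-DE and 1,250/50-50 designs with single or random outliers — plus a
"large" design of 20,000 genes, 100 samples per group, 10% DE split 40/60.
DE counts and direction splits are *exact* (not Bernoulli draws), so the
grid settings are machine-checkable. `nGenes` can be overridden for
reduced-size runs; the DE fraction scales proportionally.

`sampleBaseExpression()` is a parametric stand-in for resampling empirical
(mean, dispersion) pairs from real datasets, chosen to stay
self-contained: `log2 mu ~ Normal(6, 2.5)` truncated to `mu >= 1`, and
`phi = (0.05 + 2.5/mu) * LogNormal(0, 0.3)`, reproducing the canonical
decreasing mean-dispersion scatter of bulk RNA-seq (checked by Spearman
correlation in the tests). Effect sizes are `S = 1.5 + Exp(mean 1)`
multiplying (or dividing) the test-class mean, so every DE gene has
|log2FC| >= log2(1.5) ~ 0.58 and the median planted effect is about
log2(2.2). Per-sample depth factors are Uniform(0.7, 1.4). Outlier
injection: "single" multiplies one random sample's count by Uniform(5, 10)
in 10% of genes; "random" multiplies every cell independently with
probability 5%. These rates, the effect-size family and the depth range
follow the simulator conventions this benchmark family is built on; none
are printed in a reference table anywhere, so they are fixed here once and
exposed in the API rather than tuned.

What the simulator does **not** emulate: gene-gene correlation, gene
length and GC effects, isoform structure, batch effects, library-prep
zero inflation. Passing benchmarks here therefore demonstrate correct
*statistical* behavior of the engines and combiners under clean NB
sampling — not end-to-end performance on any particular real dataset.

Scoring ignores call direction by default (a DE call on a truly DE gene is
a TP regardless of sign, matching how such benchmarks are usually
tallied); a direction-aware mode exists behind `directionAware = TRUE`.
All 0/0 metric ratios are defined as 0.

# Orchestration

`runPipeline()` wires everything into one call: read/validate, filter,
both normalizations, four (or five) engines, combination, Cook's flags,
MDS/PCA/volcano/heatmap plots, per-engine and combined TSVs, a JSON run
summary and a markdown report that narrates each executed step. Every
number in the report is re-derivable from the emitted TSVs. The rowsums
filter is the pipeline default (selectable): it is the assumption-free
choice for a general run, whereas the benchmark grid uses the group-aware
expression filter as its standard protocol. A thin command-line wrapper
(`inst/scripts/fusede`) exposes `run`, `simulate` and `benchmark`
subcommands; the exported functions are the real interface.

# Problem sizes used in the checks

The package's own acceptance checks run, per invocation: one null dataset
at full scale (preset 1, 12,500 genes, 10 per group) for calibration and
specificity; presets 2 and 7 at 3,000 genes, 3 per group, 5 replicates for
the small-cohort sensitivity comparison; one preset-4 dataset at 4,000
genes, 10 per group for effect-size recovery; and a 5,000-gene planted
dispersion trend (`phi = 0.1 + 1/mu`) for trend-fit recovery. These sizes
were chosen so the full suite completes comfortably on a single CPU while
keeping every binomial/KS tolerance meaningful; the generator's scientific
parameters are never reduced, only the gene count, with DE fractions
scaled proportionally.

# Known limitations

* Two-level contrasts only; no covariates, no multi-factor or paired
  designs.
* Combined p-values ignore between-engine dependence (see above); treat
  them as a ranking, not calibrated global error rates.
* The exact-NB engine's common-library scaling is a simplification; at
  wildly unequal depths (factor > ~5) its discreteness correction is
  rougher than a full quantile adjustment.
* The score test's asymptotic p is anticonservative for n < 5 per group;
  use `nPerm` there.
* The simulator's base-expression pool is parametric; absolute benchmark
  curves are not comparable against benchmarks that resample empirical
  expression pools, though orderings between approaches are.
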