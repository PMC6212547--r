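---
title: "Parallel ecotype divergence from expression and array-CGH data: models and methods"
author: "parasnail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel ecotype divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasnail)
```

## The scientific question

Replicate pairs of locally adapted ecotypes — here the "crab" and "wave"
forms of *Littorina saxatilis*, sampled as sympatric pairs in three
localities — offer a natural experiment: if the same genes diverge between
the ecotypes in every locality ("parallel changes"), drift is an
implausible explanation and repeatable selection a compelling one. The
package implements the complete inferential chain for two hybridization
assays over the same probe set: one-colour expression arrays on pooled
samples (four pools per ecotype and locality, 15 individuals per pool) and
two-colour comparative genomic hybridization (CGH), in which each
individual's genomic DNA is hybridized against a common reference pool so
that the log-ratio M = log2(Cy3/Cy5) tracks sequence/copy divergence from
the probe.

## Preprocessing

**Background and filters.** The background signal of a channel is the mean
log2 intensity of the array's empty spots. An expression gene is
disregarded when *strictly more than* 20% of its probes fall below
background (a 5-probe gene with exactly one low probe is kept). A CGH
probe must sit at or above the background threshold *in both channels*;
a fixed constant (such as 10.7) can be supplied instead of the empty-spot
estimate, since platforms often publish one. Only genes passing both
assays' filters enter the joint analyses. Filtering position in the CGH
chain is after normalization, so a threshold constant refers to the
normalized scale, which is stable across arrays; the expression filter
uses raw probe means against the raw empty-spot mean, the simplest reading
of "average hybridization signal". Both filters are idempotent.

**Normexp correction (CGH).** Observed linear intensity is modelled as
X = S + B, signal S ~ Exponential(θ) plus normal background B ~ N(μ, σ²).
μ and σ come from the empty spots of the channel — a deliberate choice:
empty spots measure background directly, so no deconvolution of the
signal distribution is needed — and θ is the mean gene-probe intensity
minus μ, floored at a small positive value. Each intensity is replaced by
the posterior mean E[S|X=x] = a + σφ(a/σ)/Φ(a/σ) with a = x − μ − σ²/θ,
computed on the log scale for stability far below background, plus an
offset (default 16) that damps the variance of low-intensity log-ratios.
The output is strictly positive, so log-ratios are always defined. A
degenerate σ estimate falls back to subtract-and-floor with a warning.

**Quantile normalization.** All columns are forced onto the mean quantile
distribution; for two-colour data both channels of all arrays are pooled
as columns and normalized jointly, so the two channels share one
distribution. Ties receive the mean of their tied quantile values —
deterministic and symmetric. Afterwards sorted column vectors agree to
1e-9 and each column's rank order is untouched.

**Median-polish summarization.** Each gene's probes × samples block is
summarized RMA-style by Tukey median polish (row sweep first, at most 10
iterations, stopping when the absolute-residual sum changes by less than
1e-4 of itself — the classic convention, fixed for reproducibility); the
gene's value in a sample is the overall effect plus that sample's column
effect. Single-probe genes pass through unchanged. On a noise-free
probe-effect + sample-effect block the sample effects are recovered
exactly up to an additive constant. The implementation sweeps all
equally-sized gene blocks simultaneously (grouped by probe count, with
per-gene convergence masking) for speed, and is tested gene-by-gene
against `stats::medpolish`.

## Row models and moderation

Each feature (summarized gene, or CGH probe M-value) is fitted by OLS on
the six ecotype × locality cell means; residual df is n − 6 (16 for 22
retained pools). Three contrast analyses are exposed: per-locality
crab − wave differences (three 1-df t contrasts), the factorial analysis
(ecotype main effect, 2-df locality, 2-df interaction) and among-locality
differences within each ecotype (2-df F), all estimable in the cell-means
parameterization, which avoids reference-level ambiguity across the three
analyses.

Variances are moderated empirically: s²|σ² ~ σ²χ²_d/d with the conjugate
prior σ² ~ s₀²d₀/χ²_{d₀}; (d₀, s₀²) are estimated by matching the mean
and variance of log s² (digamma/trigamma, Newton inversion — limma's
squeezeVar), and the posterior variance (d₀s₀² + d·s²)/(d₀ + d) feeds
moderated t (df d₀ + d) and moderated F (q, d₀ + d) statistics. No
robustified or intensity-dependent prior is used — the plain
method-of-moments variant, documented as such. If all variances coincide
the prior df is infinite and every posterior variance equals the common
value; fixed hyperparameters can be supplied to reproduce the d₀ = 0
(ordinary t) and d₀ → ∞ (fully pooled) limits.

CGH is analysed at probe level; gene-level CGH calls are derived
downstream by the any-probe rule (a gene is called when at least one of
its probes is), which reproduces the many-to-one probe/gene reporting of
replicated CGH studies. No sex covariate enters the CGH model; the design
does not track it.

## Multiple testing: SGoF

With F = #{p ≤ γ} (γ = α = 0.05), SGoF repeatedly tests the current count
c against Binomial(n, γ): while the exact one-sided tail P[X ≥ c] ≤ α
(inclusive), one more feature is declared and c decreases. Declared
features are the n_declared smallest p-values, ties broken by stable input
order (the reference procedure leaves tie order open; stability makes
reruns identical). The exact binomial tail is the default for
determinism and small-F correctness; a one-sided G/χ² approximation is
available for cross-checking large-n behaviour. Correction is applied
per contrast (each locality separately), with pooling possible by
concatenating p-vectors.

A structural property worth knowing: SGoF declares at most
F − qbinom(1−α, n, γ) features — the *excess* of nominally significant
tests over the binomial null bound. Per-feature recall is therefore
bounded away from 1 whenever the true-effect fraction is small relative
to √(γ(1−γ)/n); with 5% true effects among 2,000 features the per-locality
cap is ≈ 0.75–0.8 regardless of effect size. This is a property of the
procedure, not of the implementation, and it propagates to every
downstream set (parallel intersections, geography declarations).

## The parallelism null

For per-locality significant sets of sizes n₁, n₂, n₃ drawn uniformly from
a universe of N features, the intersection size K has the exact
hypergeometric-convolution law P(K=k) = Σ_m HG(m; N,n₁,n₂)·HG(k; N,m,n₃)
and mean N·∏(nᵢ/N). The published three-locality extension of the
two-group overlap algorithm was never formally specified; this
construction is the package's explicit formalization and is validated
against Monte-Carlo subset sampling. The permutation counterpart
("gene shuffle") permutes which features carry the calls within each
locality, preserving n_i, with p = (1 + #{k* ≥ k})/(R + 1) — never zero,
always on the lattice (1+j)/(R+1). A label mode (permute ecotype labels
within localities, refit, re-correct) exists for calibration studies at
reduced R; whether the original 200,000-resort procedure preserved counts
or refit the chain is not recoverable from its description, so both modes
are labelled. Defaults are R = 10,000 (desk runtime); the paper-scale
200,000 is settable.

Discreteness caveat: under a sparse null k is almost always 0 and the
permutation p-value is then exactly 1, so raw permutation p-values are
*sub*-uniform (valid but conservative). Calibration is assessed by the
randomized probability integral transform over the returned null draws,
which is exactly uniform for an exchangeable statistic.

## Directionality, variance, geography

A parallel feature is directional (D) when its crab − wave contrast
estimate — the same estimate that drove significance, not a re-derived
group difference — has the same nonzero sign in all three localities;
an exactly-zero estimate counts as a mismatch. The D-excess null permutes
signed estimates within localities across the parallel set (the stricter
choice; an all-features pool is available via `pool = "all"` — note that
permuting a degenerate all-same-sign parallel set reproduces itself, so
the within-set p is 1 there by construction and the pooled variant is the
informative one). Expected counts and 95% percentile intervals come from
the replicates. With balanced signs the null directional fraction tends
to 2·(1/2)³ = 1/4; with per-locality sign frequencies p_l it is
∏p_l + ∏(1−p_l).

Intrapopulation variance is the mean over the six ecotype × locality
groups (those with ≥ 2 replicates) of the unbiased within-group variance.
D and ND classes are compared by a two-tailed pooled-variance t test
(Welch behind a flag) and by label permutation of the class assignments;
the ND/D ratio of class means is reported.

Geographic differentiation within an ecotype is the 2-df moderated F among
localities restricted to that ecotype's samples, SGoF-corrected. The
enrichment of differentiation in the parallel (or nonparallel) set is
judged against B = 1,000 resamples of equal-size random sets from the
universe; "nonparallel" means divergent in at least one but not all three
localities (not the whole non-intersection universe — a config switch
gives the looser reading). Both ecotypes' results are emitted separately,
since pooling was ambiguous in the source description.

## The synthetic-data generator

The generator emulates the study design exactly: three localities × two
ecotypes; expression as 4 pools per group (22 of 24 retained after random
dropout that never empties a group), CGH as 12 individuals per group
(69 of 72), ~5 probes per gene, empty spots present. Defaults: 2,000
genes × 5 probes + 200 empty spots (a deliberate reduction from the
25,205-gene array so the full chain runs in seconds), gene baselines
N(12.5, 1.2), probe affinities N(0, 0.7), empty spots N(10, 0.3), all
log2 — chosen to put a few percent of genes near background so the
filters act realistically. Per-gene within-group variances follow the
scaled-inverse-χ² prior (d₀ = 4, s₀² = 0.05, values typical of moderated
microarray analyses) that the moderation model assumes, so moderated
statistics are exactly calibrated on generator nulls.

Effects are injected on the log2 scale directly (the analysis scale);
there is no linear-scale simulation. Truth classes per gene —
parallel-directional (equal-sign effect triple), parallel-nondirectional
(all nonzero, mixed signs), locality-specific (exactly one nonzero) —
are drawn independently for the two assays, so assay overlap among
parallel genes is at chance, as in the two-assay design. Which ecotype
carries the positive effect is a fair coin per gene, making null sign
expectations symmetric. `effect_size` is in log2 units by default;
`effect_in_sd_units = TRUE` re-expresses it in units of each gene's own
within-group sd (CGH: of the M-value sd, √2·σ because both channels carry
noise), which makes detection power independent of a gene's noise level —
without it, rank-based declaration preferentially keeps low-variance
genes and any between-class variance contrast is attenuated by selection.
`directional_sd_factor` scales directional genes' within-group sd (set
1/√2 to plant the halved-variance pattern); `locality_shift` adds
per-locality baseline shifts to parallel-class genes of both ecotypes,
planting geographic differentiation. The `pool_size_effect` divisor
leaves the within-pool/between-pool variance split to the user — the
15-snail pooling's effective variance reduction is not identifiable from
the published design — and defaults to 1 (no reduction).

CGH simulation gives both channels a shared probe baseline plus
independent noise, so M isolates the injected effect; the divergence
effect is applied to a random subset of each affected gene's probes
(each with probability 0.5, at least one), reproducing the many-to-one
gene/probe reporting. Identical seeds give byte-identical TSV output.

What the generator does *not* emulate: spatial array artifacts, scanner
saturation, probe-sequence (GC) effects, linear-scale mean-variance
coupling, and correlated probe affinities within genes. Passing tests
therefore validate the statistical chain under its own assumptions, not
robustness to platform pathologies.

## Numerical conventions and problem sizes

Reported percentages are rounded half-up (not banker's rounding): one
decimal for fractions of the gene universe, integer percent for fractions
of the parallel set — matching the published precision. Permutation
p-values use the add-one rule and cannot be zero. All randomized stages
take explicit seeds; the pipeline derives stage seeds from one master
seed, and identical configurations give byte-identical artifact files.
The test suite exercises the chain at 60–2,000 genes; calibration checks
use 100 null seeds at the 2,000-gene default and oracle comparisons use
10⁵-draw Monte-Carlo tails — sizes chosen so the full suite runs in a few
minutes on one core while keeping Monte-Carlo error well below the
tolerances asserted.

## Known limitations

* SGoF's excess-cap bounds per-feature recall (see above); sensitivity
  targets near 1 are unreachable at realistic scales whatever the effect
  size. Power statements about this chain should be phrased in terms of
  the excess, not per-feature recall.
* The exact intersection null assumes per-locality calls are independent
  uniform subsets; correlated truth (the interesting case) is exactly what
  the observed k is tested against, but correlated *nulls* (shared
  technical artifacts) would inflate it.
* The normexp parameter estimates ride on empty spots; arrays without
  empty spots need externally supplied thresholds and background
  parameters.
* Median polish is order-dependent (row sweep first); the convention is
  fixed and documented rather than averaged over.
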