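---
title: "Identifying differential A/B compartments across Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying differential A/B compartments across Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicomp)
```

## The problem

Hi-C correlation matrices show a checkerboard ("plaid") pattern produced by
the segregation of chromatin into A (active, GC-rich, gene-dense) and B
(inactive) compartments. The per-bin compartment score — the selected
principal component of the distance-normalized correlation matrix — is easy
to compute for one map but awkward to *compare* across maps: each map's
eigenvector has its own scale and arbitrary sign, the compartment signal may
sit in the first or second component, and an observed difference has to be
weighed against biological and technical noise. `hicomp` turns a set of
cis contact maps (two or more conditions, with or without replicates) into
per-bin compartment scores on a common scale and tests every bin for a
significant difference, including strength changes that never flip sign.

## From counts to comparable scores

**O/E transform.** For one chromosome, the expected count at distance `d`
is the mean over all unmasked bin pairs at that offset; each entry is
divided by its expected value. Bins with zero marginal count or with fewer
than `min_coverage_frac` (default 1%) nonzero entries are masked first, and
expected values are computed over unmasked pairs only so that dead bins do
not deflate the background. Distances with expected 0 get O/E 0. Raw counts
are the intended input; matrix-balanced maps are accepted through the same
interface but are not the default.

**Correlation PCA.** The Pearson correlation matrix of the O/E rows is
decomposed exactly; only the top-k triplets (k = 2 by default) are
retained. For these symmetric matrices the truncated decomposition is
obtained from the dense symmetric eigensolver, which is exact and fast at
the matrix sizes a chromosome produces (about 1.5 s at 2,000 bins);
components are reported as singular triplets with the principal components
`PC = X·V`. A deterministic sign convention (the largest-magnitude loading
is made positive) is applied before any biological orientation so that
repeated runs are bit-identical.

**Selection and orientation.** Among the k candidates the component with
the largest `|r_GC| + |r_gene|` is chosen. The absolute values matter: the
pre-orientation sign of an eigenvector is arbitrary, so a sum of signed
correlations would discard a perfectly informative but sign-flipped
component. Ties go to the lower component index. The selected component is
negated if its GC correlation is negative (exactly zero GC correlation
falls back to the gene-density sign), making positive scores A. Chromosomes
with fewer than 20 usable bins are skipped with a warning — a correlation
PCA on a handful of bins is noise.

**Quantile normalization.** All replicate columns of all samples are
quantile normalized *together*, independently within each chromosome, via
`limma::normalizeQuantiles` (ties receive the average of the tied reference
quantiles). Bins masked in any column are excluded from the pool for every
column rather than imputed; fabricating a score for a bin one map never
observed would contaminate the null. Replicates are then averaged into one
score vector per sample. Externally computed scores (bedGraph per
replicate) can enter here directly via `load_precomputed_scores()`.

## The differential statistic

With `M` samples, bin `i` carries the score vector
`s_i = (q_1^i, …, q_M^i)`. Its cross-sample disagreement is summarized by
`d_N^i = sqrt(sum_t (q_t^i − q_N^i)^2) / (M − 1)`, standardized across bins
within each sample to `Z_N^i`, and collapsed to a weight
`w_i = pnorm(max_N Z_N^i)`. The test statistic is the quadratic form

`MD_i = (s_i − μ_i)' Σ⁻¹ (s_i − μ_i)` with `μ_i = s_i (1 − w_i)`,

so the deviation entering the form is `s_i · w_i`: bins whose samples
disagree most (w → 1) are scored at full strength, bins at or below average
disagreement are shrunk toward the origin. Two published descriptions of
this center exist side by side — the multiplicative form `μ_i = s_i · w_i`
and the stated intent of giving *more* weight to discordant points. They
pull in opposite directions: with `μ_i = s_i · w_i` the deviation becomes
`s_i (1 − w_i)`, which vanishes exactly for the most discordant bins and
makes the test blind to planted compartment flips (recall 0 in our
recovery simulations). We therefore default to `weighting = "distant"`
(`μ_i = s_i (1 − w_i)`, the direction that matches the replicate-level
formula and the stated intent, and the one our null-calibration and
recovery tests select) and keep the literal form available as
`weighting = "printed"`.

**Robust covariance and the two-pass refinement.** `Σ` is the minimum
covariance determinant (MCD) estimate (`MASS::cov.rob`), whose subset
search is made reproducible by seeding immediately before the call
(`md_config(seed = …)`). A first pass computes MD for all bins and removes
those above the chi-square critical value `qchisq(0.90, df)` — precisely
the strong differential bins that would otherwise inflate the null
covariance. The covariance is re-estimated on the survivors and *every*
bin, including the removed ones, is re-scored against the tightened null;
this is what gives the method its sensitivity. A warning is raised if more
than half the bins are removed, which indicates a misspecified null.

**Degrees of freedom.** The chi-square reference needs a df that the
original description leaves open; we default to `df = M`, the dimension of
the score vector, which is the standard choice for a Mahalanobis outlier
test, and expose it in `md_config(df = …)` because the reference behaviour
is not verifiable from the text alone.

**Replicate covariate and FDR.** When every sample has at least two
replicates, a per-bin replicate-variability statistic is computed from the
quantile-normalized replicate scores: within-sample distances only,
standardized per replicate, weight `srw_i` from the maximum replicate
z-score, centers `s_i^r (1 − srw_i)`, and a *diagonal-masked* inverse
covariance so each replicate contributes independently. This covariate is
independent of the test statistic under the null and feeds an
independent-hypothesis-weighting style correction: bins are cut into
covariate quantile strata (5 by default), per-stratum weights with mean 1
are learned by cross-fitting (weights applied to one fold are learned on
the others; folds are deterministic stripes along the covariate order, so
no RNG state is involved), and weighted Benjamini–Hochberg is applied. A
constant covariate degenerates exactly to plain BH, as does the
no-replicate case. Adjusted p-values are floored at the raw p-value; this
is slightly conservative relative to unconstrained weighting but keeps the
monotonicity contract `padj ≥ p`.

**Transitions.** Significant two-sample bins are labelled `A->B` / `B->A`
for sign flips and `sA->wA`, `wA->sA`, `sB->wB`, `wB->sB` for within-
compartment strength changes; strong/weak is the strict comparison of
absolute scores, with no minimum-gap threshold — the FDR filter already
decides *which* bins deserve a label, so the label only reports direction.
An exact zero score counts as A (boundary-inclusive); ties in absolute
score are labelled as rising. With more than two samples the label is the
per-sample A/B sign string plus the most extreme sample (e.g. `ABB:ESC`).

## Differential interactions

Interactions called significant elsewhere (FitHiC2-style TSV; the union
over replicates is used) are restricted to pairs with at least one anchor
in a significant differential bin, converted to `log2((O + c)/(E + c))`
per sample with pseudocount `c = 1` (pairs absent in one sample stay
finite) and the same per-distance expected model as the compartment O/E,
and tested with the same quadratic form around per-sample centers (the
mean over the tested set; a trimmed mean is available). MCD covariance is
the default for consistency with the compartment test (`robust = FALSE`
gives the classical estimate); p-values are chi-square upper tails with
plain BH correction. Fewer than 10 qualifying interactions is refused —
no usable covariance exists there.

## The synthetic generator

`simulate_map()` draws counts around
`λ_ij ∝ |i − j|^(−α) · (1 + δ · a_i · a_j)`, the simplest model with the
two features the pipeline consumes: a power-law distance decay (α = 1 by
default) and a plaid compartment modulation of strength δ. The diagonal is
set from the distance-1 intensity, the matrix is scaled to a target depth
(5e6 expected reads by default) and sampled independently per pair
(Poisson; a negative-binomial option adds overdispersion to stress the
replicate covariate), then symmetrized. The track `a` is blockwise with
alternating signs, geometric block lengths (mean 20 bins, minimum 5) and
magnitudes uniform in [0.05, 0.95]: the upper cap keeps `1 + δ a_i a_j`
strictly positive at δ = 1 (the generator rejects non-positive
intensities), and the continuous lower range reflects real compartment
scores, which form a broad distribution without a hole at zero — an
all-strong bimodal track would be unrealistic and would defeat any
half-sample robust covariance estimator. Differential truth is planted in
the last condition as contiguous sign-flipped runs (exactly
`round(flip_fraction · n)` bins) and strength-shifted runs (`|a|` scaled by
`shift_factor`). The GC covariate is a noisy monotone function of the
condition-average track and gene density a Poisson log-linear function of
it, so component selection and orientation are exercised realistically.

What the generator does *not* emulate: TADs and loops, trans contacts,
copy-number and mappability artifacts, and polymer-physics correlations
between nearby pairs (counts are independent given λ). Passing tests
therefore demonstrate the statistical contract of the method — calibration,
recovery, robustness to depth — not performance on every artifact of real
data.

## Reference study conditions and numerical choices

The validation suite and `scripts/acceptance.R` use a fixed reference
study: 2 conditions × 2 replicates, one chromosome of 2,000 bins at 100 kb,
5e6 reads per map, plaid affinity δ = 1, and — for recovery — 5% planted
flips. Score-accuracy checks use 500 bins; the calibration check uses
5,000 multivariate-normal null vectors with a known covariance (bypassing
MCD, where the chi-square reference is exact). These sizes are the
package's reference problem sizes; they keep a full validation run at a
few minutes on one core while leaving each stage enough data to be
meaningfully tested (the MCD requires at least five rows per column, the
differential fit at least five complete bins per sample).

Other numerical choices worth knowing: expected values at distances with
no unmasked pairs are 0 (O/E 0 there); constant O/E rows are masked
iteratively before the correlation; the MCD support fraction is the
implementation default `floor((n + p + 1)/2)` unless overridden; exactly
duplicated score columns raise an error naming the collinear columns
rather than producing an unusable covariance; and σ(d) = 0 degeneracies
(all distances identical, e.g. perfectly duplicated replicates) map to
z = 0, hence weight 0.5, with a warning instead of NaN propagation.

## Limitations

Scores are only computed per chromosome but tested genome-wide after
per-chromosome quantile normalization; chromosome-specific biases beyond
what QN removes are not modelled. The chi-square reference assumes the
normalized scores are approximately multivariate normal under the null —
heavy-tailed score distributions make the test conservative rather than
anti-conservative (the MCD null plus the two-pass refinement tightens the
center, and the weighting shrinks concordant bins), but calibration on
strongly non-normal data should be checked with a replicate-vs-replicate
run. Adjacent significant bins are reported individually, not merged into
domains, and no effect-size shrinkage is applied.
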