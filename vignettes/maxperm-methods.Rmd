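---
title: "Permutation inference and resampled effect sizes in maxperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference and resampled effect sizes in maxperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxperm)
```

## The inferential model

`maxperm` performs hypothesis testing by constructing the null sampling
distribution of a test statistic empirically. Under the null hypothesis the
observed data are exchangeable under a group of rearrangements; recomputing
the statistic over those rearrangements yields the *permutation
distribution*, which approximates the null distribution without assuming
normality or any other parametric family. Three quantities are read off it:

- the **p-value**, the proportion of the permutation distribution greater
  than or equal to the magnitude of the observed statistic (two-tailed) or
  beyond it in the requested direction (one-tailed);
- the **confidence interval**, from the percentiles of the distribution
  (2.5% and 97.5% for a 95% CI);
- for multivariate data, a **max-corrected** version of both.

The rearrangement scheme is chosen to respect exchangeability for each
design:

| design | scheme |
|---|---|
| two-sample t, F, one-way ANOVA | permutation of group labels |
| one-sample, paired t, Z | sign flips of deviations about the hypothesised mean |
| correlation | row permutation of the second matrix |
| two-way ANOVA | unrestricted row permutation of the response |

Sign-flipping assumes the null distribution of deviations is symmetric
about the hypothesised centre; label permutation assumes the pooled
observations are exchangeable under the null. The two-sample tests are
robust to moderate variance differences when group sizes are equal, which
is why `perm_ttest2` warns when pooled variance is combined with unequal
group sizes.

## Max-statistic correction

For p variables, each permutation produces p statistics; the maximum
absolute value (two-tailed; the maximum or minimum for one-tailed tests)
across variables is retained, giving a single shared null distribution.
Every observed statistic is compared against it. Because the maximum over
more variables is stochastically larger, the procedure is automatically
more conservative for larger families, and because it is built from the
joint permutation of all variables it adapts to their correlation — highly
correlated families pay a much smaller penalty than independent ones.
This controls the family-wise error rate strongly. Max correction is on by
default whenever more than one variable is tested; confidence intervals
built from the shared distribution are simultaneous intervals and
correspondingly wider. Variables whose statistic is undefined (zero
variance) are excluded from the maximum and reported as missing rather
than forced to p = 1.

## Confidence-interval constructions

The spread of a permutation distribution estimates the null sampling
variability of the *standardised* statistic, so intervals on an
interpretable scale are obtained by rescaling:

- **t and Z tests**: the `(1 - alpha)` percentile `c` of the (max-corrected)
  absolute null distribution of the statistic gives
  `estimate ± c · se`, where `se` is the statistic's denominator. This is
  the permutation analogue of the textbook `estimate ± t_crit · se`
  construction, with the empirical critical value replacing the parametric
  one.
- **Correlations** have no separate standard-error scale; the signed
  percentiles of the null distribution are re-centred at the observed r
  and clipped to [−1, 1].
- **Variance ratios** are handled on the log scale,
  `exp(log F ± c)`, with `c` the percentile of `|log F|` under permutation.
- **ANOVA F** has no unstandardised estimate; no interval is reported.

One-tailed tests yield one-sided bounds with the other side infinite.

## Effect sizes and bias correction

Cohen's d divides the mean difference by the pooled n−1-weighted SD
(or `sqrt((s_x² + s_y²)/2)` unpooled); Glass' delta uses the control
sample's SD, for clearly unequal variances; Cliff's d is the dominance
statistic `(P(X>Y) − P(X<Y))` over all cross-sample pairs, suited to
ordinal data and computed here by the midrank identity in O(n log n) (ties
contribute zero). Mean and median differences are available unstandardised.

Standardised mean differences are biased upward in small samples. The
multiplicative factor `1 − 3/(4n − 9)` removes most of the bias and is
applied by default to Cohen's d and Glass' delta; the corrected estimate is
Hedges' g. `n` is the total number of observations backing the
standardiser: `n1 + n2` for two-sample designs (also adopted for Glass'
delta, keeping a single convention) and the number of pairs or
observations for paired/one-sample designs. The factor is applied inside
every bootstrap replicate as well, so the interval is an interval of the
corrected quantity.

Bootstrap CIs are percentile intervals (`alpha/2`, `1 − alpha/2` quantiles)
of the effect over resamples drawn **with** replacement — in contrast to
permutation, which resamples without replacement. Independent designs
resample each sample's rows independently; paired designs resample pair
indices jointly. On every replicate one shared index row is applied to all
variables of a sample, which preserves the dependence between variables and
is what makes multivariate runs cheap: the cost is one index table, not one
per variable. BCa intervals are deliberately not implemented; the
percentile principle is used throughout. Replicates with a degenerate
standardiser are dropped (a warning fires if more than 1% drop for any
variable).

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `n_resamples` | 10000 | several thousand permutations are needed for reliable p-values; 10⁴ gives Monte-Carlo SE ≤ 0.005 at p = 0.5 and is cheap for the vectorised kernels |
| `n_boot` | 10000 | same resolution argument for percentile endpoints |
| `alpha` | 0.05 | conventional 95% intervals (2.5/97.5 percentiles) |
| `correction` | `auto` | max correction whenever > 1 variable, per the strong-FWER default |
| `seed` | 42 | fixed, so naive runs reproduce; every result embeds it |
| `tail` | `two` | directional tests opt in explicitly |
| `variance_mode` | `pooled` | Student's t when equal variances are plausible; `unpooled` gives Welch with Welch–Satterthwaite df |
| `add_one` | `FALSE` | p = b/m, equalities counting as extreme; the `(b+1)/(m+1)` convention is available behind the flag |
| exhaustive cap | 10⁶ rows | above this, enumeration costs more than it buys |

Exhaustive enumeration replaces Monte-Carlo automatically whenever the
number of distinct rearrangements is at most `n_resamples` (e.g. two
samples of 4: 70 assignments; 12 pairs: 4096 sign patterns), giving exact
p-values on the 1/m grid. The observed statistic is not injected into
Monte-Carlo null distributions; in exhaustive mode the identity
rearrangement is present naturally.

## Numerical choices

- **Tie detection.** Equality with the observed statistic counts toward the
  p-value. Analytically tied rearrangements can differ in the last floating
  point digits when recomputed through the vectorised path, so equality is
  detected up to a relative tolerance of 1e−8 — negligible against
  Monte-Carlo resolution, but it keeps exhaustive p-values exact (e.g.
  complete separation with n = 3 + 3 gives p = 2/20 precisely).
- **Percentiles** use the default interpolating quantile (type 7).
- **Stability.** Resampled moments are computed from globally centred data
  (shift-invariant statistics), and negative variances from cancellation
  are clamped at zero.
- **Missing data** are removed per variable within each sample (pairs are
  dropped jointly in paired designs) via mask-based moment computation, so
  group sizes can differ across variables under a shared permutation
  table. Correlation tests instead drop incomplete rows across the (x, y)
  pair of matrices up front: shared row permutations require a common
  observation set.
- **Degenerate variables** (zero variance where a variance is needed) are
  flagged undefined and excluded, never a run-level failure.
- **Two-tailed F.** The max-correction machinery takes maxima of absolute
  values, so the variance test uses the sign-symmetric kernel `|log F|`;
  raw F and both dfs are still reported.
- **Exhaustive label permutation** is enumerated for two groups (binomial
  coefficients); designs with three or more groups always use Monte-Carlo
  (their multinomial counts are reported by `count_exact_resamples`, but
  enumeration is rarely affordable at realistic sizes).
- **Two-way ANOVA** permutes raw observations and refers each effect to its
  own global-null permutation distribution. This is an approximation: it
  does not condition on the other effects (residual-permutation schemes
  do), and it is restricted to balanced designs with a single response.
- **Rankit correlation** is Pearson's r on the normal scores
  `qnorm((rank − 0.5)/n)`; Spearman uses midranks for ties.

## The synthetic generator

`synth_spec()`/`synth_two_sample()` produce the package's reference design:
two independent Gaussian samples, 30 observations × 20 variables, unit SD,
with variables 1–10 of the second sample shifted by −1 — ten true effects
of one SD and ten true nulls, the regime in which max correction shows both
its FWER control and its retained power. Variants: `global_null` (no
shift), `correlated_null` (equicorrelated variables via a single-factor
construction, Cholesky for negative rho), and `synth_ordinal()`
(equiprobable discretisation of the latent Gaussian, for Cliff's d and tie
handling). The generator emulates location shifts under homoscedastic
Gaussian noise; it does not emulate heavy tails, skew, outliers, or
heteroscedastic or autocorrelated noise, so passing tests demonstrate
correctness of the machinery, not robustness claims about arbitrary real
data — the point of permutation inference is precisely that its validity
does not rest on the generator's Gaussian form.

## Verification scales

The test suite verifies behaviour at sizes chosen to give tight Monte-Carlo
bounds while keeping a laptop run short: family-wise error is measured over
1000 simulated 20-variable null datasets at 2000 permutations each
(binomial SE ≈ 0.007 at the nominal 0.05); bootstrap coverage over 1000
simulations at 1000 resamples; small-sample bias over 20000 simulated
datasets; exhaustive-versus-Monte-Carlo agreement over 100 instances at
10000 permutations against a 70-assignment enumeration oracle.

## Limitations

- Repeated-measures and n-way ANOVAs, unbalanced two-way designs, and
  rank-sum tests (sign, Wilcoxon, Mann–Whitney, Kruskal–Wallis, Friedman)
  are not implemented.
- No FDR-style corrections: max correction is the package's multiplicity
  method (Bonferroni/Holm appear only as oracles in the test suite).
- Monte-Carlo p-values use the plain b/m convention by default; under a
  true null they are approximately, not exactly, uniform (the add-one
  convention is available where strict validity at tiny m matters).
- Stratified or blocked permutation schemes are out of scope.
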