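---
title: "Correlated outcome suites: the MEff correction, its simulation models, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated outcome suites: the MEff correction, its simulation models, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meffpower)
```

## The multiplicity problem for outcome suites

An intervention study that records $k$ outcome measures and would claim
success if *any* of them improves must control the familywise error rate
(FWER), the probability of at least one false positive across the suite.
For independent outcomes tested one-tailed at level $\alpha$ the FWER is
$1 - (1 - \alpha)^k$ — already .265 for six outcomes at $\alpha = .05$
(`fwer_independent(6)`). Bonferroni's per-test threshold $\alpha / k$
restores control exactly when outcomes are independent, but outcome
batteries are nearly always positively correlated, and then Bonferroni is
conservative: the $k$ tests carry fewer than $k$ tests' worth of
independent information.

## The effective number of tests

Let $\mathbf{R}$ be the $k \times k$ correlation matrix of the outcomes
with eigenvalues $\lambda_1, \dots, \lambda_k$ (they sum to $k$). The
spread of the eigenvalues captures the redundancy of the suite: all equal
to 1 when the outcomes are independent, collapsing onto a single
eigenvalue $k$ when they are perfectly correlated. The effective number
of tests condenses this into

$$\mathrm{MEff} = 1 + (k - 1)\left(1 - \frac{\mathrm{Var}(\lambda)}{k}\right),$$

and the per-outcome threshold is $\alpha_\mathrm{MEff} = \alpha /
\mathrm{MEff}$, applied strictly ($p < \alpha_\mathrm{MEff}$).

**Eigenvalue-variance denominator.** $\mathrm{Var}(\lambda)$ is the
*sample* variance of the $k$ eigenvalues, denominator $k - 1$. The
formula is sometimes written without a denominator convention; the
reference values this package reproduces pin it down. For six
equicorrelated outcomes at $r = .4$ the eigenvalues are
$(3, .6, .6, .6, .6, .6)$, whose squared deviations from 1 sum to 4.8:
the tabulated variance is $0.96 = 4.8/5$, not $4.8/6$. With the $k-1$
denominator an equicorrelated matrix has
$\mathrm{Var}(\lambda) = k r^2$, hence the closed form
$\mathrm{MEff} = 1 + (k - 1)(1 - r^2)$, which interpolates between
Bonferroni ($r = 0$) and no correction ($r = 1$).

```{r}
meff_result(equicorrelated_matrix(6, 0.4))
```

**Presentation rounding.** All computation is done at full precision;
published-style tables round half-up at the last step
(`round_half_up()`). The distinction is observable: 5 outcomes at
$r = .5$ give $\alpha_\mathrm{MEff}$ exactly .0125, presented as .013.
Because 0.05/4 in binary floating point falls fractionally below .0125,
the renderer adds a $10^{-9}$ guard before flooring; the guard is far
below the 3-decimal presentation scale and cannot affect values that are
not exactly on a decimal half boundary.

**Validation, not repair.** User-supplied matrices are checked for
squareness, symmetry (within $10^{-6}$ for CSV input), unit diagonal and
positive semi-definiteness. Eigenvalues in $(-10^{-8}, 0)$ — numerically
zero, as in a rank-deficient matrix estimated from few subjects — are
clipped to 0; anything more negative is rejected. No nearest-PSD
projection is attempted: a matrix that badly fails PSD is evidence of a
transcription error, and silently repairing it would change the answer.

## Lookup tables and block robustness

`meff_lookup_table()` tabulates $\alpha_\mathrm{MEff}$ for $k = 2$–$12$
outcomes and mean correlations 0–1 in steps of .1, computed analytically
from the equicorrelated closed form (the printed grid is fully
reproduced by the analytic values, so no simulation is involved). A
reader evaluating a published study rarely knows the full matrix — often
only an average correlation from a test manual. Basing the correction on
an equicorrelated matrix at the *mean off-diagonal* correlation is
justified by a robustness property the test suite checks: for two-block
structures (within-block correlation $r$, zero across blocks, $k = 4, 6,
8$) the adjusted alpha differs from the equicorrelated matrix at the same
mean off-diagonal by at most 0.002. When reproducing the published
block-comparison table, the equicorrelated comparator at each $k$ uses
that $k$'s own mean off-diagonal ($r/3$ for $k=4$, $0.4r$ for $k=6$,
$12r/28$ for $k=8$); the table's single "mean off-diagonal" column prints
the $k=8$ value.

`alpha_from_lookup(k, mean_r)` computes exactly at the supplied value
rather than interpolating the rounded grid; `table = TRUE` emulates the
audit behaviour of reading the printed table (snap to the nearest .1 row,
round to 3 decimals). When a source reports a *range* of plausible
correlations, `evaluate_study()` accepts `mean_r = c(lo, hi)` and reports
adjusted alphas and flags at both endpoints instead of silently picking a
point estimate.

## The latent-factor simulator

Power statements require a generative model for correlated outcomes. Each
outcome is an indicator of a latent factor $L$:

$$V_j = a\,L + \sqrt{1 - a^2}\,e_j, \qquad L,\, e_j \sim N(0,1)
\text{ independent},$$

so each outcome has unit variance and two outcomes sharing a factor
correlate at $a^2$. To achieve a target mean intercorrelation $r$ the
loading is $a = \sqrt{r}$ (`loading_from_target()`); a target of 0 is
excluded — uncorrelated outcomes cannot be indicators of a common factor,
and the smallest value used in the shipped grids is .2. The intervention
acts on the factor: group I's latent mean is shifted by
$E_l = E / \sqrt{r}$ (`latent_effect()`), which propagates to a
standardized mean difference of exactly $E$ on every affected outcome
since $a E_l = E$.

Three models:

- **L1** — one factor, all $k$ outcomes load on it, factor shifted by
  $E_l$ in group I.
- **L2** — two *independent* factors, outcomes split into two blocks,
  both factors shifted.
- **L2x** — as L2, but only the first factor is shifted: half the suite
  is insensitive to the intervention.

For odd $k$ the first block receives $\lceil k/2 \rceil$ outcomes — a
recorded choice (reference figures only show even splits), consistent
with "the first factor is the affected one" in L2x. A single value is
simulated per subject; pre/post change scores, non-normal or binary
endpoints, missing data and correlated factors are out of scope.

What the simulator does *not* emulate about real data: non-normality,
unequal loadings across outcomes, unequal group variances, measurement
drift between arms. Tests passing under this generator show the decision
rules behave as designed under the stated factor models, not that they
are robust to those violations.

## Decision rules and the power engine

Per replication, `run_power()` draws a dataset, computes one-tailed
two-sample p-values per outcome (alternative: intervention > control),
and declares the study significant under each rule:

- **uncorrected** — any $p < \alpha$;
- **bonferroni** — any $p < \alpha/k$;
- **meff** — any $p < \alpha / \mathrm{MEff}(\hat{\mathbf R})$;
- **pca** — one-tailed comparison of first-principal-component scores at
  the unadjusted $\alpha$.

Choices that were genuinely open, and how they were fixed:

- *t-test variant.* Welch (unequal-variance) by default, with
  `var_equal = TRUE` available. The generative models give both arms
  equal variance, so the choice is inconsequential there, but it is fixed
  and documented rather than left to a default.
- *Correlation matrix for MEff inside a replication.* Default
  `meff_corr = "sample"`: the pooled within-group sample correlation
  matrix (group means removed per outcome before correlating, so a true
  effect does not inflate the correlations and thereby loosen the
  threshold). `meff_corr = "population"` instead uses the known
  generative matrix once per run; both are available because either is a
  defensible reading of how such a simulation "applies MEff", and the
  test suite checks they give closely similar power.
- *Strict inequality.* "Significant" means $p$ strictly below the
  threshold throughout.
- *PC1 conventions.* Components are computed on both groups combined,
  centered, unscaled (outcomes are unit-variance by construction, so
  scaling is immaterial but the choice is recorded). The component sign
  is chosen so the loadings sum positive — outcomes are keyed so that
  improvement is positive, and a one-tailed test on PC1 scores is
  undefined without a sign convention.
- *RNG.* One seeded generator per power run; replications consume it
  sequentially, and the seed is echoed in all CLI output, so any run is
  bit-reproducible from its logged configuration.

The analytic single-outcome reference is noncentral-$t$ power with
noncentrality $E\sqrt{n/2}$ on $2n-2$ degrees of freedom
(`single_outcome_power()`). For the L2x setting, where a researcher
forced to pick one primary outcome might pick a responsive or an
unresponsive one with equal probability, the reference is the average of
the powered and null cases (`l2x_reference_power()`).

## Problem sizes and what the checks establish

The shipped verification suite reproduces the deterministic reference
tables exactly (6-outcome eigenvalue table; the full 11 × 11 adjusted-
alpha grid; the block-robustness table at 3 decimals) and checks the
eigendecomposition against closed-form spectra to $10^{-10}$. Monte-Carlo
properties use 2000 replications at 50 subjects per group — the scale at
which the qualitative findings are stable relative to the Monte-Carlo
standard error $\sqrt{p(1-p)/2000} \approx .01$: corrected methods stay
at or below the nominal FWER; under L1 the PC1 composite is the most
powerful rule, MEff sits between PCA and Bonferroni; power under MEff
grows with the number of moderately correlated outcomes; Bonferroni with
many highly correlated outcomes falls below the single-outcome reference;
and under L2x MEff overtakes the PC1 composite, whose first component is
diluted by the unresponsive block. Distributional checks on the simulator
use $10^4$ subjects per group for correlation targets ($\pm .02$) and
$10^5$ for effect-size recovery ($\pm .02$).

## Known limitations

- The scalar-correlation path assumes a positive, roughly uniform
  intercorrelation; strongly negative or wildly heterogeneous
  correlations should be handled with the full matrix, and matrices with
  mean off-diagonal near zero make MEff nearly coincide with Bonferroni.
- MEff (like Bonferroni) invites over-interpretation of *which* outcomes
  cross the threshold; under a single common factor, which indicators
  reach significance is largely chance, and only replication can
  establish a specific pattern.
- Estimated mean correlations imported from manuals or prior studies
  carry sampling error that the adjusted alpha does not propagate;
  `evaluate_study()`'s range interface makes that uncertainty explicit
  but does not model it.
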