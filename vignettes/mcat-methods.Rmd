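---
title: "Methods: bifactor GRM calibration and adaptive-testing simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bifactor GRM calibration and adaptive-testing simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the model, the
estimation machinery, the adaptive engine, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## The measurement model

Responses are ordinal with mixed category counts (2–6). Item `i` with `K_i`
categories follows a graded response model with a logistic link in
slope–intercept form: the probability of responding in category `k` or
above is `P*_k = plogis(a_gen θ_0 + a_grp θ_g + d_k)`, and the category
probability is the difference of adjacent boundaries. The latent space is
bifactor: one general dimension `θ_0` that every item loads on, plus `G`
group dimensions of which each item touches at most one. All factors are
mutually uncorrelated with unit variance — this is both the usual bifactor
identification and the distribution the simulation truths are drawn from,
so the MAP prior is MVN(0, I) with no free hyperparameters.

Conventions worth stating once:

* categories are 0-based internally (`0 … K−1`), so the model-implied
  expected score is simply the sum of the boundary probabilities;
* intercepts are strictly decreasing (this is equivalent to nonnegative
  category probabilities); difficulty-style tables (`b_k` increasing) are
  converted by `d_k = −b_k · ‖a‖` on read, and the conversion is exposed
  both ways;
* `a_general > 0` resolves the reflection indeterminacy of the general
  factor; group slopes are unconstrained in sign during estimation and each
  group factor is reoriented afterwards so the sum of its slopes is
  positive;
* category probabilities are floored at `1e-10` inside logarithms so
  extreme trait values cannot produce `-Inf` log-likelihoods.

## Calibration

`bfgrm()` maximizes the marginal likelihood by Bock–Aitkin EM. The bifactor
structure factors the `G+1`-dimensional person integral into a product of
conditional one-dimensional integrals over each group factor inside an
outer integral over the general factor, so only two-dimensional quadrature
grids are ever formed. Quadrature uses 21 equally spaced points per
dimension on `[−6, 6]` with normal-density weights renormalized to sum
to one — standard fixed-grid practice, accurate for slopes well beyond the
ranges generated here.

The E step produces expected category counts on each item's (at most
two-dimensional) grid; the M step maximizes each item's expected complete
log-likelihood with L-BFGS-B using analytic gradients. Intercept
monotonicity is enforced by reparameterizing the gaps on the log scale, and
a candidate step that would decrease the item's objective is rejected in
favor of the incumbent, which preserves the EM ascent property (the
observed-data log-likelihood trajectory is checked to be nondecreasing in
the tests, slack `1e-8`). Convergence is declared when the largest absolute
parameter change falls below `1e-4` or the log-likelihood change below
`1e-6`, with a 500-cycle cap; hitting the cap flags the result as
non-converged rather than failing silently.

Missing responses are handled by full information: a missing entry
contributes a factor of 1 to the person likelihood and nothing to the
expected counts. Categories never observed in the data cannot be estimated;
by default they are collapsed into the adjacent lower category with a
warning (`unobserved = "error"` turns this into a hard error).

One identification fact discovered while validating the estimator, worth
recording: when data carry *no* group variance (all group slopes truly
zero), freeing a bifactor structure with small group clusters leaves
single-item group slopes weakly identified — at `n = 2000` spurious group
slopes near 1 appear without materially changing the likelihood. The test
suite therefore checks the unidimensional *reduction* of the EM (fitting
the general-only structure, which matches an independently coded 1-D EM to
about `3e-5`), and separately checks that the free-structure fit's general
slopes still track the truth.

## Local dependence screening

Yen's Q3 is the correlation, over persons observing both items, of
observed-minus-expected residuals. The residual uses the model-implied
expected score at the person's full-pattern MAP estimate — the estimator
the rest of the pipeline uses. Pairs with fewer than 3 joint observations
are reported as unavailable. Two choices the literature leaves open are
fixed here and exposed as arguments:

* flagging uses *signed* Q3 above the threshold (default 0.20), with an
  `absolute = TRUE` option. Note that MAP-based residuals of items sharing
  a group factor carry a structural negative bias (we measured down to
  about −0.18 with 3–6-item group factors at `n = 2000`), which signed
  flagging is immune to;
* the "information" used to pick the pair member to drop is the trace of
  the item's Fisher information integrated over the standard-normal prior
  on its loaded dimensions — a global summary rather than a point
  evaluation at `θ = 0`.

Flagged pairs are processed greedily in descending Q3 order (ties broken by
item index); a pair already resolved by an earlier removal is skipped,
otherwise its lower-information member is removed. An information tie drops
the later item. `srmsr()` supplies the residual-correlation fit summary:
observed pairwise Pearson correlations versus model-implied ones obtained
by quadrature over each pair's shared dimensions. Limited-information fit
indices (M2-based RMSEA/CFI) and item-level S-X2 are deliberately out of
scope.

## Scoring and the adaptive engine

MAP estimation maximizes `log L(x | θ) − ‖θ‖²/2` by damped Fisher scoring
(expected information plus the prior precision as the Newton matrix, step
halving on the log-posterior, box `[−6, 6]` per dimension, derivative-free
fallback). Expected — not observed — information is used both for the
standard errors and the selection rule: it is smooth, always positive
semidefinite, and conventional in adaptive-testing engines; observed
information is available behind `type = "observed"` and typically moves
SEs in the third decimal. Dimensions no administered item loads on stay
exactly at the prior mode with SE 1.

Item selection is the determinant rule: maximize
`det(info + w_i a_i a_iᵀ)` over unadministered items, where `w_i` is the
item's scalar information weight at the current estimate. Because each
per-item information is rank-1 and the posterior information matrix is an
"arrow" matrix (general factor coupled to each group, groups mutually
uncoupled), both the determinant ratio and all standard errors are computed
in `O(D)` via the Schur complement; the tests verify every selection
against brute-force determinant enumeration. Ties go to the lowest item
index. With an empty state the rule is evaluated at `θ = 0` with prior-only
information, so the starting item is the same for every respondent.

Stopping is checked after every response and rescoring step, including
after the first item (only the SE rule can fire there — the change rule
needs two estimates to compare). All thresholds are strict inequalities.
The SE rule requires *every* supplied threshold simultaneously: general SE
below `se_general` and, when present, each group-dimension SE below
`se_group`. The change rule fires when the largest absolute change across
all `D` dimensions between consecutive estimates falls below
`theta_change`. The rules combine disjunctively, and item exhaustion always
terminates. A group dimension never yet probed has SE exactly 1, so a group
threshold of 0.50 mechanically forces sampling from every group factor —
this is why the factorial rows that impose it administer (nearly) the whole
bank regardless of the general-factor threshold, and why those row pairs
produce literally identical records.

The bundled design (`table3_design()`) crosses general-factor SE
`{0.32, 0.40}` × group-factor SE `{0.50, none}` × change `{0.01, none}`,
plus a no-termination "full" row. The SE levels correspond to classical
reliabilities `1 − SE²` of 0.90, 0.84 and 0.75 (0.84 is exactly
`1 − 0.40²`; the conventional pairing "0.85" rounds it up). The engine
draws no random numbers: all stochasticity lives in the generator, and
identical inputs give identical outputs.

## The synthetic-data generator

The generator produces the three study inputs: true traits (`n × D`
independent standard normals), an item bank, and complete GRM response
matrices (optionally thinned completely at random for calibration tests).
Each draw runs in a private RNG stream keyed by its own seed, so changing
one input leaves the others bit-identical.

The default bank emulates the post-screening shape of a 44-item HRQOL
inventory: ten group factors holding 6/4/3/3/5/4/5/3/4/4 items plus three
general-only items, a mixed 2/3/5/6-point response format, general slopes
uniform on `[0.92, 4.71]`, group slopes uniform on `[0.56, 5.19]`, and
boundary difficulties spread over `[−2.5, 2.5]` (sorted uniforms with a
0.1 minimum gap, converted to intercepts with the loading norm). The three
items whose domain assignment a 44-item reduction leaves ambiguous default
to general-only; the counts, categories and ranges are all configurable
through `bank_spec()`.

What the generator does *not* emulate — and hence what passing tests do
not show about real questionnaire data: model misfit of any kind
(responses are exact GRM draws), residual local dependence, non-normal or
correlated trait distributions, informative missingness, and the covariate
structure of a clinical sample. Uniform slopes in the reported ranges also
make the synthetic bank somewhat *more* informative per item than a real
calibrated inventory, so adaptive runs on it stop earlier (median ≈ 16
items under the 0.32 rule) than a real bank would; the factorial
*orderings* — which rows stop earlier, which pairs coincide, the U-shaped
relation between items used and trait extremity — are the transportable
findings, not the absolute medians.

## Evaluation conventions

Item reduction is computed from the *mean* administered count,
`100 (1 − mean/J)`; the IQR is the interpolated 25th–75th percentile
(`quantile` type 7); the general-factor SE summary is taken at termination,
per respondent. Correlation and RMSD are reported per dimension and as
across-group-factor means; a dimension whose estimates never left the
prior mode has an undefined correlation and is reported `NA` (and excluded
from the across-factor mean) rather than erroring a whole summary.

## Problem sizes and runtime

The test suite calibrates at `n = 2000` persons × 20 items (two group
factors) for recovery, `n = 800` for the faster unit variant, and runs the
full nine-row factorial at `n = 1000` respondents × 44 items — the same
respondent count the simulation design prescribes. On one CPU the whole
suite runs in roughly ten minutes, the nine-row factorial accounting for
about four.

## Known limitations

* No standard errors for item parameters, no multiple-group or invariance
  estimation, no EAP/ML scoring, no exposure control or content balancing.
* Fixed rectangular quadrature; slopes far above the generated ranges
  (`a > ~6`) would warrant adaptive quadrature.
* The Q3 threshold is applied to signed values by default; users wanting
  the absolute-value convention must opt in.
* Screening compares items by one scalar (prior-integrated information
  trace); banks with items informative in disjoint trait regions may
  deserve a range-restricted comparison.
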