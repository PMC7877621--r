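---
title: "Methods: stochastic portfolio decision analysis for vaccine platform investments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic portfolio decision analysis for vaccine platform investments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxpda)
```

## The decision problem

A funder must select a subset of early-stage vaccine platform projects under
a hard budget (US$140m by default) so that the *portfolio* — not any single
project — maximizes the chance of a usable rapid-response capability.
Three features make this a stochastic, non-linear selection problem:

1. **Project success is uncertain and expert-elicited.** Each project's
   probability of success (PoS) is the product of seven factor
   probabilities, each encoded by reviewers as a (worst, most-likely, best)
   triple, i.e. a triangular distribution.
2. **Value accrues at the platform level.** What matters is the probability
   of *at least one* success per platform type,
   $POS_{\ge 1}(k) = 1 - \prod_i (1 - \tilde p_{ik})$, which is concave in
   the number of selected projects.
3. **Stakeholders weight platforms non-linearly.** A discrete choice
   experiment (DCE) shows decreasing returns: the utility of moving
   $POS_{\ge 1}$ from 0 to a middle level $b$ exceeds the further gain from
   $b$ to the upper level $c$ for every platform.

The portfolio value draw in iteration $m$ is
$\tilde V_p = \sum_k \tilde w_k \cdot \widetilde{POS}_{\ge 1}(k)$, where
$\tilde w_k$ is the piecewise preference weight evaluated at that
iteration's realized $\widetilde{POS}_{\ge 1}(k)$ using that iteration's
Normal draws of the part-worth coefficients.

## Monte Carlo design: common random numbers

One PoS draw matrix (iterations × projects) and one coefficient draw matrix
are generated per analysis and reused for *every* portfolio evaluation.
Consequences:

- portfolio comparisons (optimization, frontier, dominance, rank
  probabilities) reflect structural differences only, never sampling noise;
- adding a project can never decrease an iteration's $POS_{\ge 1}$, which
  the test suite asserts per iteration;
- re-running any solver with the same seed returns the identical portfolio.

All stages draw from substreams derived deterministically from one master
seed and a purpose label (`derive_seed()`), so enlarging one stage never
perturbs another. Triangular sampling is inverse-CDF, making draws a
deterministic function of the underlying uniform stream; degenerate triples
(worst = best) are point masses, accepted everywhere.

Default iteration counts: 10,000 for reported analyses (the convention for
this type of elicitation study); the test-suite and solver-agreement runs
use 2,000, and unit fixtures far less — enough for the Monte Carlo
tolerances asserted (e.g. triangular means within 0.005 at $n = 10^5$).

## The preference model

**Coding.** The conditional logit uses cumulative (level-threshold) coding:
$X_b(k) = 1$ when an alternative shows level $b$ *or* $c$ on platform $k$,
and $X_c(k) = 1$ only at level $c$. Then $\beta_c(k)$ is literally the
increment from the middle to the upper level, matching how the published
coefficient table is labelled. Simple dummy coding would change the
coefficients' meaning.

**Estimation.** Fitting is by stratified Cox partial likelihood
(`survival`), which with exactly one chosen alternative per stratum equals
the exact conditional (multinomial) logit likelihood. Standard errors come
from the inverse observed information; AICc and BIC use the number of
choice sets as the sample size. Columns without variation are dropped (NA
coefficients); collinear codings raise an error naming the columns;
non-finite or runaway estimates (|β| > 15) raise a separation error. An
independent grid-search likelihood oracle cross-checks the MLE in the test
suite.

**The piecewise weight (and its edge cases).** For levels $a = 0 < b < c$:
$w = \beta_b/(b-a)$ when $pos \le b$, else
$w = (\beta_b + \beta_c (pos-b)/(c-b))/pos$. At $pos = 0$ the lower-branch
constant is returned (the value contribution $w \cdot pos$ is 0 either
way). Beyond $c$ the upper linear segment is continued and the result is
flagged `extrapolated` — with the default levels informed by *initial*
(optimistic) assessments, final-stage $POS_{\ge 1}$ rarely exceeds $c$.
Negative fitted part-worths (the mAb upper increment) are retained;
they make portfolio value locally non-monotone above $b$ on that platform,
which the tests assert as the documented exception.

**Coefficient uncertainty.** Draws default to independent
Normal(estimate, SE) per coefficient, mirroring how such coefficient
distributions are typically propagated; a multivariate mode using the
fitted covariance exists because logit estimates are correlated. The
published coefficient table is available as `default_part_worths()` and is
the default data-generating truth of the synthetic DCE.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes:

- **Roster**: 16 projects in platform groups of 4/4/3/3/2, budgets uniform
  on US$6–65m rounded to 0.1 (the published study gives only the range and
  median, not the generating law; uniform is the neutral choice).
- **Reviewer assignment**: pool of 27, 4–5 reviewers per project, by a
  randomized load-balanced greedy fill with a counting feasibility
  pre-check. The stated margins (each reviewer 3–4 projects) cannot all
  bind simultaneously — 16 × 4…5 = 64–80 slots but 27 × 3 = 81 minimum —
  so the per-reviewer maximum is a hard cap while the minimum holds only as
  far as the margins allow; balanced filling keeps loads near-uniform.
- **Assessments**: most-likely values from a Beta(6, 2) prior (mean 0.75,
  giving seven-factor products of a few percent — low, overlapping PoS, as
  observed in this field), worst/best as uniform half-widths up to 0.15,
  clipped to [0, 1]. "Final" assessments shrink all three points by
  $1 - \text{optimism\_shift}$ (default 0.2): the published pattern is that
  estimates fall after face-to-face review, without a stated mechanism;
  multiplicative shrinkage is the simplest order-preserving one.
- **Choices**: conditional-logit sampling from true part-worths, so
  estimation can be validated by simulation-recovery (coefficients within
  ±0.1 at 5,000 participants; pooled 95% Wald coverage between 90 and 100%
  over 50 replicate studies).

What it does **not** emulate: correlated factor beliefs within or across
reviewers, reviewer-specific optimism or calibration, platform-correlated
budgets, or real respondents' inattention. Passing tests therefore show the
*pipeline* is correct under the assumed structure, not that the structure
captures any particular real review process.

The DCE design generator is randomized-balanced (per-platform level
frequencies within ±1 across the design, with balance and co-occurrence
diagnostics), not D-optimal: the original design came from commercial
software, and only balance/orthogonality assessment is described for it.
Dominance and repeat probes are detected from the realized design; when a
random design contains none, validity checks report "not applicable"
rather than failing.

## Optimization

**Enumeration (oracle).** All subsets up to 24 projects; infeasible subsets
discarded; the objective is either the mean or the inverted-CDF (type-1)
empirical quantile of the value draws — type 1 because it is exactly
reproducible with no interpolation. Evaluation exploits separability:
portfolio value is the sum over platforms of per-member-subset
contribution vectors, precomputed once (at most $2^4$ per platform), so the
full 65,536-subset scan costs seconds. Ties are broken by lower cost, then
by the lexicographically smallest selection vector — fully deterministic.

**Evolutionary algorithm (scalable path).** Binary chromosomes; tournament
selection (size 3), uniform crossover (rate 0.9), per-bit mutation
(default 1.5/n), elitism of one, death penalty (−∞) for budget-infeasible
chromosomes, memoised evaluations on the shared draws. Premature
convergence is countered by re-randomizing the non-elite population after
every 20 stale generations (diversity reintroduction); the search stops
after 250 generations or 80 stale generations. The empty portfolio seeds
the population as an always-feasible anchor. On the default 16-project
conditions the GA matched the enumerated optimum in 99–100 of 100 seeded
instances during development, and by construction can never exceed it.

**Chance constraint.** The published description of the VaR setting is
ambiguous (a 95th-percentile objective versus a 5th-percentile worst-case
reading). The default maximizes the empirical 0.95 quantile of $\tilde
V_p$, with the level configurable (0.50–0.90 for comparison runs) and the
expected-value objective retained; the two readings are one `q` value
apart.

## Uncertainty analysis

Feasible alternatives under the budget are enumerated exactly (all
non-empty subsets with cost ≤ B; a strict-< flag covers the "under the
budget" reading). This replaces perturbed-budget re-optimization sweeps
with a complete and cheaper scan at n = 16.

Dispersion statistics per portfolio: population variance, below-mean
semivariance, mean absolute deviation, and the Gini mean difference
$\Gamma = E|X - X'|/2$ (Yitzhaki convention, so $\mu - \Gamma$ is the
mean-Gini criterion), computed by the rank identity
$E|X-X'| = \frac{2}{n^2}\sum_i (2 r_i - n - 1) x_i$ — $O(n \log n)$ and
equal to the naive double loop to $10^{-10}$, ties included. Mean-risk
dominance needs ≥ on the mean, ≤ on the risk, one strict; mean-Gini
dominance analogously on $\mu$ and $\mu - \Gamma$.

Pairwise rank probabilities count ties as half-wins, so
$P(a \succ b) + P(b \succ a) = 1$ exactly. The outranking report bands
alternatives (default (0.5, 0.75], (0.75, 0.9], (0.9, 1]) and profiles
project inclusion per band, the composition view of robustness.

**A caveat found during development.** Majority outranking is an empirical
property, not a consequence of optimality: a portfolio maximizing a tail
quantile — and occasionally even the mean, since $E[A] > E[B]$ does not
imply $P(A > B) > 1/2$ for skewed differences — can lose a pairwise
majority against a close rival on some synthetic draws. The acceptance
check therefore asserts the property for the expected-value optimum on the
default analysis run, and reported minima should be read per run (they were
between roughly 40% and 67% across seeds explored), just as a single
published minimum of this kind is a per-dataset result.

## Known limitations

- Uniform reviewer mixture only; no reviewer calibration or weighting.
- Factors sampled independently within an iteration (the factors were
  defined to be consequentially independent; real beliefs may correlate).
- No time-phasing, partial funding, or cross-platform interdependencies
  beyond the $POS_{\ge 1}$ grouping.
- Enumeration is capped at 24 projects; beyond that only the GA path
  scales, losing the exactness guarantee.
- First- and second-order stochastic dominance over full CDFs are out of
  scope; the mean-risk screens are necessary-condition filters.
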