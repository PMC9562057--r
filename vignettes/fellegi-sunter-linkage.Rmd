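---
title: "Probabilistic record linkage with missing data: the model behind fslink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic record linkage with missing data: the model behind fslink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fslink)
```

## The problem

Patient records scattered across clinical systems rarely share a reliable
unique identifier. Deciding whether two records refer to the same person must
then rest on partial identifiers — name parts, birth-date components, SSN,
address, telephone — all of which are noisy and, in real clinical data,
frequently missing (values coded "unknown", identifiers withheld for privacy,
fields that simply do not exist for a patient). `fslink` implements the
Fellegi–Sunter latent class approach to this problem, with particular care
for two practical questions: how missing field comparisons enter the
likelihood, and how the set of matching fields is chosen.

## The model

For candidate pair $i$ let $\delta_i \in \{0,1\}$ be the unobserved true
match status and $y_i = (y_{i1},\dots,y_{iK})$ the vector of field
comparisons, each agree (1), disagree (0) or missing. The parameters are the
match prevalence $\rho = P(\delta_i = 1)$ among the candidate pairs and, per
field, the m- and u-probabilities

$$m_k = P(y_{ik} = 1 \mid \delta_i = 1), \qquad
  u_k = P(y_{ik} = 1 \mid \delta_i = 0).$$

Within each class the $K$ comparisons are assumed conditionally independent,
so the class-conditional density of a pattern is a product of Bernoulli
terms and the marginal log-likelihood of the observed matrix is

$$\ell(\rho, m, u) = \sum_i \log\bigl[\rho f(y_i \mid m)
   + (1-\rho) f(y_i \mid u)\bigr].$$

No training labels are used: `fs_fit()` maximizes $\ell$ by EM. The E-step
computes each pair's posterior match probability by Bayes' rule; the M-step
replaces $\rho$ with the mean posterior and each $m_k$, $u_k$ with
posterior-weighted agreement rates. The fitted object carries the
log-likelihood trace (monotone by construction, and asserted in the tests),
posteriors, and convergence diagnostics.

## Two treatments of missing comparisons

A comparison is missing whenever either record lacks the field; both-missing
is also treated as missing, never as agreement. Two estimation treatments are
provided:

* **MAD (missing as disagreement).** `zero_fill()` recodes every missing
  comparison as 0 and the complete-data machinery runs unchanged. This is the
  common pragmatic strategy; it implicitly assumes the missing value would
  have disagreed, which is wrong for true matches and drags $\hat m_k$
  (and $\hat u_k$) downward. The direction of this bias is asserted in the
  test suite: under class-independent masking, $\hat m_k^{MAD} <
  \hat m_k^{MAR}$ in essentially every replicate.
* **MAR (missing at random).** The full-information likelihood: missing
  components simply drop out of the product (contribute factor 1), and the
  M-step weighted means run over the pairs with the field observed. This is
  consistent under MCAR and under missingness that depends only on observed
  information or the latent class; it is *not* consistent when missingness
  depends on the hidden comparison outcome itself (MNAR) — the generator can
  produce such data precisely so the resulting bias can be demonstrated.

On a complete matrix the two treatments are algebraically identical, and the
package implements them through one code path so the fits are bit-identical
— a property the acceptance tests check.

## Scoring and classification

A pair's match score is the log likelihood ratio
$\sum_k \log\frac{P(y_{ik}\mid\text{match})}{P(y_{ik}\mid\text{nonmatch})}$,
summed over observed fields under MAR (an all-missing pair scores exactly 0)
and all fields under MAD. The score is a strictly increasing function of the
posterior — `exp(score)` equals posterior odds over prior odds, an identity
tested to 1e-10 — so thresholding scores is equivalent to thresholding
posteriors. The threshold is the upper-$\hat\rho$ quantile of the block's
empirical score distribution, taken as the $\lceil n(1-\hat\rho)\rceil$-th
ascending order statistic; a pair is a match iff its score is *strictly*
greater, so ties at the threshold are nonmatches. (Sample-quantile
conventions differ by at most one pair; the conservative strict rule is
fixed here for determinism.) When all scores tie — e.g. a one-field block —
nothing clears the threshold and the block contributes no matches; the union
over blocks compensates, which mirrors why several blocking schemes are run
at all.

Each block is fitted and thresholded with its own $\hat\rho$, and the final
match set is the union of the per-block match sets (`union_matches()`), with
provenance retained.

## Blocking

Candidate pairs are those agreeing exactly on every variable of a blocking
scheme (`block_pairs()`), implemented by hash-grouping on the concatenated
canonical key. A record missing any blocking variable cannot exactly agree
on it and is excluded from that scheme — one more reason a single scheme is
never sufficient. Self-pairs are excluded, each unordered pair is emitted
once, and an optional per-block size cap warns (never errors) on
pathological blocks.

## Field screening and data-driven selection

For each block, candidate matching fields are screened
(`screen_fields()`): the block's own blocking variables are removed (inside
the block they agree by construction), as are fields with 100% missing
comparisons and fields with no variability among observed comparisons.
Expert mode stops there, using the configured list. Data-driven mode
(`select_fields()`) then fits the model on the full surviving set and, while
the fit is unhealthy, drops the least-variable field and refits.

Two working definitions had to be fixed here, as the underlying procedure
leaves them open:

* **Variability** of a comparison column is `min(p, 1 - p)` with `p` the
  observed agreement proportion — the simplest distance-from-constancy, 0
  for a constant column and 0.5 for a balanced one. The per-field values are
  recorded so alternatives can be compared offline.
* **An unhealthy fit** (`fs_fit_ok()`) is one that hit the iteration cap,
  pinned any probability at the clamping boundary, or estimated a degenerate
  prevalence $\hat\rho < 10/n$. These are the observable failure modes of EM
  on over-parameterized or uninformative field sets; boundary pinning is by
  far the most common in practice (e.g. a field observed in a handful of
  pairs that all agree).

One field is dropped per iteration, ties broken lexicographically, so the
procedure is deterministic and the drop log partitions the candidates by
reason.

## Numerical choices

* Initialization: $\rho_0 = 0.1$, $m_{k0} = 0.8$, $u_{k0} = 0.2$ — generic
  values encoding only "agreement is likelier among matches". Optional
  multi-start (`n_starts`) jitters the start and keeps the best final
  likelihood, guarding against the mixture's local optima.
* Clamping: all probabilities are clamped to $(10^{-6}, 1-10^{-6})$ each
  M-step so log-densities stay finite; scores are computed with the same
  clamped estimates, never re-clamped.
* Convergence: relative change in the marginal log-likelihood below
  $10^{-8}$, capped at 1000 iterations.
* Label switching: the mixture is invariant under
  $(\rho, m, u) \to (1-\rho, u, m)$; `orient_classes()` picks the
  representative with $\sum_k \log(m_k/u_k) \ge 0$ so "match" is the class
  favouring agreement.
* All density work is in log space with log-sum-exp posteriors.

## Evaluation

Predicted matches are compared against a reviewed gold standard of pairs
(`confusion_counts()`); gold pairs never produced by any block are predicted
nonmatches by construction. `linkage_metrics()` reports sensitivity,
specificity, PPV, NPV and F1, with zero-denominator metrics reported as
`NA`, never 0. `bootstrap_metrics()` attaches percentile confidence
intervals from resampling gold pairs with replacement (default 999
replicates). Since every metric depends on the gold rows only through the
2×2 table, the resampling is realized exactly as a multinomial draw over the
four cells — same distribution, constant cost in the gold size. Coverage of
the resulting intervals is checked by simulation in the test suite.

## The synthetic generator

Real linkage data of this kind are protected health information, so the
package validates itself on two tiers of synthetic data whose generative
structure is exactly the model's:

* `simulate_agreement()` draws $\delta_i$, then conditionally independent
  agreements, then masks cells under MCAR, class-dependent MAR, or
  value-dependent MNAR. This tier tests the estimator in isolation:
  parameter recovery, bias directions, treatment comparisons.
* `simulate_records()` plants duplicate records (per-field perturbation and
  masking) in synthetic identity files with pools sized to mimic strong
  (SSN, telephone), moderate (names, zip) and weak (sex, birth components)
  identifiers, and emits ground truth. This tier exercises the whole
  pipeline: blocking, comparison, selection, fitting, classification,
  union, evaluation.

A single root seed spawns per-component sub-seeds, so outputs are
byte-reproducible and adding a mechanism does not shift other draws.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: correlated fields (real addresses and phones move
together; the model itself assumes conditional independence), typographical
error structure (swaps are uniform over the pool, not keyboard- or
phonetically-shaped), family/household clustering, and drift in data quality
across sources. Validation sizes were chosen to keep the full suite under a
minute of simulation per property: n = 50,000 pairs for consistency checks,
50 seeded replicates for directional claims, 5,000 entities for the
end-to-end fixture, and a coarse-plus-refined exhaustive grid (steps 0.025
then 0.01) as the independent optimum oracle on tiny two-field instances.

## Known limitations

* Exact-equality comparison only; no string-similarity comparators.
* Conditional independence is assumed, not tested; highly correlated field
  sets degrade accuracy and are the main reason field selection exists.
* Single-threshold decisions; no possible-link review zone and no
  one-to-one assignment post-processing, so one record may match several.
* Small blocks (tens of pairs) often pin $\hat u_k$ at the boundary and
  lose fields to the selection loop, occasionally contributing zero matches;
  rely on the union over schemes rather than any single small block.
* MNAR missingness biases every estimate; only detectable here by
  simulation, not from the data.
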