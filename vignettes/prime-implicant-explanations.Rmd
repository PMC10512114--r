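---
title: "Compiling random forests into decision diagrams for exact, range-based explanations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling random forests into decision diagrams for exact, range-based explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primo)
```

# Scope and model

`primo` targets a specific but representative setting: a binary classifier
for early prediction of clinically meaningful weight loss (at least 7% of
body weight at six months), realized as a random forest of 13 trees with
maximum depth 3 over five continuous self-monitoring features captured in
the first two weeks of treatment:

| feature | units |
|---|---|
| average weekly weight change | % |
| average daily food entries | items |
| average daily fat | g |
| average daily custom food entries | items |
| average daily saturated fat | g |

Everything downstream depends only on the forest being (a) an ensemble of
axis-aligned threshold trees and (b) aggregated by a **hard majority vote**
over per-tree leaf labels. Probability averaging is deliberately out of
scope: the propositional reduction is defined over votes, and the import
shim for externally trained forests takes each leaf's majority class. With
an even number of trees a tie votes "negative" — conservative for a success
label — and this is tested, not assumed.

Feature values are stored and compared in **natural units**. The z-score
scale familiar from cohort tables is an ingest/display affordance handled by
an affine map `natural = z_mean + z * z_sd` per feature; thresholds must
live in exactly one canonical space or routing and discretization would
drift apart.

# From forest to discrete function

All thresholds of a feature, collected over every node of every tree and
deduplicated by **exact float equality**, induce the half-open intervals
`(-Inf, t1), [t1, t2), ..., [tk, Inf)`. Exact equality (rather than a
tolerance) is intentional: thresholds come from one training run, and
merging near-equal thresholds would silently change the function being
explained. The boundary convention is left-closed — a value equal to a
threshold belongs to the interval whose left edge it is — matching the
routing rule "`x >= t` goes high". The convention at `x == t` is not fixed
by the underlying method description, so we fix it once, document it here,
and test boundary membership explicitly.

A **cell** (one interval index per feature) is the discretized instance; the
forest is constant on each cell, which the test suite verifies by sampling
points inside random cells. Each feature is a **multi-valued variable**
(one value per interval) rather than a bank of one-hot Boolean variables
with mutual-exclusion constraints; the indicator of each value recovers the
binary-variable-per-interval view while keeping the diagram canonical and
free of encoding clauses.

# Compilation

Trees compile by if-then-else over interval literals: a test `x_i >= t`
becomes the set of interval values at or above `t`. Forests compile by
dynamic programming over the trees, maintaining diagrams for "at least `c`
positive votes among the first `k` trees", truncated at the majority
threshold `floor(n_trees / 2) + 1` since higher counts saturate. This is
polynomial in the number of trees; expanding the majority gate into all
majority subsets would not be.

The diagram is a reduced ordered decision diagram over the multi-valued
features, with a unique-node table enforcing reduction at construction.
Canonicity — equal functions get identical diagrams under a shared manager —
is what makes equivalence checks O(1) and is itself tested by compiling
structurally different but equivalent trees. The **variable order** defaults
to the feature order of the forest specification and is configurable but
never dynamically reordered: with five variables, order optimization buys
nothing and determinism aids testing and reproducibility.

Correctness does not rest on construction-time invariants alone. The
package carries two independent full-grid evaluators: forest votes
accumulated straight from the tree structures by array broadcasting, and a
level-sweep evaluation of the diagram. `check_equivalence()` compares them
on *every* cell — around 10^6 cells for a trained 13-tree forest — in a few
seconds, and the acceptance suite does this for 50 forests (47 with random
structure over compact threshold pools, which keeps the product space small
while varying the decision functions; 3 trained on full 419-row cohorts at
roughly a million cells each). Those problem sizes are the package's chosen
test conditions: large enough to exercise every code path exhaustively,
small enough to re-run on every test invocation.

# Explanations

A **prime implicant** is a minimal partial assignment of features to
intervals whose every completion receives the same label. The explanation
for an instance is the **shortest prime implicant compatible with it**:
subsets of features are scanned in increasing cardinality (lexicographic
within a cardinality, which makes ties deterministic across platforms), and
the first subset whose restriction of the instance's cell is sufficient
wins. Minimum cardinality implies primality — any proper subset would have
been found earlier — so no separate primality check is needed on this path.
Subset enumeration is exact and cheap at five features (2^5 subsets);
beyond about twelve features a branch-and-bound on the diagram would be the
defined escape hatch, but that regime is outside this package's scope.

Displayed **ranges** are a separate, clearly labeled post-process: base
implicants assign single intervals, and each assigned feature is then
greedily extended — in variable order, left first, then right — to the
maximal contiguous run of intervals containing the instance's interval such
that the set-valued assignment remains sufficient. Greedy order matters for
which maximal region is reported (regions are not unique), but per-feature
boundary maximality holds regardless and is verified by probing: adding one
interval past any reported boundary admits a counterexample cell.

Inside the displayed ranges the **prediction** provably cannot change; the
test suite fuzzes hundreds of instances against this guarantee. A stronger
claim — that the *explanation itself* is also invariant inside the ranges —
does not hold in general: a different shortest implicant can become
compatible elsewhere in the region. The package guarantees prediction
invariance and makes no claim about explanation stability.

Degenerate inputs behave sensibly: a constant classifier yields the empty
implicant and zero ranges (every feature annotated "no constraint"); a
feature never tested by the forest has a single interval `(-Inf, Inf)` and
can never be assigned.

# Baseline metrics

Two baseline explanation styles are implemented for comparison studies.
**Monotonicity** of a feature: the percent of instances whose binary
prediction sequence, as the feature sweeps its ordered intervals with the
others held fixed, has at most one transition. "At most one transition" is
the only order-theoretic reading of monotone available for binary outputs.
The instance set is a parameter because the original description does not
state one: the default is every cell when the product space has at most
10^5 cells and a seeded uniform sample of 10,000 cells otherwise, so results
are exhaustive where feasible and reproducible otherwise. A single-interval
feature is vacuously monotone (100, flagged).

**Best–worst case** for a (feature, interval) pair: the proportion of
completions of the remaining features classified positive versus negative.
"Proportion of feature vectors" is ambiguous between the uniform cell
measure and the data distribution, so both are offered: the default is
uniform (a single model count, deterministic), with empirical weighting over
dataset rows optional; the empirical variant refuses to divide by zero when
no rows fall in the interval.

# The synthetic cohort generator

The original 419-participant cohort is not public. The generator emulates
its *structure*, not its data: five correlated features drawn multivariate
normal on the z-scale, mapped to natural units through affine maps recovered
by least squares from the four published archetype instances (each printed
as z-score and natural value; the fits reproduce all twenty pairs to better
than 0.01 z-units), and a binary outcome from a logistic model on the
z-features whose intercept is calibrated by bisection so the cohort's mean
predicted probability equals the target prevalence.

Defaults are study conditions where printed, assumptions where not, and they
are set once:

- `n = 419` (the published training-set size);
- prevalence `0.29`: the only value consistent with the printed accuracy
  (0.81), sensitivity (0.69) and specificity (0.86), since
  `0.69 p + 0.86 (1 - p) = 0.81` gives `p ≈ 0.294`;
- coefficient signs: negative on weekly weight change and both fat intakes
  (more early loss, less fat — more success), positive on both engagement
  counts, matching the direction findings reported for these predictors;
  magnitudes (−1.5, +0.6, −0.8, +0.4, −0.5 on the z-scale) are assumptions
  chosen so the study-size forest lands near 80% held-out accuracy;
- correlation 0.3 between the two fat variables and between the two
  engagement counts, 0 elsewhere — plausible, stated, overridable.

What the generator does **not** emulate: the longitudinal two-week
trajectories the features were summarized from, missingness, the original
10-feature superset, and the true (unpublished) feature distributions and
correlations. Passing tests therefore show that the *machinery* is correct
on cohorts with this structure; they do not validate the clinical model
against real data, and held-out accuracy near the printed 81% is a
qualitative analog, not a reproduction.

# Agreement statistics

The expert-evaluation analysis models binary agreement outcomes on
explanation method with a logit link. Published aggregate counts are
reconstructed from printed percentages and denominators by
`counts_from_percent()`, which errors unless the recovered integer re-rounds
to the printed percentage — a consistency check, not a convenience. On
aggregate counts the model is the grouped-binomial GLM, whose coefficients
are exactly the marginal odds ratios; the likelihood-ratio test is the
closed-form grouped-binomial LRT. This is the zero-random-effect limit of
the mixed model used on participant-level data, and it is the appropriate
desk reproduction here because the published intraclass correlation for
these outcomes is below 0.01. Outcomes with substantial reported ICC (0.18
for switching to agree) cannot be reproduced from aggregates — the random
effect matters and participant-level data are not printed — so they are
exercised only as simulation scenarios: `simulate_responses()` draws
participant intercepts Normal(0, sigma^2) and `fit_agreement_model(...,
random_intercept = TRUE)` (adaptive Gauss–Hermite quadrature, 7 points)
recovers known odds ratios within 10% and the ICC within 0.05 at 5,000
simulated participants. Confidence intervals are Wald on the log-odds
scale throughout.

# Numerical choices, in one place

- Threshold dedup: exact float equality; forest JSON serializes doubles at
  17 significant digits so round trips are bit-exact.
- Boundary convention: value equal to a threshold goes to the
  right (left-closed intervals), consistently in routing, discretization,
  and literals.
- Cell representatives: interval midpoints; `edge ± 1` for unbounded ends;
  `0` for untested features — always strictly interior, so representatives
  discretize back to their cell.
- Tie-breaks: even-ensemble votes → negative; equal-length shortest
  implicants → lexicographically smallest feature-index set; widening →
  variable order, left before right.
- Intercept calibration: bisection on `[-30, 30]` to tolerance 1e-10 on the
  mean predicted probability.
- Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; identical configuration gives byte-identical
  artifacts.

# Limitations

The compiler is built for small, depth-limited ensembles — the regime where
exact explanations are tractable and clinically useful. Diagram size can
grow quickly with tree count and depth (the equivalence oracle's full-grid
scan grows with the product of interval counts as well), and no dynamic
variable reordering is attempted. Explanations are exact with respect to
the *model*, not the world: a prime implicant describes the forest's
decision boundary, and its clinical meaning is only as good as the model's
calibration. Multiclass outcomes, soft voting, missing-value routing, and
counterfactual (minimum-change) explanations are out of scope.
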