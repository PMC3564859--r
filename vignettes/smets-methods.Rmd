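---
title: "SMETS: comparing multivariate time series of unequal dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SMETS: comparing multivariate time series of unequal dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smets)
```

## The problem

A dynamic model — a biochemical network simulated from its differential
equations, a basket of stocks, a multichannel physiological recording —
produces a *multivariate* time series: a set of named univariate component
traces observed at common time points. Asking which of several such models
behaves most similarly to a reference is a distance problem, but the
standard multivariate distances are only defined when both series have the
same number of components. Collapsing each group to its (weighted) average
trace makes any pair comparable at the price of discarding almost all
component-level structure: two models whose averages coincide can have
entirely different internal dynamics.

SMETS (Semi Metric Ensemble Time Series) compares two multivariate series
of dimensions $n \le m$ using *all* components of both. This vignette
documents the model as implemented here, the tunable parameters, the
numerical conventions, the design choices that were genuinely open, and the
limitations a user should know about.

## The distance

### Component representation

Each univariate component is preprocessed independently:

1. **Z-normalization**: subtract the mean, divide by the population
   (divide-by-$q$) standard deviation, so only shape differences remain.
   A constant trace has zero spread and maps to the all-zero trace rather
   than raising an error — static variables are legitimate model behavior
   and central to the worked example below. The population form of the
   standard deviation is an arbitrary but fixed convention; every
   comparison uses it consistently and no result in this package is
   sensitive to the choice.
2. **Zero-padding** to a power-of-two length. All series entering one
   comparison or collection are padded to the *common* next power of two of
   the longest component, so that transform coefficients live in a single
   indexed space; this is also what makes series of different lengths
   comparable.
3. **Orthonormal Haar transform**: each level stores pairwise scaled
   averages $(a+b)/\sqrt2$ and differences $(a-b)/\sqrt2$; coefficients are
   ordered as the coarsest approximation followed by detail levels from
   coarse to fine. Orthonormality preserves total energy (Parseval,
   checked to $10^{-9}$ in the tests) and means Euclidean geometry in
   coefficient space is the geometry of the raw series.
4. **Top-$k$ retention**: keep the $k$ coefficients of largest absolute
   value together with their positions ($k = 16$ by default); magnitude
   ties break toward the lower index for determinism.
5. **Padding-bias truncation**: trailing zero-padding contaminates the
   trailing (finest-scale, latest-time) symbols, so retained symbols are
   removed from the end, in transform-index order, down to
   `truncate_to` (default $k-1 = 15$). Longer padding warrants deeper
   truncation (e.g. keeping 64 coefficients and truncating to 47 for
   series of 6000 points padded to 8192).

The distance between two component representations is the Euclidean
distance over the union of their retained positions, with positions absent
from one side contributing implicit zeros. Equivalently: each
representation densifies to a fixed vector in the padded coefficient
space, and distances are plain Euclidean distances between those vectors.
This embedding is what gives the component distance full metric structure.
Setting `wavelet = FALSE` in `smets_control()` skips steps 3–5 and
computes Euclidean distances on the raw normalized, padded traces instead.

### Matching, aggregation, penalties

Given the cross-matrix of component distances between series $A$
(dimension $n$) and $B$ (dimension $m \ge n$):

* **Greedy partial matching.** Repeatedly select the globally smallest
  remaining entry, record it, and delete its row and column, until the
  smaller series is exhausted. Each component of $A$ is matched exactly
  once; $m - n$ components of $B$ stay unmatched. Ties break
  lexicographically by (smaller-series index, larger-series index).
* **p-norm.** The $n$ matched distances $d$ are aggregated as
  $\lVert d\rVert_p = (\sum_i d_i^{\,p})^{1/p}$ with $p = n$, evaluated in
  scaled form ($\max d \cdot (\sum (d_i/\max d)^p)^{1/p}$) so large $p$
  cannot overflow.
* **Entropy penalty.** Every unmatched component $j$ carries $d_j$, its
  smallest distance to any component of $A$, read from the *full*
  pre-deletion matrix. Its weight is its share of Shannon entropy among the
  unmatched components, $w_j = H_j / \sum_k H_k$, so
  $EP = \sum_j w_j d_j$: high-information unmatched components dominate,
  constant traces ($H = 0$) contribute nothing, and $EP$ stays on the
  scale of a single component distance. If all unmatched entropies are
  zero, or nothing is unmatched, $EP = 0$.
* **Dimension penalty.** $P = (m-n)/(m+n) \in [0, 1)$: zero at equal
  dimensions, strictly increasing in $m$ for fixed $n$. It is what keeps
  two series apart when the extra components are pure constants and $EP$
  vanishes.
* **Combination.** $\mathrm{SMETS} = \lVert d\rVert_n + \sqrt{EP^2+P^2}$.
  The 2-norm coupling of the penalties deliberately weakens the dimension
  term: adding $P$ outright would make series of different dimensions
  never similar regardless of how well their components match.

Entropy is computed on the normalized, pre-padding values with exact value
frequencies by default: $H = -\sum_v f(v)\log f(v)$ in nats over the
distinct observed values. For continuous measurements every value is
unique and $H = \log q$; since the weights are normalized within the
unmatched set this degeneracy is harmless, but `entropy_bins` can
discretize values into equal-width bins when a finer information ranking
between noisy and structured traces is wanted. Padding zeros are never
counted as observations.

### Properties

With identical pipeline settings on both sides, SMETS is non-negative,
symmetric (the smaller/larger roles are assigned by dimension, so swapping
the arguments is a no-op; at equal dimensions the matching is
orientation-stable), reflexive, and zero exactly when the preprocessed
representations coincide. At equal dimensions both penalties vanish and
SMETS reduces to the matched p-norm, where it empirically satisfies the
triangle inequality (1000 random triples in the acceptance suite). Across
dimensions the triangle inequality can fail, and the test suite constructs
an explicit witness: for a normalized oscillator $x$, the series
$A = \{x\}$, $B = \{-x, \text{const}\}$, $C = \{-x\}$ give
$d(A,B) \approx 3\lVert x\rVert$ — greedy matching pairs $x$ with the
constant at distance $\lVert x\rVert$, and the unmatched $-x$ contributes
$2\lVert x\rVert$ through $EP$ — while
$d(A,C) + d(C,B) \approx 2\lVert x\rVert + 1/3$. Hence a *semi*-metric.

Complexity is dominated by the cross-distance matrix and the greedy
selection, cubic in the larger dimension for a single pair; collections
reuse one preprocessing pass across all pairs.

## A worked example

```{r fig2}
specs <- tibble::tibble(name = c("A", "B", "C"), n_constant = c(2, 4, 9))
trio <- generate_toy_collection(specs, n_oscillating = 1, length = 64)
fit <- smets(trio)
as.matrix(fit)
tidy(fit)
```

All three models share one bit-identical oscillator; the constants
normalize to indistinguishable zero traces with zero entropy. Matched
distances and $EP$ vanish, so the three distances are pure dimension
penalties: $1/4$, $1/3$ and $7/13$ — the method separates models that any
averaging comparison would call identical, ordered by how many
uninformative extra variables they carry.

## Tunable parameters

| Parameter (`smets_control()`) | Default | Meaning |
|---|---|---|
| `normalize` | `TRUE` | z-normalize components (shape-only comparison) |
| `wavelet` | `TRUE` | Haar representation backend; `FALSE` = raw traces |
| `k` | 16 | retained largest-magnitude coefficients per component (capped at the padded length) |
| `truncate_to` | `k − 1` | retained length after removing padding-biased trailing symbols; `k` disables truncation |
| `entropy_bins` | 0 | 0 = exact value frequencies; otherwise equal-width bins |
| `linkage` | `"average"` | agglomerative criterion for `smets_hclust()` |

The defaults mirror a daily-resolution use case (a few hundred points
padded to 256, compressed 16:1). For very short series `k` caps itself at
the padded length. The linkage criterion is a genuinely free choice —
nothing in the distance construction prefers one — and average linkage is
the conventional default; single and complete linkage are available and
recorded in the run log.

## The synthetic generator

`generate_toy_model()` builds series from four archetypes: sinusoidal
oscillators (optionally damped; period `length/4`, amplitude 1 by
default), exponential relaxations, constant traces, and Gaussian
random-walk traces emulating asset prices. Components are deterministic
functions of their index and the shared settings — two models generated
with the same oscillator settings share bit-identical oscillating
components no matter how many other components each has, which is what
isolates the penalty terms in the worked example. Randomness enters only
through the optional noise term and random-walk components, both seeded.
Defaults (length 64, noise 0) reproduce idealized small dynamic models:
clean limit-cycle-like oscillations, monotone relaxations to steady state,
and static variables.

What the generator does *not* emulate: measurement noise correlated across
components, trends, regime switches, missing data, or the heavy tails of
real financial series. Passing property suites on these fixtures therefore
demonstrates the correctness and the axioms of the *distance*, not
clustering quality on any particular real domain.

The test and acceptance suites run at deliberately modest sizes — series
of 16–128 points, dimensions 1–10, 1000 randomized pairs or triples per
property, 500 matching instances — chosen so the whole suite exercises
every claim at full breadth while remaining a few minutes of desk-scale
computation.

## Numerical and design notes

* **Degenerate inputs.** Constant components normalize to zeros (not an
  error); zero-variance is detected exactly, not by tolerance. Non-finite
  values are rejected naming the offending component. Series must have at
  least 2 points (normalization) and components of one series equal
  length; different series may differ in length and are padded to a common
  power of two.
* **Tie-breaking.** Top-$k$ magnitude ties keep the lower transform index;
  greedy-matching ties take the lexicographically smallest (row, column).
  Both choices are arbitrary but fixed, making every result byte-stable
  across runs (the CLI's matrix output is tested to be byte-identical).
* **Exact zeros.** Cross-distances are computed from explicit coordinate
  differences rather than the $\lVert x\rVert^2+\lVert y\rVert^2-2x\cdot y$
  expansion, so identical components are at distance exactly 0 and
  reflexivity holds without tolerance.
* **Entropy base.** Natural logarithm; only ratios of entropies enter the
  penalty, so the base cancels.
* **Normalization order.** Components are normalized first, then padded,
  then transformed; entropy is taken on normalized, pre-padding values.
  Normalizing after padding would let the padding shift means and spreads,
  coupling a component's representation to how much padding it received.

### Representation distance: metric versus lower bound

A truncated representation is useful for indexing when distances between
representations never exceed distances between the original series (no
false dismissals). With *first-k* coefficient selection this holds because
every comparison projects onto one fixed subspace. With *largest-magnitude*
selection, each component keeps its own position set, and the union-with-
implicit-zeros distance is no longer a projection of the difference
vector: it can exceed the raw distance when one side retains a position
whose coefficient the other side discarded. Measured under the default
pipeline, a few percent of random normalized pairs exceed the raw distance
at $k = 4$ or $16$ (never at $k = $ all, where the distance is exact).

This is not fixable without giving something up. Any scheme that shrinks
the one-sided terms enough to restore the bound — counting only shared
positions, or counting the provable residual
$\max(0, |c| - \tau_{\text{other}})$ against the other side's largest
discarded magnitude — ceases to be an embedding into a fixed vector space,
and measurably breaks the triangle inequality, including at dimension 1
where SMETS *is* the component distance. Both variants were implemented
and measured during development. The package keeps the union-with-zeros
convention: it is the one under which the distance is a true metric on
representations, which carries the semi-metric axioms and the
equal-dimension metric property — the heart of the method. Users who need
guaranteed lower bounding for indexing should either use `k = all`
(`smets_control(k = L, truncate_to = L)`), accept first-k-style
conservative pruning outside this package, or treat representation
distances as approximate.

## Known limitations

* Samples are assumed equally spaced; irregular time stamps are accepted
  with a warning and treated as uniform. No temporal alignment or warping
  is performed — components are compared in phase.
* Greedy matching is order-dependent under exact distance ties; with
  continuous data ties are measure-zero, and the fixed tie-break keeps
  results deterministic regardless.
* Identity is relative to the representation: two different raw series can
  share a truncated representation and be at distance 0. At `k = all`
  without truncation identity is exact.
* The entropy penalty's weights normalize within the unmatched set; it
  measures *where* the unmatched information is, not *how much* unmatched
  information there is in total (that is the dimension penalty's role).
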