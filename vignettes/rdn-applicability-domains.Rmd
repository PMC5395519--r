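---
title: "Mapping predictive reliability with reliability-density neighbourhood applicability domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping predictive reliability with reliability-density neighbourhood applicability domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnad)
```

## The problem

A QSAR classifier's accuracy is not uniform across chemical space: it is
high where training data is dense and the structure–activity landscape
is smooth, and it degrades in sparse regions, near activity cliffs, and
in pockets where the model is systematically wrong. An applicability
domain (AD) should therefore not be a single in/out threshold but a
*continuous map* of predictive reliability. This package implements such
a map, the reliability-density neighbourhood (RDN), together with the
comparator methods it is usually benchmarked against and a score that
quantifies whether an AD behaves consistently on independent data.

## The RDN construction

Working on z-scored descriptors (means and standard deviations estimated
on the training set only, sample-SD convention, zero-variance descriptors
dropped), the method iterates over neighbour counts $k = 1, \dots,
k_{\max}$:

1. For every training compound, compute the average Euclidean distance
   to its $k$ nearest training neighbours.
2. Bound the resulting list of averages by the Tukey outlier fence
   $\mathrm{RefVal} = Q_3 + 1.5\,(Q_3 - Q_1)$. Quartiles use linear
   interpolation between order statistics (R's default type 7); this
   convention is declared so that distances and profiles are exactly
   reproducible.
3. Each training compound's radius $D_i$ is the mean of its distances to
   all training neighbours at distance $\le \mathrm{RefVal}$, or 0 if no
   neighbour qualifies — a fence-isolated compound offers no coverage.
4. The effective radius is $D_i \times s(k) \times W_i$, where $s(k)$ is
   the step schedule and $W_i$ the reliability weight (below).
5. A query is inside the AD at iteration $k$ when it lies within the
   effective radius (closed ball) of at least `min_neighbors` training
   compounds. Inclusion accumulates as the union over iterations;
   cumulative accuracy is the fraction of included compounds whose
   external model prediction was correct.

Recomputing RefVal and $D_i$ at every $k$ — rather than fencing once —
matches the iterative expansion the method is defined by: the fence
adapts as the neighbourhood averages grow.

### The reliability weight

$$W_i = (1 - \mathrm{STD}_i) \times \mathrm{agreement}_i$$

$\mathrm{STD}_i$ is the sample standard deviation (denominator $M - 1$)
of the $M$ ensemble members' predictions for compound $i$: a precision
measure. $\mathrm{agreement}_i$ is the fraction of members whose class
call matches the observed class: a bias measure. Both lie in $[0, 1]$,
so $W_i$ does too. The product matters because the two failure modes are
orthogonal: a compound can be predicted with near-zero spread
(STD $\approx 0$) by an ensemble that is consistently wrong
(agreement $= 0$); only the product sends its radius to zero. With
STD 70% and agreement 35%, $W = 10.5\%$ — an 89.5% shrinkage of that
compound's coverage; with STD 1% and agreement 99%, $W = 98\%$ and the
neighbourhood is nearly untouched.

When per-member predictions are unavailable and only a mean ensemble
probability $\bar y_i$ is provided, the probability-variant agreement
$1 - |Y_i - \bar y_i|$ is used. It is the more conservative of the two:
a mean of 0.23 against an observed class 0 yields 0.77 rather than the
vote fraction.

Ensemble predictions for the training set may come from any base
learner via `bag_ensemble()`, which draws 80% bootstrap resamples (with
replacement) per member, ten members by default. The learner contract is
a plain function `(X, y) -> function(newX) -> probabilities`, keeping
the module model-agnostic; probability calibration (e.g. Laplace
smoothing at tree leaves) is the learner's concern. Training-set weights
use in-sample ensemble predictions by default; a caller with
out-of-bag or cross-validated predictions can supply those instead,
since `rdn()` accepts any weight vector.

### The step schedule

Dense cores are extremely sensitive to radius growth: the full $D_i$ at
$k = 1$ can already cover most of an external set. The default schedule
therefore scales radii by $1/3$ for $k \le 30$, $1/2$ for
$31 \le k \le 40$, and $1$ beyond, so the core is scanned slowly and the
periphery quickly. `k_max` defaults to 65, which empirically approaches
full coverage; both the schedule (`rdn_schedule()`) and `k_max` are
user-settable, and `k_max` is treated as a fixed parameter rather than a
coverage-based stopping rule.

`dknn_profile()` is the exact special case $W \equiv 1$, $s(k) \equiv 1$
— the unweighted density k-NN AD — and is computed by the same code
path, a reduction the test suite asserts bit-for-bit.

### Numerical conventions

* Neighbour selection uses a stable sort on (distance, training index);
  ties at the $k$-th distance do not enlarge the neighbour set.
* Ball inclusion uses $\le$ (closed ball), mirroring the "closer or
  equal" rule of the fence, but a zero radius covers nothing — otherwise
  a fully unreliable instance would still admit coincident queries.
* Distances are computed by direct coordinate differences, not the
  quadratic expansion, so identical points give an exact 0 and boundary
  tests are reproducible.
* Accuracy over an empty inclusion set is `NA`, never 0; profiles
  enforce this so an empty core cannot masquerade as a failing one.

## Comparator ADs

**STD tiers** (`std_profile()`): compounds enter in order of ensemble
standard deviation; the default grid is the sorted unique STD values
thinned to ≤ 50 edges (the tier width is a declared default, not an
inferred one). **KDE** (`kde_profile()`): a Gaussian kernel density is
fitted to the training set's projection onto its first principal
component (sign fixed so the largest-magnitude loading is positive);
a compound is in-AD at percentile $p$ when its density reaches the
$p$-th percentile of training densities. Bandwidth `"auto"` is
Silverman's rule on the training projection — a local, reproducible
default — and any explicit bandwidth is accepted so external choices can
be replayed.

## The robustness score

An AD is only useful if the accuracy-versus-coverage relationship it
establishes is stable across independent external sets. `ad_score()`
compares the two curves $y$ and $z$ a single AD expansion produces on
two datasets over segments $i = 2..P$:

$$\mathrm{score} = \frac{1}{F_{\mathrm{added}}} \sum_{i=2}^{P}
  WP_i \,\bigl(1 + |y_i - z_i|\bigr), \qquad
  WP_i = \mathrm{SMP}_i \times
  \frac{N_{\mathrm{added},i}\{y{+}z\}}{N_{\mathrm{total}}\{y{+}z\}}$$

Each curve's segment slope (accuracy against the combined cumulative
fraction included) is penalised 1 / 2 / 4 for negative / null / positive
direction — accuracy is supposed to fall as the AD expands — and the two
penalties multiply into $\mathrm{SMP}_i \in \{1, 2, 4, 8, 16\}$. The
weight is the fraction of combined data added in the segment, so a slope
flip caused by two compounds matters less than one caused by fifty, and
segments adding nothing contribute nothing. The $|y_i - z_i|$ gap enters
as a coefficient of $WP_i$, keeping its influence secondary to shape.
$F_{\mathrm{added}}$ — the fraction of combined data added between the
first and last iteration — rewards methods with a well-resolved core: an
AD whose first iteration already swallows half the data has told the
user nothing about that half.

Design choices worth stating:

* The normaliser could be read as total coverage at $P$ instead of the
  first-to-last difference. The difference form is used, because it is
  what makes first-iteration bloat directly punitive; both values are
  reported (`f_added`, `f_total_coverage`).
* Slope "zero" is declared by a tolerance of $10^{-9}$ on the slope.
* Leading iterations where either dataset has no included compound are
  dropped (cumulative accuracy is undefined there); at least two
  iterations with data added after the first must remain.
* Two identical strictly decreasing curves score exactly 1, which the
  suite checks as a closed-form property over randomized coverage
  patterns.

The score ranks AD methods on the same data (lower is better); it is not
an absolute quality measure, and it deliberately rewards smooth
degradation, so a method that robustly *locates* a mid-coverage trouble
spot can score worse than a smoother but less informative one.

## ReliefF descriptor selection

Distances — and therefore the whole AD — are only as meaningful as the
descriptors behind them. `relieff_weights()` implements binary-class
ReliefF: for each (optionally subsampled) instance, the `n_neighbors`
nearest hits and misses under the Manhattan distance of min–max-scaled
features update each feature's weight down by hit diffs and up by miss
diffs. Defaults follow common practice: `n_neighbors = 10`, `sigma = 2`.
`sigma` is interpreted as the decay parameter of the exponential
rank-based neighbour weighting $e^{-(\mathrm{rank}/\sigma)^2}$
(normalised over the neighbours used) — the convention of the classical
implementations, declared here rather than reverse-engineered from any
particular toolkit. Repeated subsampled runs are combined by
`average_ranks()` (mean rank, lexicographic tie-break), and
`select_top_k()` takes the best k (default 20). ReliefF is chosen
because it scores features individually on local class separation and is
indifferent to inter-feature correlation — correlated descriptors that
jointly cover chemical space are kept, which suits AD construction
(unlike model building).

## What the synthetic generator emulates

`synthetic_config()` plants the three regimes that make AD methods
disagree:

| region | n (train / per external) | geometry | labels | ensemble |
|---|---|---|---|---|
| core | 120 / 40 | spread 1 at origin | 5% flips | 85% mass on observed class, dispersion 0.05 |
| biased | 40 / 15 | spread 1, offset ~5.7 | 5% flips | 15% mass on observed class, dispersion 0.03 |
| sparse | 15 / 8 | spread 2.5, remote | 30% flips | 55% mass, dispersion 0.30 |

Descriptors are three informative Gaussian dimensions plus two pure-noise
ones. The dimensionality is deliberately low: in high dimensions
pairwise distances concentrate and the AD snaps from empty to full at a
single step change, whereas real descriptor sets (and this generator)
show graded density so the expansion is gradual. Class-1 compounds shift
along the first axis so labels have geometry; the two external sets are
drawn i.i.d. from the same mixture, which is precisely the premise the
robustness score tests. Ensemble matrices are simulated directly
(truncated-normal member probabilities around a per-region target)
rather than via trained classifiers, isolating the AD logic from learner
variance; `bag_ensemble()` covers the trained path separately.

The "biased" region is the diagnostic one: dispersion 0.03 with the mean
on the wrong side gives near-zero STD and near-zero agreement — rows an
STD-only AD admits at its core and RDN defers to the last iterations.
The suite checks this contrast as a stochastic property over 20 seeds,
alongside the property that matched external pairs score lower than
accuracy-shuffled pairs.

What the generator does **not** emulate: real descriptor distributions
(skewness, discreteness, collinearity at realistic strengths), activity
cliffs with structural meaning, class imbalance beyond the region rule,
or assay-specific noise. Passing tests therefore demonstrate the
machinery's correctness and the planted contrasts' recovery, not
performance on any particular chemical endpoint.

## Problem sizes and determinism

The default study (175 training compounds, two external sets of 63, 5
descriptors, 10-member ensembles, k = 1..65) profiles in well under a
second, and the oracle-equivalence checks run instances up to 200 × 200
compounds in up to 10 dimensions. These sizes were chosen so the full
suite exercises every code path at desk scale; all stochastic components
take explicit integer seeds and are bit-reproducible.

## Known limitations

* Binary endpoints only; no regression or multi-class profiling.
* Coverage scanning is a dense double loop (vectorised, but no spatial
  indexing); for training sets beyond ~10⁴ compounds a kd-tree-backed
  variant would be preferable.
* The probability-agreement variant assumes calibrated mean
  probabilities; badly calibrated ensembles shift agreement wholesale.
* KDE uses the first principal component only, by construction; it is a
  global-density comparator, not a faithful multivariate density model.
* `std_profile()` tier edges default to data-derived values, so STD
  profiles from different datasets share a grid only if edges are passed
  explicitly.
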