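---
title: "Elite hybrid binary cuckoo search: model, parameters and design notes"
author: "ehbcs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elite hybrid binary cuckoo search: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehbcs)
```

## The problem

Given a binary-labeled dataset with `n` cases and `d` numeric features —
typically a transcriptomics-style matrix where `d` is large and most
features are irrelevant or redundant — wrapper feature selection searches
the `2^d - 1` nonempty feature subsets for one that maximizes the
cross-validated performance of a classifier trained on exactly those
features. Exhaustive search is infeasible beyond a dozen features, so the
search is delegated to a population metaheuristic.

This package implements an elite hybrid binary cuckoo search (EHBCS): a
binary cuckoo search whose sigmoid transfer function is parameterized by
Relief feature weights and whose nest-abandonment step is replaced by an
elitist genetic layer. Binary cuckoo search (BCS), a binary genetic
algorithm (BGA) and binary particle swarm optimization (BPSO) are provided
as baselines behind the same `feature_select()` interface.

## The model

### Candidate subsets and fitness

A candidate solution ("nest") is a bit vector `x ∈ {0,1}^d`; bit `j` means
feature `j` is included. A subset with `s = Σ x_j ≥ 1` selected features is
scored by

```
f(x) = beta * (d - s) / d + (1 - beta) * acc(x),      beta = 0.2
```

where `acc(x)` is the mean cross-validated accuracy of the classifier on
the selected columns. The reduction term breaks the degeneracy of plain
accuracy: of two subsets with equal accuracy the smaller one scores
strictly higher. `beta = 0` recovers accuracy-only fitness (the `acc`
fitness mode of the benchmark harness). Since `acc ∈ [0,1]` and `s ≥ 1`,
the fitness is positive, which the roulette operator requires.

### Relief feature weighting

Relief scores each feature by its ability to discriminate neighboring
cases of different classes. Sweeping every case `x` (`T = n` picks), with
`NH(x)`/`NM(x)` the Euclidean-nearest same-/other-class case:

```
w_j <- w_j + |x_j - NM(x)_j| / T - |x_j - NH(x)_j| / T
```

A feature that differs across the class boundary but agrees within a class
accumulates positive weight; a feature on which same-class neighbors
disagree goes negative. The k-neighbor variant replaces the single hit and
miss with the `k` nearest of each, every term divided by `T * k`.

Decisions worth recording:

* **`T` defaults to `n` with a deterministic sweep over all cases** rather
  than random sampling. This is standard Relief practice, removes one
  source of Monte-Carlo noise, and makes the weights reproducible without
  a seed.
* **The `1/k` averaging in the k-neighbor variant is our normalization
  choice.** It makes the `k = 1` variant coincide exactly with the
  single-neighbor rule, so the two variants are on the same scale; without
  it the weights (and hence the transfer-function coefficients) would grow
  linearly in `k`.
* **Features should be min-max normalized first** (the default in
  `feature_select()`): the update accumulates raw absolute differences and
  is therefore scale-sensitive. We normalize globally to `[0,1]` rather
  than dividing each difference by the feature's range inside the update;
  on normalized data the two conventions coincide.
* Nearest-neighbor ties are broken by lowest case index, and a case is
  always excluded from its own hit search.

### Lévy flights and the weight-parameterized transfer function

Each non-elite nest is perturbed once per iteration by a Lévy-flight step
vector sampled with the Mantegna algorithm: per dimension

```
step = alpha * u / |v|^(1/beta_levy),   u ~ N(0, sigma_mu^2),  v ~ N(0, 1)
sigma_mu = { Gamma(1+b) sin(pi b/2) / [ Gamma((1+b)/2) b 2^((b-1)/2) ] }^(1/b)
```

with `alpha = 1` and stability exponent `b = beta_levy = 1.5`
(`sigma_mu ≈ 0.6966`). The heavy tail mixes many small refinements with
occasional large jumps.

The real step is mapped to a bit through a sigmoid transfer function whose
coefficient is the feature's Relief weight `gamma_j = w_j`:

```
p = 1 / (1 + exp(-gamma * step))        for step >= 0
p = 1 - 1 / (1 + exp(-gamma * step))    for step < 0
```

and bit `j` is set iff a uniform draw is `<=` p (the tie kept inclusive).
The two branches make the map symmetric in the step, so what matters is
the weight: the probability is 0.5 at `gamma = 0`, grows with `gamma` for
any nonzero step (heavily weighted features are selected more often), and
stays below 0.5 for negative weights. `plogis()` makes the evaluation
saturate cleanly to exactly 0/1 for `|gamma * step|` beyond ~745 instead
of overflowing.

Two readings of the original update are possible: accumulate the step onto
a continuous position and squash the position, or squash the step
directly. The transfer functions above consume only the step, so **the
step is binarized directly and no continuous position is kept**; this is a
documented interpretation, not an assertion about the source method.

### The elitist genetic layer

After the Lévy sweep (greedy acceptance: a nest keeps its new bits only if
fitness improves — configurable to unconditional replacement), the
classical "abandon the worst nests at random" step is replaced by
selection and crossover:

1. the elite (best) nest is copied through untouched — it undergoes
   neither Lévy flight nor crossover, so best fitness never regresses;
2. the worst `floor(p_r * (n_pop - 1))` non-elite nests are replaced by
   offspring of parent pairs drawn by roulette-wheel selection
   (`p_i = f_i / Σ f`), each pair undergoing single-point crossover with
   probability `p_c` and cloning otherwise.

Interpretation notes: `p_r` is read as the regenerated worst fraction —
the structural analogue of the abandonment probability `p_a` that the
crossover step replaces. Parent pairs are drawn from the whole population
(selected × selected, not elite × selected). Offspring replace the chosen
worst nests directly. Fitness ties for the elite are broken toward fewer
selected features, then lower index — the tie-break that matches the
fitness function's own preference for small subsets.

### Baselines

* **BCS**: identical loop with uniform `gamma = 1` and no genetic layer;
  the worst fraction `p_a` of nests is re-randomized each iteration.
  `p_a = 0.25`, the conventional cuckoo-search value, since the benchmark
  parameter table does not cover BCS.
* **BGA**: generational, roulette selection, single-point crossover at
  `p_c = 0.8`, per-bit mutation at `p_m = 0.1`, elitism of one.
* **BPSO**: velocity `v <- 0.9 v + 1·r1·(pbest - x) + 2·r2·(gbest - x)`,
  clamped to ±6, bit set iff uniform ≤ `plogis(v)`.

## Evaluation protocol

Subsets are scored by stratified k-fold cross-validation with **k = 5 for
datasets under 100 cases and k = 10 otherwise**. Stratification (shuffle
within class, deal round-robin) keeps every fold's label proportion within
one case of the global one; the small-n, high-d datasets this method
targets make unstratified folds degenerate too easily. Per fold the
confusion counts give accuracy, sensitivity, specificity, precision and
F-measure; fold metrics are averaged. A metric with a zero denominator is
reported as 0 and flagged, so averages always exist.

The classifier is an SVM (`e1071`), radial kernel below 2000 features and
linear above — the dimensionality split used in the benchmark protocol —
with cost 1 and RBF bandwidth `1/(s · mean feature variance)`; these
hyperparameters are unstated in the protocol and recorded in every run.
A nearest-centroid **surrogate classifier** is also provided: it is
deterministic and fast enough to enumerate all 255 subsets of a d = 8
problem in seconds, which makes exhaustive-oracle testing and large
property suites feasible. The surrogate is a first-class classifier
option, not a stand-in of last resort; SVM remains the default for user
runs.

The benchmark harness (`fs_benchmark()`) runs each algorithm 5 times
(seeds `seed + 0..4`) against one fold plan fixed for the whole benchmark,
so algorithm comparisons are paired. The reported `Std` is the population
(divide-by-R) standard deviation of the run accuracies — with R = 5 the
convention is material, so it is printed with the table. The reported
accuracy re-evaluates each run's final subset on the shared folds (the
search-internal accuracy is available in each stored fit).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_pop` | 30 | nests / individuals / particles |
| `n_iter` | 100 | iteration budget (no convergence rule is prescribed) |
| `beta` | 0.2 | weight of the feature-reduction term in the fitness |
| `alpha` | 1 | Lévy step-size scale |
| `levy_beta` | 1.5 | Lévy stability exponent |
| `p_c` | 0.5 | crossover probability (EHBCS layer) |
| `p_r` | 0.3 | regenerated worst fraction per iteration |
| `relief_k` | 3 | neighbors in the k-NN Relief variant |
| `p_a` | 0.25 | BCS abandonment fraction (package choice) |
| BGA `p_c`, `p_m` | 0.8, 0.1 | crossover / mutation |
| BPSO `c1`, `c2`, `omega`, `v_max` | 1, 2, 0.9, 6 | velocity update and clamp |

All but `n_iter`, `p_a` and `v_max` follow the published benchmark
parameter table; those three are unstated there and fixed at the field's
conventional values.

## The synthetic generator

`generate_synthetic()` emulates the shape of the benchmark datasets:
informative features are class-conditional Gaussians with a standardized
mean shift of `effect_size`, noise features are i.i.d. standard normal in
both classes, redundant features copy an informative one plus
`N(0, noise_sd²)`. Class sizes are fixed at `round(n · class_balance)`.
The defaults used throughout the test-bench — n = 200, d = 50, 5
informative features at effect size 2 — give a planted signal that a
two-sample t statistic separates from the noise floor with probability
near 1, so recovery is a meaningful yes/no question rather than a coin
flip.

What the generator does **not** emulate: heavy-tailed and discrete
expression distributions, correlated noise blocks, batch effects,
class-dependent variance, and d ≫ n regimes in the thousands of features.
Passing tests on this generator show the search and evaluation machinery
behave as specified; they do not certify performance on real microarray
data.

## Numerical and degenerate-input choices

* All-zero candidate subsets are repaired before evaluation (the fitness
  of an empty subset is undefined): EHBCS sets the single highest-weight
  bit, the baselines one uniform random bit.
* Fitness values are cached per bit string, so recurring subsets cost one
  classifier run; `n_evaluations` counts distinct evaluations and cache
  hits are reported separately.
* Constant features min-max-normalize to 0 and get Relief weight exactly 0,
  hence transfer probability exactly 0.5.
* Every run is reproducible from one integer seed; folds, initialization
  and all stochastic operators draw from it in a fixed order. (Named
  per-component RNG streams were considered and dropped: base R offers no
  cheap stream splitting, and single-seed determinism is what the
  reproducibility checks exercise.)
* Numeric label values are mapped to 0/1 by numeric order (so −1/+1 maps
  by sign); other labels by locale-independent lexicographic order. The
  larger value is the positive class unless `positive_label` overrides it
  — which class is "positive" is a reporting choice the protocol leaves
  open, and it changes sensitivity/specificity orientation, so it is
  exposed rather than guessed.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data,
sized to keep the full suite in minutes on one core: Relief oracle
equivalence on 50 instances with n ≤ 30, d ≤ 6; exhaustive enumeration at
d = 8 (255 subsets, surrogate classifier); elitism sweeps at n = 60,
d = 15 over 100 iterations and 10 seeds per algorithm; planted-feature
recovery at n = 200, d = 50 with 5 runs of 50 iterations. These sizes are
the package's own test-bench choices; the algorithms themselves have no
size-dependent switches.

## Known limitations

* Binary classification only; no multi-class Relief or metrics.
* No SVM hyperparameter tuning or nested cross-validation; the fitness CV
  and the reported CV share folds by design (both choices favor paired,
  reproducible comparisons over unbiased generalization estimates).
* The Lévy step is binarized directly; no continuous-position variant.
* Wrapper selection at `n_iter × n_pop` classifier fits is inherently
  expensive; for d in the thousands use the surrogate classifier or the
  linear kernel.
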