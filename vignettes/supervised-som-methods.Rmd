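---
title: "Supervised SOM classifiers: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised SOM classifiers: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpann)
```

This vignette documents the models implemented in **cpann**, the parameters
that matter, the numerical conventions the implementation fixes where the
underlying methods leave freedom, and what the synthetic-data experiments
can and cannot show.

## The base map and its schedules

All four classifiers share a rectangular, non-toroidal grid of `nx * ny`
neurons at 1-based integer positions `(i, j)`. Each neuron holds one weight
per descriptor plus a single output weight in `[0, 1]` carrying the class
response. The winning neuron for an object is the one with the smallest
Euclidean distance between the object's descriptors and the neuron's
descriptor weights; the output layer is never consulted at prediction time,
and ties go to the lowest row-major linear index `(i-1)*ny + j`.

The weight update is the classical Kohonen rule
`w <- w + eta(t) * h * (o - w)`. Three schedules drive it:

* **Learning rate** `eta(t)`: linear from `eta_max` at the first presented
  object to `eta_min` at the last. Defaults `eta_max = 0.5`,
  `eta_min = 0.01` — conventional values that start with coarse ordering
  and end with fine convergence. For the X-Y fused network `eta_max`
  should stay at or below 0.5, because its adaptive factor can double a
  correction.
* **Neighborhood radius**: linear from `max(nx, ny) - 1` (the largest
  possible neighborhood) down to exactly 0 at the last iteration, so only
  the winner is corrected at the end. The kernel is triangular,
  `h = max(0, 1 - d/(r + 1))`, cut off beyond the radius; the winner
  always receives factor 1. The grid distance `d` is the Chebyshev
  distance on `(i, j)`, giving square rings of neighbors — the
  conventional choice for square SOM neighborhoods. (Euclidean grid
  distance would be an equally defensible reading; Chebyshev is fixed
  here for determinism and because square-ring neighborhoods match how
  rectangular top-maps are usually drawn.)
* **Iteration counter**: `t` advances once per presented object, and the
  total `t` range is `epochs * subsample size`, so the schedules span the
  entire run rather than restarting each epoch.

Weights initialize uniformly in `(0, 1)` from the training seed. All
randomness (initialization and subsampling) is drawn in R; the compiled
update loop is purely deterministic, which makes whole model fits
bit-reproducible for a given seed.

## Class-balanced subsampled epochs

Descriptor datasets for toxicity endpoints are typically imbalanced. Each
epoch therefore draws a fresh random subsample — a fraction of each class,
without replacement, in permuted order — and presents it exactly once. The
default fractions 0.33 (majority class) and 0.66 (minority class) equalize
the class counts for a 2:1 imbalance; for balanced experimental data one
simply sets both to 1. Per-class draw counts are rounded half-up, and each
class must contribute at least one object.

## The four training variants

**cpann.** Both layers are updated by the plain Kohonen rule; the output
layer's "object value" is the binary label.

**xyf.** During training the winner minimizes the fused dissimilarity
`alpha(t)*S(X) + (1 - alpha(t))*S(Y)`, where both terms are normalized
Euclidean distances `ED/sqrt(n)` on `[0, 1]`-scaled values, so 0 means a
perfect match. Reading `S` as a *distance* (not a similarity) is what
makes the adaptive factor `F = 2 - (alpha*S(X) + (1-alpha)*S(Y))` hit both
of its documented extremes — 2 for a perfectly matched object, 1 for no
match — so that reading is adopted. `F` is evaluated at the winning neuron
and scales the correction of the whole neighborhood for that presentation.
`alpha` decreases linearly from 1.0 at the first epoch (descriptor-only
winner selection) to 0.5 at the last (both maps contribute equally); only
the endpoint is prescribed by the method, so the 1.0 start is a package
choice. At prediction time the winner is descriptor-only, exactly as for
the other variants.

**cpann_v1.** Every correction is multiplied by
`m = 1 - (1 - p)*|scaled(o) - scaled(w)|`. The object value is
range-scaled against the full training set's values of that variable, and
the weight against the current values of its weight level across all
neurons — recomputed at every iteration, since the level moves during
training. Where all reference values are equal the scaled value is defined
as 1. `p` decreases linearly from 1 at the first epoch to 0 at the last,
per epoch rather than per object (the annealing is described per training
stage, and per-epoch stepping keeps every object of one epoch under the
same regime). The output layer uses the same rule with the target as the
variable. At `p = 1` the factor is identically 1, so the whole update
reduces exactly — bit for bit — to the cpann trajectory; the
`p_fixed = 1` option exposes this reduction as a diagnostic.

**cpann_v2.** The v1 factor is multiplied by the analogous factor for the
endpoint, `1 - (1 - p)*|scaled(o_target) - scaled(w_target)|`, for every
descriptor weight. On the output layer the generic two-factor rule is
applied with the target as the variable `k`, which degenerates to the
squared target factor — the consistent reading of "the same rule on both
layers" when the layer's variable *is* the target.

Both damping factors are provably in `[0, 1]` for arguments in `[0, 1]`;
the test suite confirms the bound by brute force over a dense grid of the
argument cube.

## The clustering formation score

`cfs()` scores a binarized response surface (output weight > 0.5 maps to
1; exactly 0.5 maps to 0, since only responses strictly greater than 0.5
are the positive class) as 1 minus the number of discordant
horizontally/vertically adjacent pairs divided by `2*Nx*Ny - Nx - Ny`, the
pair count of the non-toroidal grid. A uniform surface scores 1, a
checkerboard 0, and the score is invariant under label inversion,
transposition and mirroring. It is undefined on a 1x1 grid (no pairs).

Because CFS depends on the grid size and the per-class neuron counts, a
model's score is compared with the mean CFS of random rearrangements of
the same responses. The default baseline is Monte-Carlo with 100
permutations; an exhaustive mode enumerates all distinct arrangements on
small grids and serves as the oracle for the Monte-Carlo estimator (on a
2x2 grid with two positive neurons the exact mean is 1/3). The permutation
operates on the *binarized* responses — "random distributions of the same
responses" is read as rearranging what the map actually answers, not
re-drawing raw weights.

## GA descriptor and hyperparameter selection

A chromosome is a binary descriptor mask plus four genes: epochs, square
grid side, `eta_min`, `eta_max`. Fitness trains one model on the masked
training set and evaluates one of four criteria on train and internal test
predictions (MCC-sum, MCC-product with a train/test-gap penalty, worst-case
sensitivity/specificity, and the latter with an additional spread penalty),
each multiplied by the descriptor-count penalty
`f(Nsel) = 1 - a*(Nsel - 1)/Ndes`. As printed, the fourth criterion
contains `f` twice — once inside the third criterion it builds on and once
as a trailing factor. It is implemented exactly that way; a `single_f`
switch drops the duplicate for sensitivity analysis. MCC is defined as 0
when its denominator vanishes.

The GA operators are not prescribed by the method, so standard,
reproducible defaults are fixed: tournament selection (size 3), uniform
crossover on the mask, one-point crossover on the hyperparameter genes,
per-gene mutation probability `1/(Ndes + 4)`, a full random re-draw when a
mask goes empty, and five elites carried unchanged (hence a non-decreasing
best fitness). Default gene ranges are epochs 20–200, grids 6x6–12x12,
`eta_min` 0.01–0.1, `eta_max` 0.1–0.5; all are configurable since only
*which* parameters evolve is prescribed, not their bounds. Every fitness
evaluation derives its training seed deterministically from the chromosome
and the run seed, so fitness is a pure function of the chromosome and
re-evaluations are free (they are cached).

## Model screening

A run is screened on its last 20 populations: some best-5 chromosome must
reach an average sensitivity/specificity of at least 0.7 (inclusive) on
train, internal test and internal validation sets. "Average value of
sensitivity and specificity" is read as the mean of the two metrics per
set — the per-set quantity that is then thresholded; a strict mode
requiring each metric individually to pass is provided as an option, since
the phrase admits both readings. Passing candidates undergo a stability
stage: 100 models retrained with different permutation seeds, averaged per
set, all averages >= 0.7; the external validation set is held back until
this stage and checked last with the same threshold. Raising the threshold
can only shrink the selected set — monotonicity the tests verify.

Frequent-descriptor analysis counts, per group of selected models (e.g.
per algorithm), how often each descriptor was selected, takes the top 10
with all ties at the boundary included (alphabetical order within equal
frequencies), and intersects the lists across groups.

## Data pipeline conventions

* Low-variability filter: a descriptor is dropped when its most frequent
  value exceeds 70% of rows; exactly 70% is kept.
* Correlation pruning removes descriptors one at a time until the maximal
  pairwise |Pearson r| is at most 0.5. The removal order is greedy
  most-connected-first with deterministic tie-breaks (larger mean |r|,
  then name order); any order satisfies the stopping rule, so the final
  set is reproducible but not canonical.
* Normalization is range scaling with training-partition ranges; constant
  training columns map to 1, and values of new data outside the training
  range are clamped to `[0, 1]` because the weights live in the unit cube.
* The train/test/validation split maps compounds with an unsupervised
  Kohonen fit and samples every occupied neuron into every set: the first
  compounds of a neuron (by distance rank) seed one per set in decreasing
  fraction order, the rest follow a largest-deficit rule. This replaces
  the manual picking of validation compounds from a drawn top-map with a
  deterministic procedure that keeps each set structurally representative.
* Continuous activities are classed by a strict median split: above the
  *training* median is the high-activity class, ties at the median go low.

## The synthetic generator

`generate_dataset()` emulates the shape of a curated QSAR descriptor
table: a few hundred compounds with a 2:1 class imbalance (default 160
negatives, 80 positives), tens of descriptors (default 4 informative + 4
redundant + 12 noise), columns range-scaled to `[0, 1]`, and planted
cluster structure — informative descriptors are class-conditional
Gaussians whose means differ by `separation` within-class standard
deviations (default 2, a moderate overlap regime where algorithms can
differ), redundant descriptors are informative ones plus Gaussian noise
(sd 0.3, correlating above 0.9 with their parent), and noise descriptors
are class-independent. The Gaussian cluster model is the simplest
structure consistent with the similarity principle underlying QSAR —
similar compounds behave similarly — and is what the planted-recovery
tests rely on.

What it does **not** emulate: heavy-tailed or discrete descriptor
marginals of real descriptor calculators, activity cliffs (structurally
similar compounds with opposite labels), block correlation structures
beyond parent–duplicate pairs, or label noise. Tests that pass on this
substrate therefore demonstrate algorithmic correctness and qualitative
behavior, not performance on real chemistry.

## Experiment scales

The package's experiment-style checks run at desk scale: GA recovery uses
populations of 30 over 20 generations (with gene ranges 10–30 epochs and
5x5–8x8 grids) on 100-compound sets with 2 informative among 20
descriptors, repeated over 10 seeds; the cluster-formation comparison
trains the algorithms on 20 generated datasets at the generator defaults
(50 epochs, 8x8 grids) and compares mean CFS deltas with a sign test.
Full-scale campaigns (hundreds of 200-generation runs with populations of
95) use exactly the same code paths via `ga_config()` defaults.

## Known limitations

* Grids are rectangular and non-toroidal; hexagonal and toroidal
  topologies (and batch-SOM updates) are out of scope, and the clustering
  formation score is only defined for the non-toroidal case.
* The endpoint is a single binary class; multi-class output layers and
  regression endpoints are not supported.
* Weight-level rescaling in the damped variants recomputes level ranges at
  every iteration, which is exact but makes those variants the slowest;
  the compiled loop keeps this acceptable at the scales above.
* The correlation-pruned descriptor set depends on the documented removal
  order; other orders satisfying the same stopping rule may keep a
  different (equally valid) subset.
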