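---
title: "Selective sensor ensembles with a binary glowworm swarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective sensor ensembles with a binary glowworm swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowsel)
```

## The model

A multi-sensor human-activity-recognition (HAR) system records `M` sensor
sources on several subjects. `glowsel` treats sensor deployment as
decision-level ensemble pruning: each sensor source drives its own base
classifier, the active classifiers vote, and the deployed subset is the
binary mask `c ∈ {0,1}^M` that maximizes

```
fitness(c) = ω · A_tr(c) − (1 − ω) · m / M ,     0 < m ≤ M ,
```

where `A_tr(c)` is the training (resubstitution) accuracy of the masked
majority vote, `m = Σ c_i`, and `ω` is slightly below 1. The second term is
the deployment cost: at equal accuracy, fewer sensors always win. We default
to `ω = 0.95`, so dropping one sensor from a 16-sensor pool is worth a
training-accuracy sacrifice of up to `(1 − ω)/(ω·M) ≈ 0.0033`.

Three assumptions are load-bearing. First, per-sensor classifiers are
*diverse but comparable* — they see the same windows through different
sensors and different random hidden layers. Second, resubstitution accuracy
of the fused vote ranks subsets usefully; an internal validation split could
replace it, but the default follows the training-accuracy formulation of the
fitness. Third, majority voting with deterministic tie-breaking (smallest
class label) is the fusion rule; no weighting or stacking.

### Base classifiers: extreme learning machines

Each member is a single-hidden-layer network whose input weights `w` and
biases `b` are drawn uniformly from [−1, 1] and never trained; only the
output weights are fitted, in closed form, as `β = H⁺ T` with
`H = sigmoid(Xw + b)` and `T` one-hot targets. The pseudoinverse uses an SVD
with the Moore–Penrose rank cutoff `max(dim(H)) · eps` relative to the
largest singular value: it discards only numerically zero directions, so a
full-rank square `H` interpolates its training set exactly while hidden
matrices made rank-deficient by constant features remain stable. The random
input layer is exactly what makes the ensemble diverse: two members trained
on identical data but different seeds are different classifiers.

Defaults: `hidden = 50` nodes, sigmoid activation, per-member seeds derived
from the pool's master seed. The hidden count is a genuine knob — too few
nodes underfit the 8-feature windows, too many make resubstitution accuracy
saturate at 1 for every subset, flattening the fitness landscape.

### Features

Windows of 0.5 s with 50 % overlap (both configurable) are summarized by
eight order-free statistics: max, min, mean, RMS, the *population* standard
deviation `σ = sqrt(mean((a − ā)²))` (the 1/N form, not N−1), skewness
`S = mean((a − ā)³)/σ³`, *raw* kurtosis `K = mean((a − ā)⁴)/σ⁴` (a Gaussian
window sits near 3; this is not excess kurtosis), and energy `E = Σ|aᵢ|²`.
For constant windows `σ = 0` and we define `S = K = 0` rather than raising:
all-zero windows are a legitimate product of the missing-data rule below.
Features are min–max normalized to [0, 1] with bounds fitted on training
rows only; test values outside the training range are clipped, preserving
the interval invariant without leaking test statistics.

Missing samples are repaired per window: a window more than half missing is
zeroed wholesale; otherwise each gap copies the nearest preceding observed
value (a leading gap takes the first observed value). The "more than half"
test is deliberately scoped to the window — it keeps the rule local, makes
it unit-testable, and means one long dropout cannot zero an entire
recording.

## The optimizer

Classical glowworm swarm optimization moves agents in a continuous space:
each worm carries luciferin `l_i(t) = (1 − ρ) l_i(t−1) + γ J(x_i(t))`,
is attracted to brighter worms within an adaptive decision radius, and
steps toward one of them. Subset selection is a binary space, so the
continuous step is replaced and three further devices are added:

* **Bulletin board.** The best mask and fitness ever evaluated are recorded
  each iteration. Elitism lives here, not in the swarm: mutation may destroy
  any worm, but the board never regresses, which is why the logged
  convergence trace is non-decreasing by construction.
* **Probabilistic binary move.** Moving worm `i` toward target `j` decides
  each bit with a fresh uniform draw `r`: keep the own bit if `r ≤ p1`
  (0.15), copy the target's bit if `p1 < r < p2` (0.85), otherwise draw a
  random bit. The per-bit random branch (expected flip rate
  `(1 − p2)/2 = 0.075`) is the optimizer's background exploration.
* **Composite three-candidate search.** Each worm generates candidates
  toward (a) the bulletin best, (b) the brightest neighbour within its
  decision radius, (c) a uniformly random neighbour, and adopts the fittest
  candidate; ties resolve in that order, preferring exploitation. With no
  neighbours (all dimmer, or radius collapsed) the bulletin candidate
  competes against the current position alone.
* **Decaying mutation.** After moving, every bit flips with probability
  `R(t) = (1 − t/t_max)² `: rate 1 at t = 0, 0.25 at half time, 0 at the end
  — global search early, local refinement late.

Distance between binary positions is Hamming distance — the canonical
choice for subset masks — and the sensing radius defaults to `M`, so initial
neighbourhoods are global. Defaults follow the standard parameterization:
`ρ = 0.4`, `γ = 0.6`, radius gain `β = 0.08`, neighbour threshold
`n_t = 5`, `t_max = 300`, population 30, initial luciferin `l0 = 5`.
Population size, `l0` and the initial radius are conventions of the swarm
literature rather than derived values; they are exposed in
`ibgso_config()` and recorded in every report.

Two numerical details deserve note. All-zero masks (possible after mutation)
are repaired by setting one uniformly random bit, since the fitness requires
`m > 0`. And the radius update is implemented in two modes: the default
`"standard"` cumulative form `rd ← clamp(rd + β(n_t − |N|), 0, r_s)`, and a
memoryless `"as_printed"` form `clamp(β(n_t − |N|), 0, r_s)` that appears in
some formulations; with β = 0.08 and n_t = 5 the memoryless form caps the
radius at 0.4, below the minimum Hamming distance of 1, emptying every
neighbourhood and reducing the search to bulletin-driven moves only. Both
modes are tested; the cumulative default keeps the neighbourhood mechanism
alive.

Fitness evaluations are memoized by mask — there are at most `2^M − 1`
distinct subsets, and on a 16-sensor pool a 300-iteration run revisits masks
constantly; memoization makes the fused-vote evaluation the cost of a table
lookup after first sight. For pools of up to 20 sensors,
`exhaustive_oracle()` enumerates all subsets and serves as the ground-truth
optimum in tests; ties go to the lexicographically smallest selected-index
set.

## The evaluation protocol

`run_protocol()` runs leave-one-subject-out (LOSO) cross-validation: one
fold per subject, features extracted once, normalization bounds and the ELM
pool fitted on the training subjects only (the suite asserts that perturbing
the held-out subject's raw values changes no trained model). Per fold the
swarm selects a mask on training data, and both the pruned ensemble and the
full "ensemble all" baseline are scored on the held-out subject. Per-fold,
per-repeat seeds derive from the master seed by a fixed counter scheme, so
an entire report reproduces bit-for-bit from `(dataset, config)`. Repeats
(`n_repeats`) re-randomize both the ELM input layers and the swarm; the
default is 1 because the bundled benchmark is instead repeated over master
seeds.

Metrics are computed one-vs-rest per class from the confusion matrix
(rows = true, columns = predicted); the headline F1 is the macro average,
with the micro average also reported, since averaging conventions differ
across the HAR literature. Zero-denominator rates are defined as 0.

## The synthetic benchmark and what it can show

`demo16_spec()` defines the standing test bed: 5 subjects × 4 activities ×
16 sensors at 25 Hz, 16 s per subject-activity run, sensors 1–4 informative,
amplitude-to-noise ratio 10. Informative sensors emit, for activity `k`, a
sinusoid of amplitude `1 + 0.5(k − 1)` and frequency `k × 1 Hz` plus
Gaussian noise of sd amplitude/snr and a constant per-(subject, sensor)
offset (sd 0.5); the other twelve sensors are unit Gaussian noise. The
1 Hz base cadence matches slow human locomotion and is chosen deliberately:
a 0.5 s window covers less than one cycle of the slowest activity, so
window statistics depend on phase and a single sensor is an *imperfect*
classifier. That is the regime in which ensemble selection is a meaningful
problem — were every informative sensor individually near-perfect, the
size-penalized optimum would be a trivial singleton. The per-subject offsets
create the train/test shift that LOSO is designed to expose: resubstitution
accuracy is optimistic, held-out accuracy is not.

The generator emulates class-dependent oscillation statistics, subject
heterogeneity, balanced designs and bursty missing data
(`inject_missing()`). It does **not** emulate biomechanical coupling between
axes, label noise, transition segments between activities, sensor drift, or
unbalanced activity durations. Passing the bundled benchmark therefore shows
that the pipeline separates informative from uninformative sources and that
pruning does not cost held-out accuracy *under those idealized conditions*;
it does not certify performance on any real recording.

Problem sizes in the bundled evaluation were chosen so the full benchmark
(5 master seeds × 5 LOSO folds, swarm population 30, 300 iterations)
completes in a few minutes on one CPU: 16 s of signal per subject-activity
run gives 65 windows per (subject, activity, sensor) series — roughly a
thousand training windows per sensor per fold, comfortably enough for an
8-feature, 50-node ELM.

```{r demo, eval = FALSE}
ds <- generate_dataset(demo16_spec(seed = 42))
report <- run_protocol(ds, protocol_config(ibgso = ibgso_config(t_max = 300),
                                           seed = 42))
print(report)
recover_informative(report, informative_ids(ds))
```

On this benchmark the selections typically keep 1–3 informative sensors and
no noise sensors (pooled over folds they recover the informative set), prune
more than 80 % of the pool, and beat the all-sensor vote on held-out
subjects — the all-sensor ensemble drowns four informative voters among
twelve noise voters, which is precisely the failure mode selective
ensembling exists to fix.

## Known limitations

* Resubstitution `A_tr` overfits with large hidden layers; if every subset
  reaches training accuracy 1, the fitness degenerates to size-only and
  selection within the informative set becomes arbitrary. Reduce `hidden`
  or use more training subjects if you observe saturated fitness traces.
* The optimizer is stochastic; on rugged landscapes it attains the
  exhaustive optimum in most but not all seeds (the suite requires ≥ 80 %
  on 10-sensor lookup tables). For pools of ≤ 20 sensors the exhaustive
  oracle is the definitive answer.
* Majority voting ignores confidence; classes confusable by every sensor
  stay confusable after selection.
* The CSV ingestion contract is the long format
  `subject,activity,sensor,sample_index,value`; adapters for specific
  public archives are out of scope.
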