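# glowsel

Sensor deployment optimization for multi-sensor human activity recognition
(HAR) by selective-ensemble pruning with an improved binary glowworm swarm
optimizer.

## The problem

Body-sensor networks for HAR place many inertial sensors on the body, train
a classifier per sensor source, and fuse the per-sensor decisions. More
sensors mean more power, more bandwidth and more obtrusion — and many
sensors add little accuracy. Choosing which sensors to deploy is an
ensemble-pruning problem: with `M` base classifiers there are `2^M − 1`
non-empty subsets, and finding the best-performing one is NP-complete.

`glowsel` implements the full select-then-deploy pipeline for users who want
to answer "which sensors are worth wearing?":

1. **Preprocessing** — missing-data repair (segments more than half missing
   are zeroed; short gaps copy the previous sample), sliding windows
   (default 0.5 s, 50 % overlap), and eight time-domain features per window:
   max, min, mean, RMS, population standard deviation σ, skewness S,
   (raw) kurtosis K, and signal energy E = Σ|aᵢ|², min–max normalized to
   [0, 1] on training data only.
2. **Base classifiers** — one extreme learning machine (ELM) per sensor
   source: random input weights `w`, biases `b` ~ U[−1, 1], hidden layer
   `H = σ(Xw + b)`, and closed-form least-squares output weights
   `β = H⁺T` against one-hot targets.
3. **Decision fusion** — majority voting over the selected members, ties
   broken toward the smaller class label.
4. **Subset search** — a binary glowworm swarm maximizing

   ```
   fitness = ω · A_tr − (1 − ω) · m / M,     ω = 0.95
   ```

   where `A_tr` is the training accuracy of the masked fused ensemble and
   `m` the number of selected sensors: at equal accuracy, the smaller
   ensemble wins. The swarm extends classical glowworm swarm optimization
   (luciferin update `l(t) = (1 − ρ)l(t−1) + γJ`, adaptive decision radius)
   to binary spaces with four devices: a **bulletin board** remembering the
   best mask ever seen; a **probabilistic bit move** (keep / copy-target /
   randomize per bit with thresholds p₁ = 0.15, p₂ = 0.85); a **composite
   three-candidate search** toward the bulletin best, the brightest
   neighbour and a random neighbour, adopting the fittest candidate; and a
   **decaying mutation** flipping bits with probability `R = (1 − t/t_max)²`.
5. **Evaluation** — leave-one-subject-out (LOSO) cross-validation with
   accuracy, per-class precision/recall/F1, macro-F1 and confusion matrices,
   always against the "ensemble all" baseline.

Because real multi-sensor archives are large and externally licensed, the
package ships a synthetic-data module generating multi-subject recordings
in which a *known* subset of sensors carries class-dependent oscillations
(activity k: amplitude `1 + 0.5(k−1)`, frequency `k` × 1 Hz, noise sd =
amplitude/snr, constant per-subject offsets) and the rest are pure noise —
so selection quality can be scored against ground truth.

## Worked example

```r
library(glowsel)

spec   <- demo16_spec(seed = 42)            # 5 subjects, 16 sensors, 4 informative
ds     <- generate_dataset(spec)
report <- run_protocol(ds, protocol_config(ibgso = ibgso_config(t_max = 300),
                                           seed = 42))
print(report)
#> leave-one-subject-out evaluation over 5 run(s), pool of 16 sensors (omega = 0.95)
#>   pruned ensemble : accuracy 0.9869, macro-F1 0.9871, mean size 2.6
#>   ensemble all    : accuracy 0.7954, macro-F1 0.7945, size 16

recover_informative(report, informative_ids(ds))$per_run
#>   run precision recall jaccard size
#> 1   1         1   0.75    0.75    3
#> 2   2         1   0.75    0.75    3
#> 3   3         1   0.25    0.25    1
#> 4   4         1   0.75    0.75    3
#> 5   5         1   0.75    0.75    3
```

Reading: on every LOSO fold the swarm discarded all twelve noise sensors
(precision 1) and kept 1–3 of the four informative ones (mean ensemble size
2.6 of 16, i.e. > 80 % pruned), and the pruned ensemble beat the
all-sensor majority vote on held-out subjects by ~0.19 accuracy. Pooled
over folds the selection recovers the informative set exactly (Jaccard 1).

A thin CLI wraps the same functions (`inst/cli/glowsel`):

```sh
Rscript inst/cli/glowsel simulate --output out --seed 1
Rscript inst/cli/glowsel optimize --input out/dataset.csv --output out --seed 1
Rscript inst/cli/glowsel evaluate --input out
Rscript inst/cli/glowsel oracle   --input out/dataset.csv --seed 1
```

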