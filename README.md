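# capfuse

Second-by-second detection of cyclic alternating pattern (CAP) **A phases**
in sleep EEG by **feature-level fusion of multiple channels**, with the
classifier architecture chosen by bit-string metaheuristics.

CAP is a periodic NREM-sleep EEG activity alternating transient activation
events (A phases, 2–60 s) with returns to background activity; its load
marks unstable sleep and is altered in disorders such as nocturnal frontal
lobe epilepsy. Scoring A phases manually over a whole night is slow and
only fairly reproducible, and most automatic detectors read a single
channel even though A phases are visible across cortical areas. `capfuse`
is for researchers in sleep EEG and multichannel biosignal classification
who want an end-to-end, fully testable implementation of:

* a **fusion classifier**: per-channel (bi)directional LSTM branches over
  windows of `T` one-second epochs (100 samples each at 100 Hz), feature
  concatenation `f = [f1 … fn]`, optional dense layers of size `S`, and a
  2-unit softmax head, trained with cost-sensitive Adam
  (class weights `N/(2·Nc)`, learning rate 0.001, batch size 1024) —
  implemented in plain R matrix algebra with finite-difference-verified
  backpropagation through time;
* a **15-bit architecture genome** (channel mask, `T`, layers, direction,
  `H`, dropout, `S`, activation; 7·2¹² = 28,672 valid patterns) searched by
  a **genetic algorithm** (tournament-of-two, two-point crossover,
  mutation `m(g) = max(0.01, 0.2·0.7^⌊(g−1)/5⌋)`, two elites) or
  **discrete binary PSO** (ring topology, inertia
  `ω(i) = max(0.4, 0.9·0.91^⌊(i−1)/5⌋)`, `c1 = 0.6`, `c2 = 0.3`, bitwise
  `P(x_d = 1) = σ(v_d)`);
* the **evaluation protocol**: Chebyshev-I(8, 0.05 dB, 0.8/s) zero-phase
  anti-alias resampling to 100 Hz, per-recording standardization,
  subject-independent two-fold CV (the optimizers' fitness is the mean
  fold AUC) and leave-one-subject-out assessment with ROC-optimal
  (Youden's J) thresholds and isolated-label correction (010→000,
  101→111);
* **robustness protocols**: channel-loss substitution (all 10 scenarios
  for 3 channels) and additive white Gaussian noise at −20…20 dB SNR,
  applied at test time only;
* a seeded **synthetic CAP-like generator** (correlated 1/f background,
  amplitude-burst events of 2–60 s, configurable prevalence and
  channel visibility) so everything above runs without clinical data.

## Worked example

```r
library(capfuse)

# a 6-subject synthetic cohort, 10 min per subject, two groups
# (3 disorder-free-like at 15% A-phase prevalence, 3 disorder-like at 21%)
cohort <- generate_cohort(cap_sim_params(n_subjects = 6, duration_s = 600,
                                         seed = 7))

# a scaled-down 3-channel bidirectional fusion model
cfg <- cap_config(hidden = 16, time_steps = 5)
res <- loo_evaluate(cfg, cohort, cap_control(epochs = 5, seed = 1))
res
#> Leave-one-subject-out evaluation over 6 subjects
#>   ACC: 83.86% +/- 2.52 (79.19-86.07)
#>   SEN: 61.96% +/- 10.72 (48.86-73.81)
#>   SPE: 88.77% +/- 2.78 (85.97-93.58)
#>   AUC: 80.07% +/- 5.02 (74.09-87.62)
```

Each row of `res$per_subject` is one cold-started training on the other
five subjects, thresholded on the training ROC (Youden's J), post-processed
and scored on the held-out subject; AUC is threshold-free. The run takes
about half a minute on one CPU; on this synthetic cohort the fused model
separates A-phase seconds far above chance (AUC 0.5) after five epochs,
with the usual sensitivity/specificity trade-off of a rare positive class.

The published reference architectures are built-in:

```r
summary(build_fusion(reference_config("ga")))
#> Fusion classifier configuration
#>   channels : Fp2-F4, F4-C4, C4-A1
#>   recurrent: 1 x BLSTM layer(s), 100 units/direction, T = 10
#>   dense    : S = 300 (sigmoid), dropout 15%
#>   trainable parameters: 934,202 (closed form 934,202)
#>   class weights: 1 / 1
count_valid_configurations()
#> [1] 28672
```

Architecture search runs through the same interface with any fitness:

```r
run_ga(function(bits) sum(bits), ga_params(seed = 1))$best_fitness   # OneMax: 15
fit <- make_tfcv_fitness(cohort, cap_control(epochs = 2))            # real fitness
```

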