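---
title: "Methods: synthetic ErrP decoding and feedback-guided reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ErrP decoding and feedback-guided reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(errpRL)
```

This package implements, end to end and in simulation, the two halves of a
brain-computer-interface (BCI) driven robot-training study: decoding
error-related potentials (ErrPs) from EEG while a person watches a robot
navigate, and using that decoded feedback to guide a deep reinforcement
learning agent. This vignette documents the models, the free parameters and
their defaults, the numerical choices, and what the simulations can and
cannot show.

## 1. The synthetic EEG generator

Real ErrP recordings are not redistributable, so every analysis here runs on
synthetic EEG whose *structure* follows the well-established ErrP
literature: observing an erroneous action evokes a frontocentral negativity
around 200 ms (N200) followed by a delayed positivity between roughly 300
and 600 ms.

The single-trial model is deliberately minimal:

* **Evoked shape.** Two Gaussian bumps in time — a negativity (default
  −6.5 µV, center 200 ms, SD 45 ms) and a positivity (+8 µV, 450 ms, SD
  90 ms) — added only on error trials. Both classes share a small common
  evoked component (+2 µV at 300 ms) so that "correct" trials are not pure
  noise. The expected error-minus-true difference wave therefore equals the
  two-bump template exactly, which gives clean oracles for the
  grand-average and SNR tests.
* **Topography.** Each channel receives the template scaled by a fixed
  frontocentral weight in [0, 1] (maximal at Fz/FCz/Cz, decaying laterally
  and posteriorly; see `frontocentral_weights()`).
* **Noise.** Independent per-channel background noise, by default 1/f-shaped
  (white noise whose spectrum is reweighted by f^(−1/2), then rescaled to a
  6 µV standard deviation), plus a common 50 Hz mains component (1 µV) that
  exercises the notch filter. Per-trial latency jitter (SD 20 ms) smears
  the average, as real single trials do.
* **Scheduling.** Error trials are fixed-count — exactly
  `round(n_trials * error_fraction)` of them, uniformly shuffled — because
  the emulated protocols state exact totals (100 of 500 at 20%; 200 of 400
  at 50%).

**Calibration of the free parameters.** The literature fixes the morphology
but not single-trial amplitudes or noise levels, and the source study does
not quantify them either; they are free parameters of the simulation. The
defaults above were chosen once so that the four classifier families land in
a plausible decoding range for this kind of paradigm (bootstrap-mean test
ROC-AUC roughly between 0.85 for the time-domain-feature models and 0.98
for the CNN on the dry 20-channel montage at 500 epochs). Synthetic data
are *cleaner* than real EEG — no artifacts, stationary noise, a perfectly
repeating template — so absolute decoding numbers exceed typical
real-data values and must not be read as a reproduction of them; only the
relative structure (all families above chance, monotone in effect size,
chance-level on null data) is meaningful.

What the generator does *not* emulate: eye blinks and muscle artifacts,
electrode drift and impedance changes, non-stationarity across a session,
volume conduction between channels (noise is channel-independent), or
habituation of the ErrP. Passing tests on this generator show the
*pipeline* is correct, not that any decoder would reach these numbers on
real recordings.

## 2. Preprocessing

`preprocess_recording()` applies, in order: linear detrend over the whole
recording; zero-padding (1 s per edge, removed afterwards) to suppress
filter edge transients; a 50 Hz notch (4th-order IIR band-stop, 2 Hz wide);
a 1–10 Hz band-pass (4th-order Butterworth); common average reference;
downsampling to 250 Hz for 500 Hz recordings (plain decimation — the signal
is already band-limited to 10 Hz); epoching into half-open [−0.2 s, 1.0 s)
windows (300 samples at 250 Hz); and per-trial/channel baseline correction
over [−0.2, 0) s. The classifiers then work on the half-open window of
interest [0.2, 0.8) s — 150 samples.

Numerical choices worth stating:

* Filters are applied zero-phase (forward–backward, `signal::filtfilt`),
  preserving component latencies; the analysis is offline so the
  non-causality is harmless.
* "4th order" refers to the transfer-function order of each IIR stage.
* Baseline correction runs on the full epoch *before* the
  window-of-interest cut, so the interest window inherits the baseline
  alignment.
* Half-open windows make sample counts unambiguous: a (−0.2, 1.0) s window
  at 250 Hz is exactly 300 samples, and the onset sample belongs to the
  post-onset segment.

## 3. Classifiers

Four families, all evaluated with an outer repeated stratified k-fold
(5 splits; 10 repeats at full scale) and ROC-AUC, with every fitted
component — scaler, PCA, grid search, xDAWN filters, CNN weights — fitted
strictly inside training folds:

* **Features + LDA / RBF-SVC.** Five time-domain statistics per channel
  (mean, skewness, kurtosis, standard deviation, peak-to-peak; sample
  (n−1) convention for the SD, classical biased moment estimators for
  skewness/kurtosis), standardized, reduced to the principal components
  holding 95% of the variance, then classified. Hyperparameters come from
  an inner stratified 5-fold grid search: for the SVC, cost 10^−2…10^3 and
  kernel coefficient 10^−4…10^1 (log-spaced); for the LDA, the covariance
  estimator (`moment`/`mle`) — the solver variants of other
  implementations are numerically equivalent, so the estimator is the
  closest genuinely behavior-changing knob.
* **Riemannian tangent space.** Per class, xDAWN spatial filters (4 per
  class by default — enough to keep the augmented matrices
  well-conditioned between 16 and 64 channels) maximize evoked-to-total
  power; each trial is augmented with the filtered class prototypes, its
  covariance (with 5% shrinkage towards the scaled identity, guaranteeing
  positive definiteness on 150-sample windows) is mapped to the tangent
  space at the geometric mean of the training covariances (fixed-point
  iteration under the affine-invariant metric), and an LDA with default
  settings classifies the vectors. No hyperparameter search.
* **Compact CNN.** The standard depthwise/separable EEG architecture:
  8 temporal kernels of length rate/2 (125 samples), batch norm, depthwise
  spatial convolution with multiplier 2 (max-norm 1), batch norm, ELU,
  average-pool 4, dropout 0.5; separable convolution to 16 maps, batch
  norm, ELU, average-pool 8, dropout; dense softmax (max-norm 0.25). For
  (20 channels, 150 samples) this is exactly 2,042 trainable parameters.
  Trained with categorical cross-entropy, Adam at 0.01, batch 16, with the
  learning rate divided by 10 when the validation loss stagnates for 5
  epochs. The implementation is a hand-written vectorized
  forward/backward pass (no deep-learning framework is involved); its
  gradients are verified against finite differences in the test suite.
  After training, batch-norm statistics are recomputed as population
  moments over the training data under the final weights ("precise BN"),
  which makes evaluation stable even for short trainings.

Class imbalance (100 vs 400) is handled by stratification only; ROC-AUC is
threshold-free.

The 16-channel gel montage is a fixed frontocentral subset of the
64-channel layout (Fz, F1–F4, FC1–FC4, Cz, C1–C4, CP1, CP2). The original
selection is not published; this list is an assumption and is configurable.

**Problem sizes.** The package defaults reproduce the full protocol (5×10
outer folds, 300 CNN epochs). The shipped acceptance script and test suite
run scaled-down versions (5×3 folds, a few tens of CNN epochs, a few
hundred trials) chosen so the whole analysis runs on a laptop-class single
core; the statistical machinery is identical.

## 4. Bootstrap statistics

`bootstrap_mean()` implements the percentile bootstrap (5,000 iterations
for model and SNR comparisons, 1,000 for learning curves), with quantiles
at α/(2m) and 1−α/(2m) under a Bonferroni correction for m simultaneous
comparisons. BCa intervals are deliberately not used — the emulated
procedure states percentile limits. The significance reading of two
intervals is `ci_overlap_verdict()`: disjoint → strong (p<0.01), partial
overlap with both means excluded → moderate (p<0.05), otherwise not
significant.

The SNR of the ErrP contrast is computed on the channel-group-averaged
error-minus-true difference of trial averages: the absolute mean of the
trace inside the component interval (0.1–0.3 s for the N200, 0.3–0.6 s for
the delayed positivity) divided by the standard deviation of the trace
across the samples of the same interval. The "amplitude" reading (interval
mean, absolute) is a documented choice; a peak-based variant is available
(`amplitude = "peak"`), since the source procedure's wording does not name
a peak.

## 5. The navigation world

The robot task is reproduced at the level the RL problem is defined: a
21×21×11 grid, six unit moves, an obstacle wall spanning the full width at
the middle y-plane and rising to z-index 6 of 11 (the agent must climb
over), a 6×11 floor-level start region on the near side, the goal at floor
level on the far side, sparse reward 1 at the goal, a 160-step cap, and an
8-dimensional observation: the three coordinates normalized by (dim − 1)
plus five laser distances (−x, +x, −y, +y, −z; 5-cell range, clipped to
[0, 1]). Collisions leave the agent in place and are non-terminal by
default (the replay stratification needs collision transitions inside
ongoing episodes). Wall geometry, laser directions/range, reward magnitude
and collision semantics are not specified in the main text being emulated;
each is a documented assumption behind a configuration flag.

Within a run the goal is fixed and only the start varies between episodes
(`world_reset()`); the goal moves between runs. This matches the emulated
task and is also structurally necessary: the observation carries no goal
coordinates, so no policy could condition on a per-episode goal.

The optimal-action oracle ("green arrow") is the first move of a shortest
path under A* with the admissible Manhattan heuristic; ties between equally
short first moves are broken by the fixed action order (left, right,
forward, backward, down, up). Because all moves cost 1, breadth-first
search gives identical distances, which the test suite exploits as an
independent oracle (200 random worlds). Inner loops use the cached BFS
distance field of the current goal; `optimal_action(method = "astar")` and
`method = "bfs"` are verified to agree.

## 6. Human-feedback policy

The HF policy is a fully connected 8 → 32 (ReLU) → 6 (softmax) network
mapping an observation to per-action probabilities of receiving positive
feedback. Collection is epsilon-greedy on the improving policy (ε linear
1 → 0.1 over the 1,000-label budget; a pure-random mode exists as a
configuration option). Every executed action yields one feedback event —
labelled by the oracle, by a noisy keyboard (labels flipped with
probability 0.3), by a confusion-matrix BCI surrogate of configurable
per-class accuracy, or by the full closed loop (one synthetic EEG epoch
generated conditional on the action's true correctness, preprocessed and
classified by a CNN calibrated with `calibrate_bci()`, threshold 0.5 on
the error probability). Events are appended to an append-only store;
training batches (size 20) are stratified to 10% collision / 90%
non-collision transitions when enough collision samples exist. The
executed action's softmax output is trained toward its binary label with
binary cross-entropy and Adam (learning rate 0.001): the gradient touches
only that output's component, the most literal reading of the
softmax-plus-BCE pairing; a one-vs-all sigmoid variant was considered and
rejected as a larger departure from the stated architecture.

Two free parameters were set empirically and deserve honesty:

* **`updates_per_label` (default 4).** With a single gradient step per
  incoming label, feedback collected in rarely visited regions (beyond the
  wall, on the descent to the goal) never consolidates, and the frozen
  policy retains systematic mistakes there. A few steps per label (each on
  a freshly stratified batch) fix this without changing the data budget.
* **Exploration with the trained policy** (stage 3 below) samples from the
  policy's softmax rather than taking its argmax. A deterministic argmax
  policy in a deterministic grid turns any residual mistake into an
  absorbing loop: measured pure-argmax rollouts reach the goal essentially
  never even when per-state agreement with the oracle exceeds 90%, while
  softmax sampling — near-deterministic where the policy is confident,
  exploratory where it is not — reaches it almost always. The argmax
  variant remains available (`hf_greedy = TRUE`).

## 7. Discrete-action DDPG with guided exploration

The RL agent is DDPG adapted to the discrete action space: the actor ends
in a softmax over the six actions; the critic scores (state,
action-representation) pairs, where stored transitions enter one-hot and
the policy gradient ascends the critic's value of the actor's own action
distribution. Defaults
follow the emulated protocol: γ = 0.9, τ = 0.005 soft target updates,
Adam learning rates 0.003 (actor) and 0.001 (critic), 20 updates per
environment step on freshly sampled batches, ε decaying linearly from 1 to
0 at global step 125,000, 8,000 episodes of at most 160 steps. The replay
buffer fills `ceiling(0.1 × batch)` slots with the highest-reward
transitions (ties broken uniformly at random, so equal-reward
transitions are exchangeable rather than a fixed few being replayed in
every batch; prioritization is vacuous and
falls back to uniform when all stored rewards are equal) and draws the
rest uniformly without replacement. Exploration actions come from the HF
policy when one is supplied and are uniform random in the sparse baseline.
Unstated architecture details are configuration: two hidden layers of 64
rectified units, batch 64, buffer capacity 200,000. Because the critic is
trained exclusively on one-hot action inputs, it is also only *queried*
at one-hot inputs by default (`target_action = "expected"`): the TD
target is the exact expectation of the target critic over the six
actions under the target actor's softmax, and the actor gradient is the
exact gradient of the expected critic value under its own softmax.
Feeding the probability vector itself to the critic (`"soft"`), as a
literal continuous-DDPG translation would, asks the critic to
extrapolate to an input distribution it never saw during regression; at
desk scale this measurably destabilizes the post-handover policy (most
seeds collapse into deterministic loops once ε reaches 0). A one-hot
argmax variant (`"hard"`) is also provided.

Three further stabilizers address failure modes observed at desk scale
and documented here because each traces to a general property of the
algorithm rather than to tuning:

* **Timeout is not termination.** The step cap ends an episode but is
  not a state of the task; transitions are bootstrap-masked only on true
  task termination (goal, or collision when configured terminal).
  Masking on timeouts regresses the value of every slow state towards
  zero and poisons the value function exactly where learning is hardest.
* **Bounded TD targets** (`q_clip`, default `[0, 1]`). With a single
  unit reward on termination and discounting elsewhere, every attainable
  return lies in `[0, 1]`; clipping the bootstrapped target to that
  range removes the upward value spiral (critic overestimates feed the
  target of other states through the expectation) without biasing any
  attainable value. Training runs without the clip were observed with
  critic outputs far above the theoretical maximum.
* **Actor entropy bonus** (`actor_entropy`, default 0.01) and **sampled
  execution** (`actor_execution = "sample"`). A saturated softmax has
  vanishing policy gradients, so an actor that commits while the critic
  is still inaccurate is frozen forever — measured directly: per-state
  optimality of the greedy actor stuck at its initialization level for an
  entire run, then climbing to ~0.98 with the bonus enabled. Sampling
  the softmax at execution time is the distribution the actor objective
  actually optimizes and cannot be trapped in the deterministic loops an
  argmax policy falls into at any state it gets wrong (the same argument,
  and the same measurement, as for the HF policy above).

**Desk scale.** The full protocol (10 runs × 8,000 episodes × ≤160 steps ×
20 updates/step) is far beyond an interactive budget. The packaged
experiments therefore run a reduced world (7×7×3 with the same wall
structure, 30-step cap), 150 episodes, 4 updates per step, batch 32,
hidden layers 32/32, and an ε schedule ending at global step 1,000 so
that roughly the last third of each run is executed purely by the
learned policy — the same algorithm at smaller numbers. The
reduced runs are used to demonstrate the *ordering* finding (guided
exploration accelerates learning relative to the sparse baseline); the
absolute SPL values of the full protocol are not claimed at desk scale.

## 8. Evaluation

Per episode, SPL = S·ℓ/max(p, ℓ) with S the success flag, ℓ the shortest
path length at episode start (from the BFS field) and p the number of
executed moves *including* collision-blocked attempts — collisions
penalize SPL, consistent with "as quickly and efficiently as possible".
Learning curves are aggregated by resampling whole runs (pointwise
bootstrap band, 1,000 iterations) and final performance is the mean SPL
over a terminal window (500 episodes at full scale, 50 at desk scale — the
emulated report does not state its averaging window, so both the terminal
window and the whole-curve mean are available, with the terminal window as
default comparator).

## 9. Known limitations

* Synthetic EEG only; no claim transfers to real recordings (Section 1).
* The BCI-surrogate accuracy is a free parameter: the mapping from a
  decoder's ROC-AUC to realized single-trial feedback accuracy depends on
  the threshold and class balance and is reported separately, never
  equated with the AUC.
* Discrete-softmax DDPG inherits the known brittleness of off-policy
  actor-critic under sparse rewards and narrow (guided) action coverage;
  at desk scale the guided agent's advantage over the sparse baseline is
  robust, but absolute post-handover performance varies across seeds.
* The grid world has no physics: no arm kinematics, no self-collision
  geometry beyond the blocked-cell set, no rendering.
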