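# errpRL

Synthetic-EEG error-related-potential (ErrP) decoding and
human-feedback-guided reinforcement learning, in base R.

## The scientific problem

When a person watches a robot act, an erroneous action evokes a
stereotyped EEG response over frontocentral electrodes: a negativity
around 200 ms after the action (N200) followed by a delayed positivity
around 300–600 ms. If a classifier can detect this *error-related
potential* on single trials, the observer's brain becomes an implicit
feedback channel — every robot action gets a free "that was wrong" /
"that was fine" label without the person pressing anything.

This package implements both halves of that idea as a simulation study:

1. **Decoding suite.** A generative model of single-trial ErrP EEG
   (two Gaussian bumps on spectrally shaped 1/f background noise, plus
   50 Hz mains and a class-shared evoked component) over three montages
   (64- and 16-channel gel at 250 Hz, 20-channel dry at 500 Hz); the
   standard offline preprocessing chain (linear detrend, 50 Hz notch,
   1–10 Hz band-pass, common-average reference, downsample to 250 Hz,
   epoch −0.2–1.0 s, baseline-correct, 0.2–0.8 s window of interest);
   and four classifier families — statistical features + LDA, features
   + RBF-SVC (PCA 95% + inner grid search), xDAWN + Riemannian
   tangent-space + LDA, and a compact convolutional network — evaluated
   with repeated stratified cross-validation and bootstrap statistics.

2. **Feedback-guided navigation.** A discretized 3-D grid world with a
   wall, a 5-beam laser observation model, an exact shortest-path
   oracle (breadth-first search, verified against A*), a small
   human-feedback policy trained from binary "was that action right?"
   labels (delivered by a perfect oracle, a noisy oracle, or a
   simulated EEG decoder), and a discrete-action DDPG agent whose
   exploration is guided by that policy. Success weighted by path
   length (SPL) with run-level bootstrap bands quantifies how much
   guided exploration accelerates learning over the sparse-reward
   baseline.

## Worked example

Simulate one subject, preprocess, and evaluate two classifier families:

```r
library(errpRL)

# 1. simulate one subject: 20-channel dry montage at 500 Hz, 300 observed
#    robot actions, 20% of them erroneous
rec <- generate_recording(montage("dry20"), errp_model(),
                          n_trials = 300, error_fraction = 0.2, seed = 42)
print(rec)
#> <subject_recording: 20 ch x 301100 samples @ 500 Hz, 300 events (60 error)>

# 2. offline preprocessing chain (detrend, notch, 1-10 Hz band-pass, CAR,
#    downsample to 250 Hz, epoch, baseline-correct) and window of interest
epochs <- preprocess_recording(rec)
print(epochs)
#> <epoch_set: 300 trials (60 error) x 20 ch x 300 samples @ 250 Hz>
snr <- erp_snr(epochs, c("Fz", "Cz"), interval = c(0.3, 0.6))
cat(sprintf("frontocentral positivity SNR: %.2f\n", snr))
#> frontocentral positivity SNR: 1.04
iw <- extract_interest_window(epochs)

# 3. two classifier families under repeated stratified cross-validation
for (model in c("lda", "riemann")) {
  cv <- evaluate_cv(iw, model, splits = 5, repeats = 3, seed = 7)
  print(cv)
}
#> <cv_scores lda: 5 x 3 folds>
#>   train: <bootstrap mean 0.9925 [0.9916, 0.9934] (n=15, B=5000, m=1)>
#>   test:  <bootstrap mean 0.9246 [0.9064, 0.9405] (n=15, B=5000, m=1)>
#> <cv_scores riemann: 5 x 3 folds>
#>   train: <bootstrap mean 1.0000 [1.0000, 1.0000] (n=15, B=5000, m=1)>
#>   test:  <bootstrap mean 0.9734 [0.9628, 0.9839] (n=15, B=5000, m=1)>
```

The feedback-guided navigation study runs through a single declarative
entry point:

```r
rep <- run_experiment(list(
  world = list(dims = c(7, 7, 3), max_steps = 30),
  modes = c("sparse", "hf-oracle", "hf-noisy:0.3"),
  seeds = 1:5, episodes = 150, hf_labels = 1000, final_window = 50,
  ddpg = list(updates_per_step = 4, batch_size = 32,
              epsilon_end_step = 1000, buffer_capacity = 50000,
              hidden = c(32, 32))), out_dir = "runs")
```

which trains, per seed and mode, a human-feedback policy from 1,000
binary labels and then a DDPG agent whose exploratory actions are drawn
from that policy, and writes per-run SPL learning curves plus a
bootstrap comparison report.

A command-line front end for the EEG half lives at `inst/cli/errpRL`
(subcommands `simulate-eeg`, `preprocess`, `erp-report`,
`evaluate-classifier`, `run-rl`).

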