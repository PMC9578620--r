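# respigate

Respiratory-signal prediction and gating-error feasibility for
latency-compensated radiotherapy.

## The problem

Respiratory-gated radiotherapy turns the treatment beam on only inside
preselected breathing phases (here the 30% and 70% phase points of each
cycle), using an external 1D surrogate of chest motion sampled at 20 Hz.
The beam control chain reacts with a system latency of roughly 300–800 ms,
so by the time the beam actually switches, the breath has moved on. The
standard fix is to *forecast* the surrogate one latency ahead: a model reads
a window of T_s ms of signal and predicts the amplitude P_t ms past the
window's end (standard condition: T_s = 1000 ms, P_t = 500 ms).

`respigate` implements that study end to end for researchers in medical
physics and biomedical signal processing:

* a **synthetic surrogate generator** — cos^2n breathing cycles with
  per-cycle period/amplitude jitter, drift and noise — producing labeled
  cohorts in four regularity classes (regular, irregular period, irregular
  amplitude, both);
* a **breathing-irregularity taxonomy** built on the irregularity value
  `(STD(peaks) + STD(valleys)) / 2`, computed on extremum amplitudes and on
  cycle periods, with top-k cohort ranking into the four classes;
* three **sequence forecasters** — a 15×3 stacked LSTM, a bidirectional
  LSTM (`y_t = W_fy h_fwd + W_by h_bwd + b_y`), and an encoder–decoder
  Transformer (`softmax(QK'/sqrt(d_k))V` attention, 8 heads, look-ahead
  masking, one-position decoder offset) — implemented natively in
  RcppArmadillo with analytic backpropagation, trained by Adam
  (lr 1e-4, weight decay 2e-4, batch 300) with best-validation
  checkpointing;
* **evaluation**: RMSE and Pearson CC per held-out signal (predictions
  Savitzky–Golay smoothed as postprocessing), one-way ANOVA across models,
  and sweeps over T_s ∈ {1000, 1200, 1400} ms and P_t ∈ {300, 500, 700,
  900} ms;
* **gating feasibility**: each breathing cycle is split into 10 phases,
  the 30%/70% gate times of the predicted signal are located, amplitude is
  scaled to an assumed 10 mm tumor excursion, and
  `|actual(t_g) − predicted(t_g)|` is reported in millimetres per latency.

## Worked example

```r
library(respigate)

# 1. simulate a small labeled cohort (8 regular + 4 irregular signals)
gc <- default_group_configs()
cohort <- c(
  generate_cohort(8, group_configs = gc["regular"], seed = 1L,
                  duration_range_s = c(45, 60)),
  generate_cohort(2, group_configs = gc[c("type1", "type2")], seed = 2L,
                  duration_range_s = c(45, 60))
)

# 2. quantify breathing irregularity and classify
profiles <- classify_cohort(lapply(cohort, irregularity_profile), group_size = 2)
head(irregularity_report(profiles), 3)
#>     signal_id    amp_irr phase_irr combined_irr   group
#> 1 regular_001 0.01923177 0.1866292   -1.0871599    <NA>
#> 2 regular_002 0.02136639 0.1743595   -1.0910825 regular
#> 3 regular_003 0.02067748 0.2659720   -0.4754394   type1

# 3. split, window (T_s = 1000 ms, P_t = 500 ms) and train an LSTM
split <- split_cohort(cohort, n_test = 3, seed = 3L)
ds <- build_datasets(cohort, split, ts_ms = 1000, pt_ms = 500)
state <- train(init_predictor(predictor_spec("lstm", seed = 5L)),
               ds$train, ds$validation,
               training_protocol(epochs = 30, learning_rate = 2e-3))
state
#> <train_state lstm>: 30 epochs, best val MSE 0.151861 (final 0.151861)

# 4. accuracy on held-out signals
ev <- evaluate_model(state$model, ds$test)
round(c(rmse = ev$rmse, cc = ev$cc), 4)
#>   rmse     cc
#> 0.3795 0.9257

# 5. millimetre gating error at the 30%/70% phases for a 10 mm excursion
sig <- zscore_normalize(cohort[[1]])
ps <- predicted_signal(state$model, sig, ts_ms = 1000, pt_ms = 500)
act <- scale_to_motion(ps$actual, 10)
prd <- apply_motion_map(ps$predicted, act$metadata$mm_map)
gating_error(act, prd, latency_ms = 500)
#> <gating_error_report>: latency 500 ms, 26 gate errors, mean 0.820 mm, max 2.383 mm
```

Reading the output: the per-signal irregularity values place each trace on
the amplitude and period axes (z-standardized and summed in
`combined_irr`); the trained LSTM predicts z-scored amplitude 500 ms ahead
with RMSE 0.38 and correlation 0.93 on held-out signals; at a 10 mm tumor
excursion this corresponds to a mean gate-amplitude error of 0.8 mm (max
2.4 mm) at the 30%/70% phases — the quantity that decides whether a 500 ms
beam latency is clinically tolerable. Larger cohorts, more epochs, the
Bi-LSTM/Transformer, the T_s/P_t sweeps and the multi-latency feasibility
grid all run through the same functions (`run_sweep()`,
`feasibility_study()`) or in one shot via `run_experiment()` and the thin
CLI in `inst/cli/respigate.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline at desk scale — simulating a
cohort, classifying it, training all three predictors at the standard
condition, evaluating them and computing the 500 ms gating-feasibility
grid — and writes the (empty) acceptance-target report to `--out`. The
qualitative claims themselves (oracle equivalence of every core operation,
closed-form identities, the standard-condition accuracy level, horizon
degradation, irregularity sensitivity, the latency trend, taxonomy label
recovery, and end-to-end determinism) live in
`tests/testthat/test-acceptance.R`.

## Scope notes

The published patient-data results this pipeline mirrors were measured on
540 undeposited clinical recordings; this package reproduces the method and
its qualitative behaviour on synthetic cohorts, not those numbers. See the
methods vignette (`vignettes/respigate-methods.Rmd`) for the model
assumptions, parameter defaults with units, numerical choices, and known
limitations.
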