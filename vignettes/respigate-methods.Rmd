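---
title: "Methods: respiratory-signal forecasting and gating-error feasibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory-signal forecasting and gating-error feasibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiratory-gated radiotherapy delivers the beam only inside preselected
respiratory phases (here the 30% and 70% phase points of each breathing
cycle). The beam control chain reacts with a system latency of roughly
300–800 ms, so the gating decision must be made on a *forecast* of the
respiration surrogate that latency ahead. `respigate` implements the full
desk-scale pipeline for studying that problem: a surrogate generator with
controlled irregularity, windowed dataset construction, three sequence
forecasters (stacked LSTM, bidirectional LSTM, encoder–decoder Transformer)
trained with Adam and best-validation checkpointing, RMSE/correlation
evaluation with window-geometry sweeps, and translation of prediction error
into millimetre gating error under an assumed tumor excursion.

Throughout, `T_s` is the input-window length in ms (standard condition
1000 ms = 20 samples at 20 Hz), and `P_t` the forecast horizon in ms
(standard condition 500 ms = 10 samples), matched to the machine latency it
compensates.

## The synthetic-data generator: a stated world

No patient recordings are distributed with this package, so every
quantitative statement the tests make is about *synthetic* cohorts. The
generator (`generate_signal()`) uses the cos^2n breathing model: cycle *i*
has period `tau_i = base_period_s + e_tau` and peak-to-valley amplitude
`b_i = base_amplitude + e_b`, with zero-mean normal jitters truncated at
`0.5 * base_period_s` and `0.2 * base_amplitude` so no cycle degenerates.
Within the cycle the waveform is `b_i * cos^(2n)(pi t / tau_i)` minus its
cycle mean; linear drift and white per-sample noise are added. The exponent
`n = 2` gives the long exhale dwell and sharp inhale peak typical of real
surrogate traces. Defaults — period 4 s (quiet breathing is 3–6 s),
unit amplitude (the clinical recorder is unitless), drift 0.001/s, noise
SD 0.02 — are plausibility choices for guided free breathing, not fits to
any cohort; the source study reports only duration statistics
(84.35–272.50 s at 20 Hz), which `generate_cohort()` uses as its default
duration range.

The four regularity classes are produced purely by the two jitter knobs:
`regular` (period SD 0.05 s, amplitude SD 0.02), `type1` irregular period
(0.80 s), `type2` irregular amplitude (0.35), `type3` both. The knobs are
deliberately well separated so the irregularity taxonomy can be validated by
label recovery.

What the generator does *not* emulate: coughs, breath-holds, baseline steps,
cardiac interference, or any coupling between surrogate and internal tumor
trajectory. A green test on this world establishes that the pipeline's
machinery is correct and that the qualitative trends (horizon degradation,
irregularity sensitivity, latency dependence) emerge for quasi-periodic
breathing; it does not establish clinical accuracy levels.

## Preprocessing decisions

* **Per-signal Z-scoring** with the population (divisor-N) standard
  deviation. The choice of divisor is irrelevant to rankings but is fixed for
  reproducibility.
* **Temporal 7:3 split.** Each training signal contributes its first 70% of
  samples to training windows and the rest to validation windows; no window
  straddles the boundary. A random split of overlapping windows would leak
  future samples into training, so the split is temporal even though the
  source protocol does not state its mechanics. Whole held-out signals form
  the test role.
* **Windowing** is stride-one: a signal of `N` samples yields
  `N - L - H + 1` (input, target) pairs. For budgeted runs the *training*
  set may be subsampled to every k-th window (`train_thin`); this is pure
  runtime control — adjacent windows overlap in 19 of 20 samples — and
  validation/test windows are never thinned for metrics (a `val_thin` option
  exists for the per-epoch checkpointing loss only).
* **Savitzky–Golay filter** (window 5 = 250 ms, order 2 by default) is
  applied to the *predicted* series as postprocessing, never to network
  inputs. Edge handling is mirror reflection by default; note that mirror
  padding reproduces polynomials exactly only away from the edges, so an
  `edge = "interp"` mode (evaluate the first/last full-window fit at the edge
  positions) is provided where exact polynomial reproduction at every sample
  matters. Whether targets should also be filtered is ambiguous in the
  source description; filtering predictions only is the default and the
  alternative is a caller-side one-liner.

## The irregularity taxonomy

The irregularity value of a series pair is
`(STD(peaks) + STD(valleys)) / 2` (population STD), computed on extremum
amplitudes (amplitude irregularity) or on peak-to-peak and valley-to-valley
periods in seconds (phase irregularity). The extremum detector — prominence
≥ 0.2 signal units, minimum separation 1.5 s, alternation enforced by
dropping the lesser of two same-kind neighbours — is this package's own,
since no detector is specified by the source.

Group assignment standardizes both irregularity axes within the cohort
before ranking, because amplitude (z-units) and period (seconds) are
incommensurable and their sum is otherwise dominated by whichever axis has
larger spread. Groups of `group_size` are then taken with exclusion in the
order: highest combined → `type3`, highest phase → `type1`, highest
amplitude → `type2`, lowest combined → `regular`, ties broken by signal id.
The source text contradicts itself on whether type 1 ranks on amplitude or
period irregularity; the definitional sentence (type 1 = irregular
*period*) is followed, and `flip_axes = TRUE` reproduces the other reading.

## The three forecasters

All three models map a `T_s` window of the standardized surrogate to the
single amplitude `P_t` ahead, and all are implemented natively
(RcppArmadillo) with analytic backpropagation — no deep-learning framework
is involved. Gradient correctness is pinned by finite-difference tests.

* **LSTM**: 15 stacked layers of hidden size 3 (the comparison study's
  stated architecture), scalar input, affine readout of the final hidden
  state. The standard cell with separate input-gate parameters is the
  default; `tied_input_candidate = TRUE` reproduces the literal published
  gate equations in which the input gate shares `W_c, b_c` with the
  candidate.
* **Bi-LSTM**: each layer runs a forward and a time-reversed LSTM and merges
  them as `y_t = W_fy h_fwd + W_by h_bwd + b_y`; layers stack on the merged
  sequence; readout from the final position of the top layer.
* **Transformer**: scalar embedding to `model_dim`, summed with sinusoidal
  position encodings; post-norm encoder layers (multi-head attention,
  feed-forward with ReLU, residual + layer norm around each); decoder layers
  with look-ahead-masked self-attention, encoder–decoder attention and
  feed-forward. The decoder input is the window delayed by one position
  (first sample repeated as start token) — the stated one-position offset —
  and the final decoder position is mapped to the forecast. 8 heads and 6
  encoder/6 decoder layers are the stated defaults; the source also
  describes a four-layer variant, available via
  `n_encoder_layers = n_decoder_layers = 4`. Width is unstated in the
  source; `model_dim = 32`, `feedforward_dim = 128` are this package's
  defaults, ample for a scalar signal and sized for single-CPU training.

**Initialization** is uniform with fan-in scaling under the spec's seed. For
the recurrent stacks the plain `1/sqrt(fan_in)` range is unusable: through
15 layers of width 3 each layer damps its input by roughly a factor 5, so
the top of the stack receives no signal (prediction SD at initialization
~1e-10) and training can only fit the mean. `init_gain = 4` widens the
range to near-unity signal gain per layer at this width, and
`forget_bias = 1` keeps the cell-state path open — both standard devices
for trainable LSTMs, exposed as spec fields.

## Training protocol and desk-scale adjustments

The protocol object defaults to the stated regime: Adam, learning rate 1e-4,
weight decay 2e-4 (added to the gradient), betas 0.9/0.999, batch 300,
100 epochs, with the lowest-validation-loss snapshot retained and returned.

The source regime amounts to hundreds of thousands of Adam steps (480
signals × ~2000 windows each / 300 per batch × 100 epochs). The acceptance
runs in this package train on a 40-signal cohort for 30 epochs — roughly
2000 steps — so the recurrent models use a desk-scale learning rate of
2e-3, the linear-scaling compensation for the ~100× smaller step budget
(the Transformer converges within the budget at the original 1e-4 and keeps
it). These rates are part of the scaled-down world and are fixed in the test
helpers, not tuned per criterion.

## Evaluation

RMSE and Pearson correlation are computed per test signal on the S–G-filtered
predicted series against the actual targets, then averaged across signals
(pooled computation is available via `pooled = TRUE`); whether the source
averaged per signal or pooled windows is unstated. The across-model
comparison uses a classical one-way ANOVA (equal variances) on per-signal
RMSE or CC values, one group per model. `run_sweep()` retrains from scratch
at every `(T_s, P_t)` grid cell so cells are independent and reproducible
from the master seed.

## Gating feasibility

The predicted series is assembled on the actual time axis (element *i* of
both series is the amplitude at sample `i + L + H - 1`). The *actual* signal
is rescaled so its global peak-to-peak span equals the assumed tumor
excursion (10 mm default; 5 mm via `motion_mm`), and the *same* affine map
is applied to the predicted series — rescaling each independently would
erase exactly the amplitude errors being measured. Global rather than
per-cycle scaling preserves amplitude irregularity.

Cycles run peak-to-peak with phase 0% at the inhalation peak (the 4DCT
convention; the source never states its origin) and increase linearly to
100% at the next peak. The gate time for phase p% is
`start + (p/100) * period`, and the error at each 30%/70% gate of the
*predicted* signal's decomposition is `|actual(t_g) - predicted(t_g)|` with
linear interpolation between samples. The sentence defining this error
admits a second reading — the actual amplitude at the predicted gate versus
at the actual signal's own gate — which `convention = "actual_vs_actual"`
implements. Reports carry per-cycle errors plus the mean and maximum; the
feasibility study aggregates the mean of per-signal means and the overall
maximum per (pattern × latency × model × gate).

## Numerical choices and degenerate inputs

* Jitter truncation bounds (`0.5 * period`, `0.2 * amplitude`) prevent
  non-positive cycles; they bias the jitter distribution negligibly at the
  default SDs.
* Constant signals are rejected by Z-scoring and by `scale_to_motion`
  (degenerate-signal errors); windowing rejects signals shorter than
  `L + H`; extremum detection requires at least two peaks and two valleys,
  irregularity profiles at least three of each (two periods).
* `ts_ms`/`pt_ms` must be positive multiples of the 50 ms sampling interval;
  off-grid values are rejected, not rounded, and off-rate CSV inputs are
  rejected, not resampled.
* Attention masks use additive −1e30 before the softmax (−Inf would NaN a
  fully masked row); layer norm uses epsilon 1e-5; ties in cohort ranking
  break by signal id so classification is deterministic.
* The experiment driver fans the master seed out to per-stage seeds through
  a fixed integer hash (`stage_seed`), so no stage consumes another's random
  stream; all artifacts are written with fixed-precision formatting and the
  manifest hashes are therefore byte-reproducible.

## Known limitations

* The 1D surrogate is assumed identical to tumor motion when scaled; real
  surrogate-to-tumor correspondence is patient- and site-specific.
* The published headline numbers (e.g. test RMSE 0.1554 / CC 0.9768, mean
  gating errors up to ~3 mm at 700 ms) derive from 540 undeposited patient
  signals; nothing here reproduces them quantitatively, and the tests only
  assert the qualitative trends on synthetic cohorts.
* Training runs single-threaded on CPU; the hand-written engine is fast
  enough for desk-scale studies, not for cohort-scale hyperparameter
  searches.
* The irregularity taxonomy is a ranking, not a calibrated severity scale;
  group membership depends on the cohort it is computed in.
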