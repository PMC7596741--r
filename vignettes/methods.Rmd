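---
title: "Canonical representations and kinematic decoding: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical representations and kinematic decoding: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what is fitted, under which assumptions, which knobs
matter, what the synthetic sessions do and do not emulate, and where the
methods are known to break down.

## The decoding problem

A session pairs per-unit spike trains from motor cortex with a uniformly
sampled 2D hand trajectory, segmented into trials. The decoding target is
instantaneous hand velocity; speed enters as a third kinematic variable
because motor cortical firing carries both directional and speed
modulation. All analysis works on a fixed preprocessing chain:

1. **Binning** — non-overlapping 50 ms windows; firing rate = count / width.
2. **Square root** — variance stabilisation for Poisson-like counts. The
   transform reduces skewness for units whose bin counts are not dominated
   by the atom at zero (empirically, mean counts of roughly 0.5 per bin and
   up); for near-silent units it over-corrects, which is harmless here
   because such units rarely pass the tuning screen.
3. **Gaussian smoothing** — per-unit convolution, SD 80 ms for center-out
   sessions and 140 ms for sequential ones (defaults; both exposed). The
   kernel is truncated at ±4 SD and renormalised at the series edges, so
   constants are preserved exactly and the operation is deterministic;
   less than 1e-4 of kernel mass is lost to truncation.
4. **Kinematics** — positions are averaged within each bin and differenced:
   velocity at bin *i* is the first difference of bin-averaged position
   over the bin width, with a forward difference at the first bin of each
   trial. Bin assignment uses the uniform grid index with a 1e-9 rounding
   guard; interval-search assignment put edge samples into two bins and
   biased the differentiated velocity by several percent.

The order is bin → sqrt → smooth, and tuning models are fitted on the
smoothed rates of the **training trials only**. The train/test split is
chronological: the first `floor(0.75 n)` trials train every model, the
remainder only ever evaluates. `floor` reproduces the worked splits
131/44 (175 trials) and 372/124 (496 trials).

## Unit selection

Each unit's smoothed rate is regressed on `[vx, vy, speed]` (ordinary least
squares — the linearised cosine tuning model). Units with r² > 0.01 are
kept. The threshold is deliberately permissive: it removes units whose
activity is statistically unrelated to movement while keeping weakly tuned
ones, and selection is monotone in the threshold. With ~10,000 training
bins the null distribution of r² concentrates well below 0.01, so untuned
units are rejected at high specificity (tested: ≥ 80% rejected, ≥ 90% of
tuned units kept, on 500 s of simulated data).

## Representations

**PCA** — eigendecomposition of the training covariance of the smoothed
rates, computed bin-by-bin (single-trial basis) rather than on trial
averages, so the components capture within-trial covariation. Scores are
re-smoothed before decoding, since truncation reintroduces high-frequency
variance from discarded components.

**Factor analysis** — EM for `z = μ + Λf + ε` with diagonal uniquenesses
(floor 1e-6) and PCA-based initialisation. Scores are posterior means. The
log-likelihood is asserted non-decreasing per iteration in the tests.

**Linear dynamical system** — EM (Kalman filter + RTS smoother E-step) for
`x_t = A x_{t-1} + w`, `z_t = C x_t + v` with diagonal observation noise.
For decoding, states are extracted by **causal filtering only**: the
representation feeds an online-style decoder, and a smoother would leak
future spikes into past states. The tests assert that truncating the future
leaves past states unchanged.

**Dimensionality selection** — for each candidate `q`, the held-out error
is **leave-one-neuron-out** reconstruction: each unit is predicted from all
the others through the `q`-dimensional model. Plain projection error is
monotone in `q` (zero at `q = m` for PCA), so its argmin is degenerate;
the leave-one-out variant has a genuine minimum at the underlying
dimensionality and is the standard device for this purpose in neural
population analysis. Plain projection error remains available via
`error = "projection"`. Candidate grids default to steps of 5 (PCA up to
`m`; FA/LDS up to `min(m, 40)`).

**Linear CCA** — both views are centred and whitened with
`(Σ + ridge I)^{-1/2}` (default ridge 1e-8, raised only for numerically
singular views); the SVD of the whitened cross-covariance yields the
canonical coefficients and correlations. Three pairs are produced — the
kinematic dimensionality caps the pair count. Signs are fixed so training
correlations are non-negative. The implementation is checked against an
independent generalized-eigenvalue oracle to 1e-8 on 100 random instances.

**Deep CCA** — per-view feedforward networks (logistic sigmoid hidden
layers, linear output of width 3) trained by minibatch Adam on the total
canonical correlation of the output batches: the sum of singular values of
the whitened cross-covariance, with per-view ridges `rcov_z`, `rcov_x`
stabilising the whitening. Two auxiliary terms shape the objective: an
autoencoder reconstruction penalty weighted by the trade-off `λ` (mirror
decoders are trained jointly), and L2 weight decay. Encoder layers are
initialised by layer-wise denoising-autoencoder pretraining with masking
noise. After training, a linear CCA on the network outputs provides the
canonical rotation; this final rotation uses a minimal stabilising ridge
(1e-8, escalated only on failure) rather than `rcov`, so the stored
training correlations equal the empirical correlations of the projected
series. With identity activations and `λ = 0` the procedure reproduces the
linear CCA optimum to 1e-3, and the analytic gradient of the correlation
objective matches finite differences to ~1e-9 — both are standing tests.

Hyperparameters follow the published search space (nodes 2⁴–2¹⁰, layers
1–4, batches 2⁵–2⁸, learning rate 1e-5–1e-2, rcov/L2/λ 1e-6–1e-1). The
package replaces full-scale Bayesian optimisation with a budgeted random
search over that grid (default budget 50, inner 80/20 chronological
validation split, deterministic given the seed): at desk scale the
network sizes that matter are far below the upper end of the grid, and
random search over a bounded box is a well-behaved stand-in at this
budget. `fit_dcca(n_restarts = )` additionally supports best-of-k
initialisation selected by the final training objective, which removes
most seed-to-seed training variance.

## Decoders

**Steady-state linear Kalman filter.** State `[vx, vy, speed]`; `A` and `H`
by least squares (state-transition pairs never straddle trial boundaries),
`Q`, `V` as residual covariances, no intercepts (the state is near
zero-mean by construction). The gain is iterated to its Riccati fixed point
(sup-norm tolerance 1e-10, cap 1e4 iterations), after which filtering is a
fixed-gain recursion and each trial can start from the zero state — the
filter never needs a covariance burn-in mid-session. Decoded speed is
dropped; evaluation uses velocity only. The steady-state filter is asserted
to agree with the full time-varying filter to 1e-6 after gain convergence,
and to recover a planted `(A, H, Q, V)` within 5% at n = 50,000.

**Neural dynamical filter.** For LDS states the Kalman filter would stack a
second dynamical model on top of a representation that already has one, so
a ridge regression (with intercept) from latent states to kinematics is
used instead.

**LSTM.** Single layer, standard gate equations (forget/input/output gates
sigmoid, candidate cell tanh), linear readout to `[vx, vy]`. Speed is not a
training target — velocity is the decoding objective, and the readout can
synthesise speed information internally if useful. Each trial is one
sequence with hidden and cell state starting at zero; this mirrors the
Kalman filter's per-trial reset and keeps both decoders comparable.
Training is Adam with decay factors 0.95 / 0.99, squared-error loss,
trial order reshuffled every epoch, forget-gate biases initialised to 1,
and early stopping on a 10%-of-trials inner-validation plateau (patience
10, default cap 100 epochs). The gate arithmetic and the full BPTT
gradient are tested against scalar brute-force evaluation and finite
differences.

**CCA-only inversion.** As a deliberately minimal baseline, velocity can be
reconstructed without any decoder: each kinematic canonical variable is
predicted from its paired neural canonical variable by per-pair linear
regression, and the kinematic canonical map is inverted (matrix inversion
for the linear model; logit + pseudo-inverse layer-by-layer for the deep
model, with activations clipped into (ε, 1−ε), ε = 1e-6). This route
discards the cross-pair structure a decoder can exploit and is expected to
trail the Kalman filter; it exists to quantify that gap.

## The synthetic sessions

The simulator generates what the estimators assume, plus controlled
violations:

* **Kinematics** — minimum-jerk point-to-point reaches (analytic peak speed
  `1.875 d/T`, zero velocity at segment ends), either center-out to 8
  targets at 45° spacing (8 cm radius, 0.6 s legs) or sequential reaches to
  uniform random targets in a square workspace. Minimum jerk was chosen
  because it is the standard smooth reach model and its closed forms anchor
  the kinematics tests.
* **Spiking** — per-unit rates `max(0, b + d(vx cos φ + vy sin φ) + g|v|)`;
  baselines 2–12 Hz, depths 0.4–1.2 Hz/(cm/s), speed gains 0.05–0.4 — a
  population in which movement modulation is comparable to baseline
  variability, as in typical M1 samples. A configurable fraction of units
  ("nonlinear", default 0.3) additionally saturates through a tanh ceiling
  (default 25 Hz). Spikes come from an inhomogeneous Poisson process via
  thinning at the per-unit peak rate. One seed governs targets, tuning and
  spikes and is recorded in the session metadata.
* **The nonlinear benchmark** (`nonlinear_benchmark_config()`) — 30 units,
  200 trials, every tuned unit saturating hard (ceiling 10 Hz against
  drives of tens of Hz, depths 1.5–2.5). This is the regime the deep
  method is designed for: the population code is deeply nonlinear in
  velocity, a linear canonical map cannot unwarp it, and the
  representation ordering deep ≤ linear ≤ raw emerges under the Kalman
  decoder (checked over 10 seeds, ≥ 8/10 per inequality).

What the simulator does **not** emulate: shared (correlated) noise across
units beyond what the latent structure induces, non-Poisson spiking
statistics, nonstationarity across a session, and sensory or preparatory
signals unrelated to the ongoing movement. Consequently, passing tests
demonstrate correctness of the estimators and the qualitative mechanism of
the deep method's advantage — not that the same margins would appear on any
particular recorded dataset. On weakly nonlinear synthetic populations the
Kalman decoder performs near-identically across raw rates and canonical
variables; this is expected (there is nothing to unwarp, and raw rates
carry strictly more information) and is documented behaviour, not a defect.

## Numerical choices and degenerate inputs

* Whitening and inverse square roots go through symmetric
  eigendecompositions; non-positive eigenvalues raise an error that names
  the ridge to increase.
* FA uniquenesses are floored at 1e-6; LDS covariances are symmetrised and
  jittered by 1e-9 each M-step; an estimated state transition with spectral
  radius > 1.05 triggers a warning.
* Zero-variance regressands get r² = 0 (flagged), not NaN. Constant test
  batches transform to finite canonical variables. Axis-aligned reaches
  make one velocity axis identically zero within a trial; per-trial
  correlations are NA there and excluded from summaries.
* Ties in dimensionality selection resolve to the smaller `q` (first
  argmin).
* All stochastic steps — simulation, DAE masking, minibatch order, weight
  initialisation, restarts — derive from one master seed through a
  string-labelled 31-bit hash, so every stage is independently reproducible
  and re-running a configuration is bit-identical.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
scale, chosen so the full suite exercises every code path in minutes on one
CPU: sessions of 12–40 units and 16–120 trials for unit tests; the
nonlinear benchmark at 30 units × 200 trials × 10 seeds; deep-CCA
benchmarks at n = 20,000 bins with 32-node, 2-layer networks; Kalman
recovery at n = 50,000. These sizes are stated here as the package's own
test conditions; all of them scale up by changing the config.

## Known limitations

* The deep CCA trains by first-order ascent on a non-concave objective;
  restarts mitigate but do not eliminate sensitivity to initialisation at
  small hidden widths.
* The Kalman observation model is linear; for strongly saturating
  populations its `V` absorbs the model mismatch, which is precisely the
  gap the deep canonical variables close.
* The LSTM at the default desk-scale settings (small hidden size, few
  epochs) often trails the Kalman filter on short synthetic sessions; it
  needs more data and training than the linear decoders before its
  capacity pays off.
* The CCA-only inversion is ill-conditioned whenever a canonical
  correlation is small; it is a diagnostic baseline, not a decoder.
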