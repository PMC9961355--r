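---
title: "Risk-scale glucose forecasting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-scale glucose forecasting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyrisk)
```

This vignette explains the models implemented in `glyrisk`, the
assumptions behind them, the parameters a user may want to move, and the
design decisions taken where the problem statement was genuinely open.
It states no empirical result that the test suite does not itself
compute.

## 1. The forecasting problem

A CGM sensor reports interstitial glucose in mg/dL at a nominal 5-minute
cadence, clipped to the reporting range [39, 400]. Given one
individual's history, the task is to predict the reading 15, 30 or 60
minutes ahead. The reference point for any learned forecaster is the
*last-measurement* (LM) forecast — carry the most recent reading forward
unchanged. Glucose is strongly autocorrelated at these horizons, so LM
is a hard baseline, and all evaluation here is reported both absolutely
and as the ratio of model RMSE to LM RMSE on identical (input, target)
pairs.

## 2. The risk scale

Learning happens on Kovatchev's symmetrized risk variable rather than on
concentration:

$$y = \gamma\left((\ln x)^{\alpha} - \beta\right),
\qquad \alpha = 1.084,\ \beta = 5.381,\ \gamma = 1.509 .$$

`(ln x)^α` is the standard reading of the notation ("ln^α(x)"); the
transform is strictly increasing and exactly invertible,
`x = exp((y/γ + β)^{1/α})`. Its zero sits at
`exp(β^{1/α}) ≈ 112.5` mg/dL; the risk score `BG(y) = 10 y²` grows
symmetrically toward hypo- and hyperglycemia, undoing the asymmetry of
the mg/dL axis where the dangerous hypoglycemic range is numerically
narrow.

Two numerical notes:

* With the printed constants, `y` over glucose [39, 400] spans roughly
  [−1.95, 2.39] — not [−10, 10]. The package implements the printed
  formula and exposes the realized bounds via `risk_bounds()`; the
  standardized variable `ξ = y/10` therefore spans about
  [−0.195, 0.239]. That is well inside the active region of `tanh`,
  which is what standardization is for, but it does not fill (−1, 1).
* The roundtrip `glucose → y → glucose` is exact to better than 1e-9
  relative over the whole sensor range (asserted in the acceptance
  suite).

## 3. Cleaning and gap imputation

Raw exports are first aligned to a regular grid (nearest-slot snapping,
first reading wins on collision). Cleaning marks invalid every entry
that is missing, non-finite, non-positive (error codes), or outside
[39, 400]; both kinds of holes are then treated identically, because
windowing needs a fully regular grid and the cleaning rule alone does
not say how removal-created holes are refilled. Ends are trimmed until
the series starts and ends with a valid reading, so every interior gap
has two anchors.

Each maximal gap of length $n$ between anchors $a$ (left) and $b$
(right) is filled by the **floor-mean recursion**: positions are filled
right-to-left, the value at in-run position $k$ being
$\lfloor (v_{k+1} + a)/2 \rfloor$ with $v_{n+1} = b$. For $n = 1$ this
is the floored midpoint; for longer runs it decays geometrically toward
the left anchor rather than following the straight line. This is the
formula as printed in the methodology the package follows, even though
that text calls it "linear interpolation"; because the discrepancy is
real, the package also ships `"linear_floor"`
(`⌊a + k(b−a)/(n+1)⌋`) behind the same interface, selectable with
`impute_gap(..., mode=)` or the CLI's `--impute-mode`. Both modes keep
every imputed value inside the closed interval spanned by the anchors
(for integer anchors — CGM devices report integers), so imputation can
never create an out-of-range reading, and both leave the glucose
distribution essentially unchanged at realistic gap rates: the
acceptance suite checks a Kolmogorov–Smirnov distance below 0.05 between
the valid-only and post-imputation distributions at 5 % artifact rates.

The recursive mode is additionally pinned, value-for-value, against an
independently written top-down recursion on 1,000 random gaps.

## 4. Windows and architectures

Two window layouts feed two model families, each targeting exactly one
horizon `h` (in grid steps) past the most recent input:

* **Recurrent family** (RNN, GRU, LSTM): 10 input points spaced `h`
  apart — base `t` reads `t, t+h, …, t+9h`, target `t+10h`. A series of
  length `L` yields `max(0, L − 10h)` windows at stride 1.
* **Lattice family** (CNN): 16 consecutive points `t … t+15` arranged
  row-major into a 4×4 one-channel image, target `t+15+h`; `L − 15 − h`
  windows. Row-major temporal fill is a convention (the layout was
  unspecified); column-major is available for ablation.

The *target placement* — one horizon after the last input — is the only
reading consistent with calling `h` a prediction horizon, but it was not
stated explicitly in the source protocol; it is our contract.

Architectures:

| name | engine | scale | readout | loss |
|------|--------|-------|---------|------|
| RNN0 | vanilla RNN | glucose | identity | MSE |
| RNN / GRU / LSTM | 1 recurrent layer | ξ | tanh | MAE |
| CNN / CNN10 | 3 conv 2×2 (4/8/16 ch) + dense | ξ | tanh | MAE |

"A single unit" is read as a single recurrent *layer*; the hidden width
was unstated and is a knob (default 16; width 1 is constructible but
would make GRU/LSTM gating nearly vacuous). The CNN follows the
published layer table exactly — spatial sizes 4×4 → 3×3 → 2×2 → 1×1, no
padding, stride 1 — giving 701 parameters, a count asserted in the
tests. MAE is used on the ξ scale because errors there are below 1 in
magnitude, where MAE's constant unit gradient trains faster than MSE's
vanishing one; on the glucose scale (errors of tens of mg/dL) the
proportional MSE gradient is the right choice.

### Training

Adam (lr 1e-3, batch 64, shuffled each epoch) for exactly 50 epochs;
optimizer, rate and batch size were unstated in the protocol and are
declared defaults, all exposed in `model_spec()`. Replicas of one
(architecture, horizon) cell differ only in the seed, which drives both
weight initialization and shuffling; a run is bit-reproducible from its
seed, and training uses a private RNG stream so it never perturbs the
caller's.

One training detail is ours: **the readout bias starts at the mean
training target** (through `atanh` for a tanh readout). This is the
standard regression-head initialization; it is essential for the
glucose-scale model, where the target mean (~120 mg/dL) is two orders of
magnitude farther than Adam can move a parameter in 50 epochs at lr
1e-3, and harmless on the ξ scale (mean near 0). It is switchable off
(`train_model(init_output_bias = FALSE)`).

The engines are hand-written vectorized R. Every backward pass is
checked against central finite differences over every parameter (max
relative error < 1e-4) — the test suite's equivalent of trusting an
autodiff library.

### Training-set selection

The experiment protocol trains on 1 individual (10 for CNN10) and tests
on all others: the individual with the largest coefficient of variation
(sd/mean of valid glucose) is always selected, plus `k − 1` sampled
uniformly from the rest under the experiment seed. High-CV individuals
exercise the widest glucose range, which is the stated rationale for the
argmax rule.

## 5. Evaluation

Three metrics per (individual, model, horizon):

* **ξ RMSE** on the standardized scale;
* **CGM RMSE** after inverting the transform back to mg/dL;
* **risk-weighted CGM RMSE** `sqrt(Σ wᵢeᵢ²/Σ wᵢ)` with
  `wᵢ = normalized_bg_risk(y(truthᵢ)) = yᵢ²/10`.

Weighting uses the *truth* point's risk — the weight reflects the
clinical danger of the state being mis-forecast — with
prediction-weighting available behind a flag; and the normalization by
`Σ w` (rather than `n`) is chosen so the metric reduces exactly to the
plain RMSE under constant weights. Both choices were unstated in the
source and are declared conventions, asserted as identities in the
tests.

Scale conversion for evaluation clips predictions into the
sensor-representable band (glucose [39, 400], i.e. ξ in
[−0.195, 0.239]) first: a tanh readout can emit ξ below −0.812 where the
inverse transform is undefined, and a forecast outside the sensor range
has no distinct clinical meaning. Clipping is applied identically to
models and to the LM baseline (whose inputs are already in-band, so it
is a no-op there).

**Clarke error grid.** The five-zone partition uses the canonical
published inequalities (the A-within-20 % rule, the E quadrants, the C
wedges, the D bands; see `?clarke_zone` for the exact order of
evaluation). The source protocol named the grid without formulas, so the
canonical rules are adopted as a convention and pinned against an
independently hand-coded point classifier over a 200×200 grid of
(0, 600]², which also proves the partition total. Per-zone model/LM
count ratios (`zone_ratio()`) report 0/0 zones as undefined rather than
dropping them.

## 6. The synthetic cohort generator

Real CGM cohorts are access-restricted, so the package ships a seeded
generator whose defaults are a single considered statement of "realistic
CGM-like data", not a tuning surface:

* **Latent process in risk space**: AR(1) mean reversion
  (θ = 0.05/step, innovation sd 0.1 risk units). Simulating in risk
  space means symmetric noise becomes right-skewed glucose through the
  convex inverse transform — one mechanism yields both the correct scale
  and the characteristic skew.
* **Meals**: Poisson arrivals at 3/day; each adds a linear 20-min rise
  to a U(40, 120) mg/dL peak, then exponential decay (τ = 1 h). The
  mean-reversion center is set to `basal − E[meal uplift]` (the uplift
  is analytic), so the long-run mean lands on `basal_glucose`
  (default 120).
* **Artifacts**: a target fraction of slots (default 2 %, up to 30 %) is
  replaced in geometric-length runs (mean 2) by one of four kinds —
  non-positive error codes, below-39, above-400, missing — in equal
  proportions. Runs longer than 1 exercise the recursive branch of the
  imputation rule. Latent glucose is clipped to [39, 400] *before*
  injection, so a zero-artifact simulation is already fully valid.
* **Cohorts** jitter basal (±10 mg/dL sd, clamped to [90, 180]) and
  noise (×U(0.7, 1.5)) per individual under deterministic sub-seeds, so
  coefficients of variation differ and the CV-argmax is almost surely
  unique.

What the generator does **not** emulate: insulin/meal feedback loops,
circadian structure, sensor drift and compression artifacts, or the
inter-individual heterogeneity of real cohorts. A green pipeline test on
synthetic data establishes that the machinery is correct and that
learned models behave sanely relative to persistence — it does not
establish clinical forecasting skill, and the original study's headline
error figures (which require its restricted dataset) are deliberately
not claimed or approximated here.

## 7. Numerical choices and degenerate inputs

* Grid snapping: slot `round((t − t₀)/Δt)`; duplicate slots keep the
  first reading (file order) with a warning.
* A series whose every slot is invalid errors at `trim_ends()`; a
  too-short series yields an *empty* window set with a warning, and
  training on an empty set errors.
* Non-finite training loss aborts with the epoch index (divergence is a
  bug, not a warning).
* `weighted_rmse` treats "all weights below 1e-12" as the all-zero-risk
  degenerate case, since the float transform never returns exactly zero.
* Seeds are kept below 2³¹; derived sub-seeds use modular arithmetic on
  the master seed.

## 8. Known limitations

* Pure-R training is fast enough for the protocol's model sizes (~40 s
  for a 12-individual, 6-architecture dress rehearsal) but does not
  scale to large hidden widths or long input sequences.
* The LSTM at the 15-min horizon is constructible but carries no
  performance claim (it was excluded from the source protocol's
  reporting as significantly worse).
* Only CGM is modeled; insulin, meal and activity channels are out of
  scope, as are model-based imputation, the Parkes grid, MARD and
  time-in-range statistics.
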