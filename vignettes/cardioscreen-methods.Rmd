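---
title: "Methods: models, parameters and design choices in cardioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cardioscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioscreen)
```

## The problem

High-throughput cardiotoxicity screens expose human iPSC-derived
cardiomyocyte monolayers to candidate kinase inhibitors and read out four
functional endpoints per well: calcium-transient peak magnitude, transient
frequency, cell viability and live-cell count.  A feedforward neural
network trained on the normalized endpoints then predicts, over a
constrained design grid, which compounds enhance the Ca²⁺ transient while
sparing viability, cell number and beating rate, and the compounds are
ranked by their mean predicted effect.  A companion engineered-tissue
("biowire") assay characterizes contractility — active tension, beat
duration, contraction slope and relaxation slope — from force traces.

`cardioscreen` implements that analysis end to end, together with a
synthetic-data generator that plants a known compound-effect model, so
every stage can be tested against ground truth without access to
experimental data.

## The synthetic screen

The generator emulates a 384-well campaign: 80 blinded compounds spanning
23 kinase targets, each tested at 0.1, 1 and 10 µM in triplicate
(720 test wells, split across plates automatically), with each plate
carrying six blank (medium) wells and three wells each of a vehicle
control, a positive chronotrope, a negative chronotrope/inotrope and a
lethal viability control.

Planted effects are multiplicative per endpoint.  The calcium-magnitude
effect is a smooth surface: a per-target base effect spanning −0.8 to +2
(covering the observed classes from strong suppression to a roughly
3-fold increase) scaled by a saturating dose response $d(c) = c/(c+1)$ in
µM, plus a small per-compound jitter (SD 0.05).  Frequency, viability and
live-count effects are small and mostly neutral-to-negative (means −3% to
−5% at full dose response), since most kinase inhibitors in such screens
leave those endpoints near control levels.  Well-to-well noise is
lognormal with coefficients of variation of 5% (magnitude, counts) and 2%
(frequency, viability).

Control-level trace parameters are a 100 AU fluorescence baseline, 50 AU
transient amplitude, 1 Hz spontaneous rate and 0.08 s Gaussian peak width,
sampled every 0.1 s for 40 s (401 samples), with additive Gaussian noise
of SD 1 AU; peak bumps are truncated at the half-period so inter-peak
valleys return exactly to baseline.  With zero noise the planted amplitude
and peak count are therefore recoverable *exactly*, which is what the
recovery tests exploit.  Counts start from 8 000 cells per well at 90%
control viability.  All of these are configuration, not constants.

What the generator does **not** emulate: dye-loading kinetics,
photobleaching, plate-reader optics, arrhythmic or irregular beating,
spatial plate effects (edge evaporation, gradients), and correlated
failures across wells.  Passing recovery tests therefore demonstrate that
the analysis inverts the generator's effect model faithfully — not that it
is robust to every artifact of real plate-reader data.

## Trace analysis

**Noise floor.**  Wells in which calcium flux is fully blocked record only
instrument noise; the minimum amplitude accepted as a contraction is
`multiplier × pooled SD` of those traces after removing linear drift, with
multiplier 3 (the three-sigma rule) by default.  The pipeline takes these
reference traces from the lethal-control wells, which are flat by
construction.

**Peak detection.**  Candidate summits are local maxima found on a lightly
smoothed copy of the trace (centred moving average over 5 samples, i.e.
0.5 s at the standard sampling; configurable).  A candidate is accepted
when it rises at least the noise floor above the valley separating it from
the previous accepted peak; candidates not separated by such a valley are
merged, keeping the higher summit.  Each accepted summit is then refined
to the raw-trace maximum in its neighbourhood, and its magnitude is the
raw maximum minus the raw minimum of the valley preceding the peak (the
peak's own baseline).  The smoothing step exists because the range of a
few hundred Gaussian noise samples routinely exceeds three SDs: without
it, pure-noise traces would yield spurious "contractions" under the
three-sigma floor.  Because magnitudes are measured on the raw trace, a
noiseless trace is still recovered exactly.  Frequency is reported as the
peak count over the 40 s window (Hz = count/duration is a division away);
peaks at the window edge count whenever their maximum lies inside the
window.  Wells with no accepted peaks report frequency 0 and an undefined
(NA) magnitude.

**Contractility.**  Paced force traces are segmented into beats by pacing
period.  Per beat: active tension is the maximum minus the beat baseline
(window minimum); beat duration is the time spent above baseline plus 10%
of the active tension, with linearly interpolated threshold crossings (on
an ideal piecewise-linear beat this yields 0.9 × the geometric rise+fall
time — the threshold fraction is configurable because where a beat
"starts" is a convention); contraction and relaxation slopes default to
the maximum instantaneous central-difference derivative on the rise and
fall, which recovers planted slopes exactly on piecewise-linear beats and
is robust to rounded shoulders; an endpoint-secant variant is available.
Force is expressed in µN throughout — a unit convention carried as
metadata, not semantics.

## Screen statistics

Viability is `(total − dead)/total` and live cells `total − dead`.  Every
endpoint is normalized against the blank (medium) wells of its own plate:

$$\text{normalized} = \frac{\text{experimental} - \text{blank mean}}{\text{blank mean}}$$

so control level maps to 0 and a doubling to +1.  The normalization
control defaults to blank wells and can be switched to the vehicle (DMSO)
wells.  Triplicates are averaged per compound × concentration; wells with
no detected peaks are excluded from the magnitude average rather than
imputed.  Each triplicate mean is coded into a signed SD band relative to
the pooled blank distribution on the normalized scale:
`band = sign(z) · min(ceil(|z|), 3)` with
`z = (mean − control mean)/control SD` — the integer codes behind the
screen heat map.  Dose–response calls use one-way ANOVA (via `stats::aov`)
with Fisher LSD t-tests against the control group at α = 0.05, built from
the ANOVA residual mean square.  The original repeated-measures structure
is not reconstructible from a plate layout, so a plain one-way ANOVA is
fitted; no multiplicity correction is applied beyond LSD.  Degenerate
tables (zero variance everywhere) are reported as non-significant with an
undefined F.

## The neural network

One record per compound × concentration carries the inputs — inhibitor
concentration (µM), kinase-target integer code, normalized frequency,
normalized viability, normalized live cells — and the output, normalized
calcium peak magnitude.  The default screen yields 240 records, split
90/10 into training and test sets by a seeded draw.

Networks are multilayer perceptrons with `tansig` (tanh), `logsig` or
linear transfer functions and a linear output.  Inputs and the output are
affinely mapped to [−1, 1] from the training data (constant columns get
half-range 1); the kinase target enters as its integer code, and
concentration enters on a log₁₀ scale.  The log transform matters more
than it may look: doses are tested and predicted on a log-spaced axis, and
with raw µM inputs the three tested doses map to −1, −0.82 and +1 of the
scaled range, so nearly the whole design grid would fall in a data-free
gap where a tanh network is unconstrained — in practice producing
predictions far outside the data range and occasionally inverted
rankings.  On the log scale the tested doses anchor the grid uniformly.
Weights initialize uniformly in [−0.5, 0.5] under a seed.

Training is Levenberg–Marquardt backpropagation, written from scratch on
an analytic per-sample Jacobian: each accepted step solves
$(J^\top J + \lambda I)\,\delta = J^\top r$ and must strictly reduce the
training RMSE; λ starts at 10⁻³, shrinks ×0.1 on acceptance and grows ×10
while a step is rejected (conventional damping constants).  Training stops
at 1 000 epochs, when the error gradient falls below 10⁻⁷, or when λ
exceeds 10¹⁰ without progress.  In the all-linear limit the trained map
coincides with ordinary least squares to 10⁻⁸, which the tests verify
against `stats::lm`, and the Jacobian is verified against central finite
differences.

Fit quality is RMSE plus R², defined as the squared Pearson correlation
between predicted and actual values (the trend-line convention; the
coefficient-of-determination variant is available).  R² is undefined when
either side has zero variance — reported as NA, never silently 0 or 1.

**Architecture search.**  Every candidate (default grid: one or two hidden
layers of 3, 5, 8 or 12 neurons, `tansig` or `logsig` hidden transfer,
linear output) trains on the same split with 3 random restarts, keeping
the restart with the best test R²; candidates rank by test R² descending
with ties broken by lower test RMSE, and diverged fits rank last.  A
caveat learned from the recovery experiments: candidate capacity should be
matched to the data — a network with more parameters than training records
can interpolate the records and still extrapolate wildly over the design
grid, so the recovery experiments restrict candidates to networks with
fewer parameters than training records.  Three per-concentration control
networks (normalized live cells + target → normalized viability) provide
the sanity check that an unrelated endpoint is learnable from the same
screen.

## Design grid and ranking

The prediction grid factorizes as 13 × 11 × 11 = 1 573 rows per compound:
13 log-spaced concentrations over the tested 0.1–10 µM range, 11
normalized-frequency levels confined to [−0.05, +0.05] and 11
normalized-viability levels confined to [0, +0.1], with normalized live
cells tied to normalized viability; the kinase-target code is fixed per
compound.  Over 80 compounds this gives 125 840 prediction points.  The
intervals encode the screening intent — candidates must not change beating
rate or cost viability — and the factorization is the minimal one
consistent with the per-compound row count; every range and level count is
configuration.  Compounds are ranked by the mean predicted normalized peak
magnitude over their grid block: rank 1 (highest mean) is the least
detrimental compound, the lowest mean the most detrimental, with ties
broken by ascending compound id.

## Numerical and degenerate-input conventions

* Zero-variance blanks make normalization impossible: a zero blank mean is
  a hard error, not an NaN.
* `sd_band` requires a positive control SD; screen summaries emit NA bands
  where the pooled blank SD is zero.
* The LM inner loop never solves an undamped system (λ > 0 always) and
  treats a non-finite loss as divergence.
* Splits use `round(fraction × n)` clamped to leave at least one record on
  each side.
* All artifact CSVs serialize numerics to 10 significant digits so reruns
  with the same seed are checksum-identical across platforms.
* One global seed fans out to per-stage seeds by fixed offsets, keeping
  every stage individually reproducible.

## Problem sizes in the test suite

The unit and property tests run on screens of 5–10 compounds and on the
full 80-compound geometry where structure is asserted; the recovery
experiments use the default 240-record screen (with additional N(0, 0.1)
output noise planted on the records) and networks of 3–8 hidden neurons
with 3 restarts.  These sizes were chosen as the smallest at which each
property is meaningfully exercised.  One caution for reusers: with a
24-point held-out set, the test-set composition itself moves the held-out
R² by several points between split seeds — on unlucky splits even the true
planted surface scores below 0.9 — so recovery assertions are made under
fixed documented seeds.

## Known limitations

* The trace model plants stereotyped, regularly spaced transients;
  arrhythmia detection and transient-decay (tau) fitting are out of scope.
* The repeated-measures ANOVA of the original assay design is not
  implemented (the plate layout does not identify the repeated factor);
  Tukey's HSD is likewise out of scope.
* Predictions carry no uncertainty quantification, and the design-grid
  intervals are a documented reconstruction of the screening constraints,
  not measured values.
* Integer target codes impose an artificial ordering on kinase targets;
  the effect generator plants a surface that is smooth in that code, which
  flatters a numeric encoding.  One-hot encoding is the natural extension
  for real screens.
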