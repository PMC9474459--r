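---
title: "Models and methods in paleoGDGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleoGDGT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoGDGT)
```

# The scientific problem

Branched glycerol dialkyl glycerol tetraethers (brGDGTs) are membrane
lipids of soil bacteria. Fifteen structural variants are routinely
separated by modern chromatography: tetra-, penta- and hexamethylated
skeletons (roman numerals I–III), zero to two cyclopentane moieties
(letters a–c), and — for the penta/hexa series — a methyl group at the
5- or the 6-position (the 6-methyl isomers are marked with a prime).
Methylation degree tracks temperature, cyclization tracks soil pH, and
the balance of 6- versus 5-methyl isomers responds to soil moisture and
alkalinity. Because the compounds survive in loess–paleosol sequences
for hundreds of thousands of years, their relative abundances preserve
a terrestrial climate archive.

paleoGDGT implements a complete desk-scale reconstruction pipeline on
this signal:

1. **Compositional preprocessing** — fractional abundances over all 15
   compounds, internal-standard quantification, strict table schemas.
2. **Closed-form indices** — MBT′, MBT′~6ME~, IR~6ME~, CBT′/CBT, the pH
   calibration, four temperature transfer functions, and the leaf-wax
   n-alkane indices CPI and ACL.
3. **Precipitation calibration** — a from-scratch deep feed-forward
   network mapping eight compound fractions to mean annual precipitation
   (MAP, mm/yr), trained by Adam on the mean absolute error, with a
   diagnosed multiple-linear-regression baseline and recurrent
   (RNN/LSTM/GRU) baselines.
4. **Chronology** — susceptibility-weighted age interpolation between
   control points.
5. **Comparison** — Morlet cross-wavelet amplitude/phase analysis
   against reference series, and PCA summaries of factor matrices.
6. **Synthetic data** — truth-known generators that make the whole
   pipeline testable without any external download.

# Index calculus

All ratio indices are computed exactly as printed in their source
calibrations, with the compound sets frozen even where they look
incomplete (e.g. the MBT′ denominator omits the IIIb/IIIc series); no
silent "correction" toward other literature variants is applied. Two
conventions are exposed behind flags rather than changed defaults:
`ir6Me(convention = "pentaHexa")` restricts the denominator to the
penta- and hexamethylated pool, and `cpi(variant = 2)` selects the
second printed CPI form.

Two definitional gaps had to be closed:

* The logarithm base of the cyclization index is not stated; it is
  taken as base 10, consistent with the decadic pH scale and the
  calibration lineage of the pH equation.
* The MAAT transfer function needs a plain CBT index that its source
  does not define; the classical
  `CBT = -log10((Ib + IIb) / (Ia + IIa))` is adopted and exposed as its
  own operation, `cbt()`.

Undefined ratios (zero denominators, empty samples) yield `NA` rather
than errors so that downcore batch runs survive degenerate horizons;
definedness is recoverable as `!is.na()`. MBT′ is only interpreted as a
relative soil-water-content (SWC) indicator where IR~6ME~ > 0.5; the
proxy suite records that gate in its `swcInterpretable` column.

# The precipitation network

The calibration model is a fully connected feed-forward network: the
input layer takes the fractional abundances of the eight default
feature compounds (Ia, Ic and the six 6-methyl isomers — the compounds
most responsive to moisture and pH; a nine-compound variant retaining
Ib is available), four hidden ReLU layers of equal width, and a single
linear output neuron in raw millimetres. The loss is the mean absolute
error; optimization is Adam with the stated constants
(λ = 0.001, ρ₁ = 0.9, ρ₂ = 0.999, ε = 1e-8). The ReLU derivative places
x = 0 on the zero branch, as printed.

Design choices where the source is silent:

* **Weight initialization** is He-style scaled normal, seeded; training
  is therefore bit-reproducible from (data, spec, seed).
* **Minibatching.** The gradient is defined as a minibatch mean, but no
  batch size is stated. The package default is 32 with a seed-derived
  per-epoch shuffle (still fully deterministic). Full-batch training is
  available (`batchSize = NULL`) but converges visibly more slowly on
  raw-mm targets at the stated learning rate — with 1000 full-batch
  epochs the network remains mildly underfit, which is why the
  minibatch default was adopted.
* **Targets are trained in raw mm** (no standardization); features are
  already fractions in [0, 1]. RMSE in mm is then directly comparable
  across models.
* **Epoch** means one full pass; the printed "frequency of training
  1000–1500" is read as the epoch count.
* **Grid search** over epochs {1000..1500 step 100} × neurons
  {160..260 step 20} selects the maximum validation R²; ties break to
  lower validation RMSE, then fewer neurons, then fewer epochs — a
  deterministic rule chosen for reproducibility. Selection is on the
  validation set and both training and validation metrics are reported.
* **R² convention**: the squared Pearson correlation between predictions
  and observations (equal to the regression R² for a linear fit on its
  own training data). This matters for nonlinear models, where other R²
  definitions can go negative.

The multiple-linear-regression baseline implements the full printed
diagnostic suite (multiple correlation R, per-coefficient t from the
inverted centred normal matrix, residual scale s on n−m−1 degrees of
freedom, the F statistic, and VIFs from auxiliary regressions); its
estimates are cross-checked in the tests against pseudo-inverse and
`lm()` oracles.

# Recurrent baselines

The RNN, LSTM and GRU baselines consume the eight feature fractions as
an ordered scalar sequence (registry order; the arrangement is a
package convention, since none is stated). Forward recursions follow
the printed equations, including two faithful quirks:

* the GRU state update keeps the reset gate inside the carry-over term,
  `h_t = (1−z_t)·r_t·h_{t−1} + z_t·h̃_t`; the conventional update is
  available behind `standardGru = TRUE`;
* the printed LSTM system stops at the cell state, so the conventional
  output gate `h_t = o_t · tanh(C_t)` is added (and documented here).

The printed RNN output applies a softmax to the readout, which is
degenerate for a scalar regression target (softmax of a length-1 vector
is identically 1). `baselineCellForward()` reproduces that printed
output, but *training* uses a linear readout on the final hidden state.
Because tanh-bounded hidden states cannot span raw-mm magnitudes at the
shared Adam step size, the recurrent readout is trained against
z-scored targets and un-scaled at prediction time; reported losses and
metrics are in mm. Gradients are full backpropagation through time,
verified against finite differences in the test suite (including the
nonstandard GRU update).

# Age–depth model

Between two chronological control points (depth, age) the accumulated
age is allocated in proportion to cumulative thickness × magnetic
susceptibility of the layers above the sample — susceptibility acting
as a relative accumulation/pedogenesis rate proxy in loess. A "layer"
is one sampling interval, nominally 10 cm, and a sample sits at its
layer base. With constant susceptibility the model reduces exactly to
linear depth–age interpolation, and scaling all susceptibilities leaves
ages unchanged. Zero-susceptibility layers contribute zero weight; an
interval that is entirely zero-weight raises an error unless the
explicit `uniformFallback` (thickness-only) flag is passed. Control
points are always user-supplied; the package hard-codes no chronology.

# Cross-wavelet analysis

The continuous transform uses the Morlet mother wavelet with centre
frequency 6 — the paleoclimate standard, chosen here because the source
names no mother wavelet — on a dyadic scale set spanning periods from
twice the grid step to half the series span, with zero padding and
cone-of-influence masking at the √2·scale e-folding distance. The cross
spectrum of two series on a common (typically 1-ka) grid is
`CS = W1 · Conj(W2)`, decomposed into amplitude and phase. The sign
convention is documented rather than asserted as physics: positive
phase means series 1 leads (a series lagged by `lag` shows phase
`+2π·lag/period`), and |phase| = π is anti-phase. Band statistics are
power-weighted circular means over the scales within a fractional
period tolerance, excluding the cone of influence by default; the
anti-phase verdict fires when the circular distance from π is below an
explicit tolerance (default 0.5 rad). The covarying/independent
decomposition that motivates the cross spectrum is represented
implicitly by the product estimator; the independent components are not
separately identifiable and are not exposed. Significance testing
against red noise is deliberately out of scope.

PCA of environmental factor matrices standardizes to zero mean and unit
variance by default (the factors mix units); normality is not enforced,
though a Shapiro–Wilk screen is provided as a utility.

# Synthetic data: what it emulates and what it does not

`simulateCalibration()` emulates the *structure* of a global
multi-laboratory surface-soil compilation: latent climate (MAT ∈ [−5,
28] °C, MAP ∈ [50, 3000] mm, pH ∈ [4, 9]) drawn uniformly, mean
compositions produced by a normalized-exponential (softmax) map of
linear/saturating climate responses in which 5-methyl compounds load
mainly on temperature and 6-methyl compounds on moisture and pH, and
Dirichlet compositional noise at concentration κ = 200 around the mean
(about 14 % relative scatter on a 0.2 fraction — the scale of
cross-laboratory variability) plus 100 mm of MAP observation noise.
The `"saturating"` link plateaus above ~1500 mm, planted to emulate the
regime where linear transfer functions fail; `"mixed"` (the default)
averages the linear and saturating channels. Under these defaults the
default network attains validation R² ≈ 0.85 at n = 700 — the same
order as real-compilation behaviour — but the generator is a structural
emulation, not a reconstruction of any real dataset: it has no spatial
autocorrelation, no inter-laboratory bias structure, and independent
uniform climate drivers. Passing tests therefore demonstrate correct
*recovery of in-class signal*, not field performance.

`simulateDowncoreProfile()` plants the canonical loess cyclicities: a
100-ka glacial–interglacial sawtooth in temperature (default ±5 °C,
i.e. a ~10 °C range), a 23-ka precessional sinusoid in precipitation
(default ±300 mm), susceptibility covarying with the warm phase
(pedogenic enhancement), and layer thicknesses inversely tracking
susceptibility so that thickness × susceptibility is proportional to
elapsed time — hence the susceptibility-weighted age model recovers the
true chronology exactly from the two end-point controls. The profile
sits in the 6-methyl-dominant regime (IR~6ME~ > 0.5 for ~94 % of
layers), the regime in which MBT′ is read as a SWC indicator.
Leaf-wax homologs are generated with moisture-dependent odd dominance
and temperature-dependent chain length.

# Numerical choices and degenerate inputs

* Abundance rows must sum to 1 within 1e-9; pre-normalized rows within
  1 ± 0.02 are rescaled only under an explicit `renormalize` flag, and
  anything further off is rejected with row numbers.
* Missing compound columns are an error unless `missingAsZero` is set:
  silent zeros bias every index.
* Both prime spellings (IIa′ / IIa') are accepted everywhere; the ASCII
  apostrophe is canonical on output.
* An exactly collinear design in `fitMlr()` raises an error naming the
  offending columns; an interpolating fit reports s = 0 and infinite t
  statistics rather than astronomically large finite ones.
* Non-finite training loss aborts with the epoch number (divergence
  diagnosis) instead of propagating NaNs.
* Depths within float noise of a control point are snapped onto it so
  interval assignment is stable under inexact grid spacing.

# Problem sizes used by the tests

The test suite exercises the full protocol at sizes a laptop handles
comfortably: the recovery and grid-search checks train the default
4 × 160 network on a 700-sample synthetic compilation (525/175 split);
the linear-versus-network comparison uses ten 400-sample
saturating-link datasets with a 4 × 64 network; the overfitting
comparison trains each recurrent cell (hidden width 32, 2000 epochs)
and a 4 × 64 network on ten 60-sample training sets with 100-sample
validation; wavelet checks use 431-point, 1-ka series. These sizes are
the package's reference experimental design; all are reproducible from
fixed seeds.

# Known limitations

* The calibration cannot be more faithful than its training
  compilation; the shipped generator emulates structure, not the real
  712-soil dataset, so absolute skill numbers here do not transfer to
  field data.
* No uncertainty quantification (ensembles, Bayesian calibration) — the
  point estimate mirrors the reference method.
* Wavelet coherence with smoothing operators and Monte-Carlo
  significance contours are out of scope; the cross spectrum reports
  raw amplitude and phase.
* Regional recalibration of the closed-form index coefficients is not
  attempted; coefficients are frozen as printed.

# A compact worked example

```{r example, eval = FALSE}
sim <- simulateCalibration(n = 700, seed = 1)
sp <- splitDataset(sim$dataset, 0.25, seed = 1)
model <- trainDlnn(sp$training, networkSpec(seed = 1),
                   validation = sp$validation)
model

dc <- simulateDowncoreProfile(seed = 1)
prof <- applyAgeModel(dc$profile, dc$controls)
mapc <- predictMap(model, prof)
ref <- simulatePairedSeries(periodKa = 23, phaseOffset = pi, seed = 1)
grid <- resampleToAgeGrid(ages(prof), mapc)
refGrid <- ref$s2[ref$s2$age %in% grid$age, ]
bandPhase(crossWavelet(grid, refGrid), period = 23)
```
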