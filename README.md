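# paleoGDGT

Reconstructing terrestrial paleoclimate from branched glycerol dialkyl
glycerol tetraether (brGDGT) membrane lipids and leaf-wax n-alkanes in
loess–paleosol sequences.

Soil bacteria adjust the structure of their brGDGT membrane lipids to
their environment: the degree of methylation tracks temperature,
cyclization tracks soil pH, and the balance of 6- versus 5-methyl
positional isomers responds to soil moisture. paleoGDGT is for
organic-geochemistry and paleoclimate groups who measure the 15
separated brGDGT compounds (Ia … IIIc′) downcore and want to turn them
into quantitative climate records.

## What it computes

**Index suite** (exactly as printed in their source calibrations):

- MBT′ = (Ia+Ib+Ic) / (Ia+Ib+Ic+IIa+IIa′+IIb+IIb′+IIc+IIc′+IIIa+IIIa′),
  read as a relative soil-water-content indicator where IR₆ME > 0.5
- MBT′₆ME, IR₆ME = Σ(6-methyl) / Σ(all brGDGTs)
- CBT′ = −log₁₀((Ic+IIa′+IIb′+IIc′+IIIa′+IIIb′+IIIc′)/(Ia+Ib+Ic)) and
  pH = 7.15 + 1.59·CBT′
- four temperature transfer functions, e.g.
  MATmr = 7.17 + 17.1·Ia + 25.9·Ib + 34.4·Ic − 28.6·IIa (°C)
- leaf-wax CPI (both printed variants) and ACL over C23–C33

**Precipitation calibration**: a from-scratch deep feed-forward network
(8 compound fractions → four ReLU hidden layers → MAP in mm/yr) trained
by Adam (λ = 0.001, ρ₁ = 0.9, ρ₂ = 0.999, ε = 1e-8) on the mean
absolute error, with epoch × width grid search and single-compound
ablation; a multiple-linear-regression baseline with the full
diagnostic suite (R, t, s, F, VIF); and recurrent RNN/LSTM/GRU
baselines trained by backpropagation through time.

**Chronology**: susceptibility-weighted age interpolation between
control points, Tₘ = T₁ + (Σᵢ≤ₘ aᵢsᵢ)(T₂−T₁)/(Σᵢ≤ₙ aᵢsᵢ).

**Spectral comparison**: Morlet continuous and cross wavelet transforms
with cone-of-influence masking; band-averaged phase with an anti-phase
verdict; PCA summaries of factor matrices.

**Synthetic data**: truth-known generators for calibration
compilations, 430-ka downcore profiles with planted 100-ka and 23-ka
cyclicity, and phase-lagged series pairs.

## Worked example

```r
library(paleoGDGT)

## calibrate on a synthetic 700-soil compilation (75/25 split)
sim   <- simulateCalibration(n = 700, seed = 1)
sp    <- splitDataset(sim$dataset, 0.25, seed = 1)
model <- trainDlnn(sp$training, networkSpec(seed = 1),
                   validation = sp$validation)
model
#> MapModel: 8 features -> 4 x 160 ReLU -> 1 (mm/yr)
#> trained 1000 epochs (Adam, MAE loss), seed 1
#> training:   R2 = 0.907, RMSE = 271 mm, n = 525
#> validation: R2 = 0.848, RMSE = 344 mm, n = 175

## date a downcore profile and reconstruct precipitation
dc   <- simulateDowncoreProfile(seed = 1)
prof <- applyAgeModel(dc$profile, dc$controls)
mapc <- predictMap(model, prof)

## proxy suite per horizon
head(computeProxySuite(prof)[, c("MBTp", "IR6ME", "pH", "MATmr", "ACL")], 3)
#>        MBTp IR6ME    pH  MATmr    ACL
#> d0001 0.315 0.617 6.644 12.428 29.307
#> d0002 0.390 0.557 6.852 13.517 29.195
#> d0003 0.457 0.534 6.955 14.913 29.213

## cross-wavelet phase against an anti-phased 23-ka reference
ref     <- simulatePairedSeries(periodKa = 23, phaseOffset = pi, seed = 1)
grid    <- resampleToAgeGrid(ages(prof), mapc)
refGrid <- ref$s2[ref$s2$age %in% grid$age, ]
bandPhase(crossWavelet(grid, refGrid), period = 23)[c("meanPhase", "antiPhase")]
#> $meanPhase
#> [1] 3.08      # radians; pi = anti-phase
#> $antiPhase
#> [1] TRUE
```

The validation block reads: on held-out synthetic soils the network
explains ~85 % of precipitation variance with a 344-mm RMSE; downcore,
the reconstruction locks onto the planted 23-ka precipitation cycle and
is flagged anti-phased (mean phase 3.08 rad ≈ π) against a reference
series constructed in anti-phase — the behaviour expected when a
precessional rainfall signal is compared with a monsoon-intensity
record.

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "paleogdgt", package = "paleoGDGT")` with
subcommands `simulate`, `proxies`, `agemodel`, `calibrate`, `predict`,
`gridsearch`, `ablate`, `mlr`, `baselines`, `xwt`, `pca`. Every output
table records the resolved options and seed in `#`-comment header
lines. Table schemas are documented in
`inst/extdata/table-schemas.md`.

```sh
paleogdgt simulate --type calibration --n 700 --seed 1 --out soils
paleogdgt calibrate --input soils-calibration.csv --seed 1 \
          --model map-model.json --metrics map-metrics.csv
paleogdgt predict --model map-model.json --input profile-aged.csv \
          --out mapc.csv
```

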