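# paleoGDGT table schemas

All files are delimited text (comma or tab; auto-detected) with a header
row. Lines starting with `#` are treated as comments. Compound columns
accept both the typographic prime (IIa′) and the ASCII apostrophe (IIa').

## Calibration table (readCalibrationTable / writeCalibrationTable)
- 15 compound columns: Ia, Ib, Ic, IIa, IIa', IIb, IIb', IIc, IIc',
  IIIa, IIIa', IIIb, IIIb', IIIc, IIIc' — fractional abundances in [0, 1],
  each row summing to 1 (rows within 1 ± 0.02 are accepted with
  `renormalize = TRUE`).
- MAP (required): observed mean annual precipitation, mm/yr, >= 0.
- Optional: site, MAT (°C), pH, MAPalt (gridded-climate cross-check, mm/yr),
  source (provenance label).

## Profile table (readProfileTable / writeProfileTable)
- depth (required): metres below profile top, strictly increasing.
- 15 compound columns: fractional abundances (or raw peak areas with
  `areas = TRUE`).
- Optional: susceptibility (SI instrument units), grainSize,
  age (ka BP), C23 ... C34 (n-alkane homolog concentrations).

## Control points (readControlPoints)
- depth (m), age (ka BP); ages strictly increasing with depth.

## Reference series (readSeriesTable)
- Two columns: age (ka) and value (e.g. speleothem δ18O); any further
  columns are ignored.

## Peak-area records (computeFractionalAbundances / quantifyCompound)
- Named compound areas in arbitrary units; optional internal-standard
  area and amount (default 0.01157 µg of C46 GTGT).
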