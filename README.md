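# enzybind

Characterisation of small-molecule enzyme inhibitors — built around the
assays used to study anthocyanins acting on pancreatic lipase, the
digestive enzyme whose inhibition reduces dietary fat absorption. The
package turns the four standard readouts of such a study into fitted
constants, mechanistic verdicts and a machine-readable report:

| Stage | Input | Model | Output |
|---|---|---|---|
| Inhibition | endpoint plate absorbances (A, a, B, b wells) | rate = [1 − (b−B)/(a−A)]·100; probit regression on log₁₀ dose | % inhibition, IC50 ± CI |
| Kinetics | velocities over substrate/enzyme grids | Lineweaver–Burk 1/V = Km/([S]·Ki·Vmax)·[I] + (1/Vmax)(1+Km/[S]), plus a nonlinear Michaelis–Menten cross-fit | Km, Vmax, Ki, competitive/noncompetitive/uncompetitive/mixed, reversible/irreversible |
| Quenching | fluorescence titration spectra (300–400 nm) | Stern–Volmer F₀/F = 1 + Ksv[Q], Kq = Ksv/τ₀; double-log lg[(F₀−F)/F] = lg Ka + n·lg[Q] | Ksv, Kq, Ka, n, static/dynamic mechanism, peak red shift |
| Thermodynamics | Ka at two temperatures | ΔG = −RT ln K; van't Hoff ΔH; ΔS = (ΔH−ΔG)/T | ΔG, ΔH, ΔS, dominant forces (H-bond/van der Waals, hydrophobic, electrostatic) |

Because raw data behind published tables of this kind are rarely
deposited, the package ships a first-class synthetic-data module
(`assay_design()`, `ground_truth()`, `generate_*()`) that emulates the
study's designs — triplicate wells with blanks, doses 0–4 mg/mL,
quencher:enzyme ratios 0–20:1 at 5×10⁻⁶ mol/L enzyme, 293/303 K — with
a stated multiplicative noise model, so every estimator is testable as
a generator→fit round trip against known truth.

## Worked example

```r
library(enzybind)

design <- assay_design(noise_sd = 0.02, seed = 7)   # 2% measurement noise
paths  <- write_synthetic_fixtures("demo", design, ground_truth())
report <- run_pipeline(run_config(
  plate = paths$plate, kinetics = paths$kinetics,
  type_plot = paths$type_plot, quench_manifest = paths$quench_manifest))
print(report)
```

```
== Lipase inhibitor characterisation report ==

IC50 (probit regression):
    sample ic50_mg_ml ci95_low_mg_ml ci95_high_mg_ml probit_slope     r2
1 sample_1      1.787          1.723           1.853        2.007 0.9976
  extrapolated
1        FALSE

Kinetics: Vmax 5.481 /min  Km 0.2652 mg/mL  Ki 0.8807 mg/mL  [competitive, reversible]

Quenching (mechanism: static ):
  T_K Ksv_L_per_mol Kq_L_per_mol_s Ka_L_per_mol n_sites peak_shift_nm  r2_sv
1 293         59808      5.981e+12        71449   1.019             3 0.9999
2 303         43703      4.370e+12        49528   1.014             2 0.9996
  r2_loglog
1    0.9992
2    0.9953

Thermodynamics:
  sample: dH -27.05 kJ/mol, forces indeterminate
  T_K dG_kJ_mol dS_J_mol_K
1 293  -27.2266   0.610002
2 303  -27.2327   0.610002

Flags: none
```

Reading it: the fitted IC50 (1.79 mg/mL) recovers the generator's true
1.80 within its CI. The apparent Km rises with dose while Vmax stays
put, so the inhibition is called competitive, and the
velocity-vs-enzyme lines pass through the origin with falling slopes —
reversible. Ki ≈ 0.88 mg/mL matches the truth. Ksv falls from 293 K to
303 K while Kq ≈ 6×10¹² L mol⁻¹ s⁻¹ sits far above the
2×10¹⁰ diffusion ceiling of dynamic quenching, so the mechanism is
static (ground-state complex), with a slight red shift of the emission
peak. The thermodynamic force call is `indeterminate` here because this
fixture's binding constants give ΔS ≈ 0 — inside the ±5 J mol⁻¹ K⁻¹
near-zero band, which refuses to guess rather than pick a force class;
an exothermic fixture with distinctly negative ΔS labels `hbond_vdw`.

`write_report(report, "report.json")` serialises the same content (with
units in every column name) against the JSON schema in
`inst/extdata/report-schema.json`; `validate_report()` checks it.

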