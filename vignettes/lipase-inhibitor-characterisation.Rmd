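---
title: "Characterising enzyme inhibitors: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising enzyme inhibitors: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzybind)
```

# The analysis problem

`enzybind` characterises a small-molecule inhibitor of pancreatic lipase
from four standard wet-lab experiments:

1. an **endpoint microplate assay** (chromogenic p-nitrophenol read at
   405 nm) giving percent inhibition per dose, from which IC50 is
   estimated;
2. **initial-velocity series** over substrate and enzyme grids, from
   which the inhibition type (competitive/noncompetitive/uncompetitive/
   mixed), its reversibility, and the constants Km, Vmax, Ki are
   estimated;
3. a **fluorescence titration** of the enzyme's intrinsic (tryptophan)
   emission, from which the quenching constants Ksv, Kq, the binding
   constant Ka and the number of binding sites n are estimated and the
   quenching mechanism classified;
4. **binding thermodynamics** at two temperatures, from which ΔG, ΔH
   and ΔS are derived and the dominant intermolecular forces read off
   their signs.

All four stages are exercised end to end on synthetic data with known
ground truth, because raw instrument data for such studies are rarely
deposited; every fitted quantity in this package is therefore testable
as a generator→fit round trip.

# Models and estimators

## Inhibition rate and IC50

Each (dose, replicate) group carries four wells: control blank `A`,
uninhibited reaction `a`, sample blank `B` (inhibitor, no enzyme) and
sample `b`. The blank-corrected inhibition rate is

$$\mathrm{inhibition}\ (\%) = \left[1 - \frac{b - B}{a - A}\right] \times 100 .$$

Raw replicate rates can leave [0, 100]% under noise; they are clamped
to the physical range *before* averaging (the estimator works on means),
and the per-dose means are clamped to [0.5, 99.5]% before the probit
transform, which is undefined at exactly 0 or 1. Both margins are
configurable; 0.5% is the conventional probit-analysis margin.

IC50 comes from unweighted linear least squares of
$\Phi^{-1}(p)$ on $\log_{10}(\mathrm{conc})$ — probit regression on log
dose. The IC50 is where the fitted probit crosses zero,
$\mathrm{IC50} = 10^{-\beta_0/\beta_1}$, with a delta-method 95% CI on
the log scale. The delta method was chosen over Fieller's theorem for
simplicity; for steep, well-determined curves the two are close, and
the choice is a documented limitation for shallow curves. The zero-dose
anchor is kept in the dose–response table for QC but excluded from the
fit (log of zero). A weighted probit variant was considered and left
out: with triplicate wells and near-constant relative noise the weights
are nearly flat, and the unweighted fit matches the way such assays are
conventionally analysed. Two usable doses are accepted with a warning
(the line is then an interpolation, exact when the doses bracket 50%
symmetrically); fewer than two is an error.

## Inhibition type, reversibility, Ki

Velocity versus **enzyme concentration** at fixed substrate gives one
line per dose. Lines through the origin whose slopes fall with dose are
the signature of a reversible inhibitor (reducing effective catalytic
rate); parallel lines displaced downward indicate irreversible
inactivation of a fixed amount of enzyme. `classify_reversibility()`
requires, for "reversible", every intercept within 5% (relative to the
largest fitted velocity) of zero and an overall slope decline beyond
the same tolerance; any slope increase beyond tolerance yields an
explicit `"indeterminate"` rather than a guess.

Velocity versus **substrate** per dose is analysed in double-reciprocal
(Lineweaver–Burk) space:

$$\frac{1}{V} = \frac{K_m}{[S]\,K_i\,V_{max}}[I] + \frac{1}{V_{max}}\left(1 + \frac{K_m}{[S]}\right).$$

Per dose, `1/V` is regressed on `1/[S]` unweighted — deliberately, for
parity with how such plots are conventionally drawn, although the
reciprocal transform amplifies noise at low velocity. The shared Vmax is
the inverse of the mean 1/V-intercept; each dose's apparent Km is that
dose's slope/intercept ratio (equal to slope×Vmax when the intercepts
coincide, as competitive inhibition predicts, but still meaningful when
they do not). Ki comes from the linear relation
$K_m^{app} = K_m (1 + [I]/K_i)$ across doses. The verdict applies the
classical patterns with a 5% relative tolerance on "unchanged": Km up
with Vmax constant is competitive; Vmax down with Km constant is
noncompetitive; both down with parallel reciprocal lines is
uncompetitive; anything else is mixed — never silently competitive. The
5% default absorbs reciprocal-fit noise at the triplicate design without
masking genuinely mixed inhibition, and is configurable.

A direct nonlinear Michaelis–Menten fit (`michaelis_menten_fit()`,
Levenberg–Marquardt, self-starting from the observed velocity range) is
the recommended estimator and is reported alongside; on noiseless data
the two agree to machine precision, which the tests assert.

## Fluorescence quenching and binding

Each titration spectrum (300–400 nm) is reduced to its peak maximum F
and peak wavelength; argmax ties break toward the longer wavelength so
a red shift is never under-reported. The peak maximum, not the
integrated area, is used because the red-shift claim concerns the
emission maximum. The Stern–Volmer relation

$$F_0/F = 1 + K_{sv}[Q], \qquad K_q = K_{sv}/\tau_0$$

is fitted with the intercept *constrained to 1* (the relation has no
free intercept); a free-intercept regression is attached purely as a QC
diagnostic. $\tau_0$ defaults to $10^{-8}$ s, the canonical biopolymer
fluorescence lifetime. The identity $K_q \tau_0 = K_{sv}$ holds exactly
by construction.

The double-logarithmic binding model

$$\lg\frac{F_0 - F}{F} = \lg K_a + n \lg [Q]$$

uses base-10 logs throughout (a natural-log slip would shift Ka by
factors of e). Points with F ≥ F0 carry no binding signal and are
excluded with a warning.

Mechanism classification is deterministic and total: **static** iff
Kq exceeds the diffusion-controlled ceiling of dynamic quenching
(2.0×10¹⁰ L mol⁻¹ s⁻¹) at every temperature *and* Ksv strictly
decreases with temperature; **dynamic** iff Kq is at or below the
ceiling and Ksv increases; every conflicting pattern is
`"indeterminate"`.

## Thermodynamics and forces

With Ka at two temperatures, $\Delta G = -RT\ln K$,
$\Delta H = R\,\ln(K_{a2}/K_{a1})/(1/T_1 - 1/T_2)$ (constant-ΔH
assumption) and $\Delta S = (\Delta H - \Delta G)/T$. Energies are
computed in J internally and converted to kJ only at the reporting
boundary; ΔS is reported in J mol⁻¹ K⁻¹ — the unit mixture these tables
are conventionally printed in, with the single conversion point
preventing the classic 1000× error. R is fixed at 8.314 J mol⁻¹ K⁻¹.
More than two temperatures are accepted but fitted pairwise with a
warning; a global van't Hoff regression is out of scope.

The force rubric (Ross–Subramanian): ΔH < 0 and ΔS < 0 → hydrogen
bonds + van der Waals; both positive → hydrophobic; ΔH ≈ 0 with
ΔS > 0 → electrostatic. The "≈ 0" branch has explicit default
half-widths of 1 kJ/mol (ΔH) and 5 J mol⁻¹ K⁻¹ (ΔS); sign patterns
outside the rubric are `"indeterminate"`.

Because published binding-constant and thermodynamics tables sometimes
disagree — e.g. sample labels transposed between them —
`check_binding_consistency()` recomputes −RT ln Ka for every row of a
binding table carrying printed ΔG values and flags mismatches beyond
0.5 kJ/mol instead of silently accepting the table. The pipeline runs
this check whenever such a table is supplied.

# The synthetic-data generator

`assay_design()` defaults encode the study layout this package
emulates: inhibitor doses 0, 0.4, 0.6, 0.8, 1.0, 1.5, 2.0, 4.0 mg/mL;
substrate 0.4–1.6 mg/mL in 0.2 steps; enzyme 5, 10, 15, 20 mg/mL;
quencher:enzyme molar ratios 0, 0.5, 1, 2, 4, 5, 10, 20 at 5×10⁻⁶
mol/L enzyme; temperatures 293 and 303 K; triplicate measurements.
Noise is multiplicative Gaussian (relative SD, default scenarios use
2%) truncated at zero, because plate readers and fluorometers have
signal-proportional error and negative signals are unphysical.
Generation is deterministic given (design, truth, seed).

Forward models, chosen so that each fitting stage recovers the truth
exactly at zero noise:

* **Plate wells** — the uninhibited blank-corrected window `a − A` is
  fixed (0.80 absorbance over a 0.10 blank) and the sample signal is
  that window scaled by `1 − p(I)`, with `p` a probit curve in log10
  dose centred at the true IC50 — the same family the estimator fits,
  so generation and fitting are self-consistent. The sample blank
  includes a small inhibitor self-absorbance term, which the Eq-style
  blank correction removes exactly.
* **Velocities** — the competitive rate law
  `V = Vmax·S/(Km(1+I/Ki)+S)`; the enzyme-layout generator scales this
  linearly with enzyme (reversible) or subtracts a fixed inactivated
  amount per dose (irreversible). Each grid point is emitted in
  triplicate, mirroring the endpoint assay's replication, which the
  kinetic runs reuse.
* **Spectra** — one Gaussian emission band (SD 18 nm) per titration
  point on a 1 nm grid, amplitude `F0/(1 + Ksv·Q)` (static single-site
  default) or `F0/(1 + Ka·Qⁿ)` for fractional stoichiometries, centre
  red-shifted by 0.1 nm per unit molar ratio. The centre is snapped to
  the wavelength grid so the grid argmax equals the model amplitude
  exactly; with off-grid centres the extracted peak would be biased by
  ~3×10⁻⁶ relative, violating exact Stern–Volmer round trips. The snap
  quantises sub-nanometre shifts, which is also what a 1 nm
  monochromator step does in practice.
* Quencher dilution of the enzyme is treated as negligible (final molar
  ratios are what is specified, not addition volumes), and no
  inner-filter correction is modelled. The generator works in mol/L for
  quencher concentrations; any mg/mL↔mol/L conversion is the user's,
  since a crude extract has no single molar mass.

What the generator does *not* emulate — plate spatial effects,
instrument drift, inner-filter attenuation at high quencher
absorbance, correlated replicate error — bounds what passing tests
show: they validate the estimators against the stated noise model, not
against every artefact of real instruments.

# Problem sizes and verification

The test-suite and acceptance-script simulations use the full default
grids with 200 seeded noise replicates at 2% relative noise, a size at
which median recovery errors are stable to a fraction of a percent
across seeds while the whole suite runs in well under a minute. Under
those conditions the median relative recovery errors are roughly: IC50
~1%, Vmax ~0.5%, Km ~3.5%, Ki ~8%, Ksv ~1.3%, n ~2%.

Ka from the double-log plot is the outlier, at ~18%: the intercept
lies 4–6 log₁₀ decades outside the titration's [Q] range
(2.5×10⁻⁶–10⁻⁴ mol/L), so slope noise is amplified ~5-fold into
lg Ka and hence exponentially into Ka. This is intrinsic to the
unweighted log–log estimator on a single-scan titration of this span —
an idealised simulation with exact 2% noise on the peak intensities
and a known F0 still shows ~20–28% — and is worth knowing when reading
any Ka fitted this way from comparable experiments. Ksv is the
well-determined binding-strength estimate; for single-site static
quenching the two coincide.

# Known limitations

* The probit CI is delta-method, not Fieller; it degenerates for very
  steep noiseless curves (collapsing to a point) and undercovers for
  shallow ones.
* Ki compounds two regressions (per-dose reciprocal fits, then the
  Km_app-vs-[I] line) and inherits both error sources.
* A single Km is reported per run (the zero-dose apparent Km when a
  zero dose is present); per-dose apparent values are always available
  in `Km_app_by_I`.
* No time-course (progress-curve) analysis, no 4PL/Hill dose–response
  alternative, no modified Stern–Volmer (fa, Ka′) formalism, no ΔCp
  extension — all outside the models this package implements.
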