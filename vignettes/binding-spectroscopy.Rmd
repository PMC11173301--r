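---
title: "Models and methods: quenching titrations, CD unmixing, and thermal unfolding"
author: "bindspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindspec)
```

This vignette is the package's account of the science behind each
fitted model: the assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data validation
does and does not establish about real measurements.

## Fluorescence quenching

### The Stern–Volmer model and its reading of binding

A quencher Q reduces the steady-state fluorescence of a protein's
tryptophans according to F0/F = 1 + K_SV[Q]. The model assumes a single
homogeneous fluorophore population, quenching linear in free quencher,
and — crucially for the binding interpretation — that free and total
ligand are interchangeable. When quenching is *static* (ground-state
complex formation), K_SV is the association constant and K_d = 1/K_SV.
The package never forces that interpretation: `stern_volmer_fit()`
reports the slope, the intercept (unconstrained by default; a
`force_unit_intercept` option pins it at its theoretical value of 1),
and the derived K_q and K_d, and leaves the mechanism call to
`mechanism_call()`.

The static/dynamic discrimination uses the apparent bimolecular rate
K_q = K_SV/τ. The fluorophore lifetime τ defaults to 5 ns — the
conventional steady-state value for tryptophan — and is configurable on
every titration object. K_q above the diffusion-controlled ceiling
(threshold default 1 × 10¹⁰ L mol⁻¹ s⁻¹) is physically impossible for
purely collisional quenching, so such data are classified `static`;
at or below the ceiling the package deliberately reports
`dynamic-possible` rather than `dynamic`, because steady-state data
alone cannot prove a collisional mechanism. The comparison is a strict
inequality: a rate exactly at the ceiling is not evidence of complex
formation.

Fluorescence intensities F are read from emission spectra at the
tryptophan band with `band_intensity()` (window maximum; the analysis
band defaults to 345 ± 10 nm, since the emission maximum is the natural
and least arbitrary choice when no analysis wavelength is recorded).
Inner-filter attenuation is corrected per point as
F·10^((A_ex+A_em)/2); the titration carries a `corrected` flag so the
correction cannot be applied twice.

### Two regimes and the breakpoint

Bimodal Stern–Volmer plots — a steep linear regime at low ligand and a
shallow one at high ligand — arise when a tight site titrates
stoichiometrically (the plot then tracks occupancy, not the binding
isotherm) and a weaker site dominates afterwards. `segmented_sv_fit()`
formalises the visual two-lines reading:

* **Split search.** All admissible splits between consecutive
  concentrations (each segment at least 3 points) are scored by the
  pooled residual sum of squares of two independent OLS lines; the
  minimum wins, ties going to the lower concentration.
* **Over-segmentation guards.** Two tests must both reject at α (default
  0.05) before a breakpoint is reported: a two-segment vs single-line
  F-test with 2 extra parameters, Bonferroni-corrected for the size of
  the searched split grid, and a t-test that the two slopes differ,
  using the conservative min-segment residual degrees of freedom. The
  second guard exists because F0/F noise is strongly heteroscedastic
  (multiplicative noise on F inflates the variance of F0/F
  quadratically in its mean), which makes the plain F-test after a
  breakpoint search anti-conservative; with both guards the measured
  false-breakpoint rate on single-line data at 2% noise is below 1%
  while power on genuine two-site data remains 1.0. Data a single line
  explains to within 10⁻⁸ of the total variance are declared unimodal
  outright, avoiding 0/0 F statistics on noiseless input.
* **Breakpoint value.** The reported breakpoint is the concentration at
  which the two fitted lines intersect, clamped into the open gap
  between the last low-segment and first high-segment point. The
  intersection is the natural "change of slope" estimator and respects
  the invariant that the low segment lies strictly below and the high
  segment at or above the breakpoint. On the default two-site truth the
  noiseless intersection falls at ≈1.47 μM for a 1 μM protein — the
  coarse concentration grid (1, 3 μM around the kink) and the curvature
  of the underlying occupancy place it slightly above the exact 1:1
  point.

### The Lehrer model

With two tryptophans of which only one is reachable, quenching
saturates at the shielded fraction: F = F0(1 − f_a K_SV[Q]/(1+K_SV[Q])).
The default fit is the *direct* nonlinear one on untransformed F,
because the classical double-reciprocal plot of F0/(F0−F) against 1/[Q]
amplifies noise exactly where quenching is weakest; the linearised
method is retained (`method = "linearized"`) for comparability with the
classical presentation, with delta-method standard errors. Points with
F ≥ F0 at nonzero ligand carry no quenching information and are
excluded with a warning rather than clamped — silently forcing them
into the model would bias f_a upward. At f_a = 1 the model reduces
exactly to Stern–Volmer, which the test-suite verifies as an identity.

Reported uncertainties throughout are asymptotic OLS/NLS standard
errors. Published f_a values for this chemistry print uncertainties
(±0.4, ±0.5) as large as the estimates themselves, which may be
typographical for ±0.04/±0.05; the package takes no position and simply
reports its own standard errors.

## Circular dichroism

### Units

Instrument output in millidegrees is converted to mean residue
ellipticity as [Θ] = θ·MRW/(10·l·c) with l in cm and c in g/L, the
standard convention giving deg·cm²·dmol⁻¹ and the familiar 10³–10⁴
magnitudes for proteins. (One-line renderings of this formula in the
literature are typographically ambiguous about whether l and the
factor 10 multiply or divide; the package adopts the standard
denominator reading and documents it here.) The conversion demands
`units = "mdeg"` and positive c and l, refuses double conversion, and
`estimate_secondary_structure()` refuses raw-mdeg input rather than
converting silently. Spectral arithmetic (`subtract_blank()`) requires
exactly matching wavelength grids; no resampling operation is provided,
a deliberate omission that keeps hidden smoothing out of v1.

### Secondary-structure estimation

The spectrum is modelled as a convex combination of three reference
curves (helix, sheet, coil): least squares under f ≥ 0, Σf = 1. With
three components the constrained problem is solved *exactly* by
enumerating the seven possible active sets and taking the feasible
minimum — no iterative QP, no convergence parameters. The fit is
scale-sensitive by design: the MRE magnitude carries structural
information, so a doubled spectrum changes the residual, not a
normalisation.

The default basis is a synthetic parametric one — Gaussian bands at the
conventional far-UV positions (helix minima 208/222 nm, sheet minimum
217 nm, coil minimum near 198 nm), tabulated 200–240 nm at 0.5 nm in a
versioned CSV fixture. It is *not* a measured reference set: absolute
fractions from it are only meaningful for spectra generated from or
resembling it, which is exactly its role in recovery testing. For real
spectra, substitute a measured `basis_set()`; large reference-database
deconvolution of the CONTIN/SELCON/CDSSTR kind is out of scope.

## Thermal unfolding

The melt model is two-state with linear baselines,
S(T) = [N(T) + U(T)K(T)]/[1+K(T)], K = exp[−(ΔH_app/R)(1/T − 1/Tm)],
temperatures in kelvin inside the exponential and °C at every
interface. Protein unfolding followed by CD at a fixed wavelength over
a 15–72 °C ramp is typically *irreversible*, so the two-state equilibrium
form is used purely as a shape model: Tm is an apparent midpoint and
ΔH_app an apparent width parameter (start value 300 kJ/mol, bounds
1–10⁵ kJ/mol), never interpreted thermodynamically.

Initialisation is deterministic: Tm₀ from the derivative method,
baselines from OLS on the first and last three points. The derivative
method itself (`tm_by_derivative()`) boxcar-smooths (half-width 1
point), takes central differences, and refines the extremum by
parabolic interpolation of the three surrounding points — on the
standard 3 °C grid this brings the model-free estimate within a few
hundredths of a degree of a symmetric midpoint, so the two estimators
can be required to agree within 0.5 °C on clean data. A transition is
declared only when the interior derivative peak dominates both ends of
the ramp (edge derivative < 0.7 of the peak) — constant-slope
(monotone linear) and flat signals fail this, as do transitions
truncated at the range boundary; such curves come back flagged
`no_transition` instead of fitted. The same flag is raised when the
fitted Tm pins to the temperature boundary. `delta_tm()` refuses to
difference midpoints measured at different wavelengths, since the
apparent midpoint is wavelength-dependent; melts default to 210 nm
with 225 nm the usual alternative, and the analysis wavelength is a
free parameter throughout because archived protocols are ambiguous at
the 0.2–1 nm level (201.2 vs 210.2 nm).

## Synthetic data: what it emulates, and what it does not

Each generator inverts one analysis. Defaults are fixed once, to the
conditions of the emulated experiments:

* titration grid 0 + {0.1, 0.3, 0.5, 1, 3, 5, 10, 20, 40} μM against
  1 μM protein; τ = 5 ns;
* two-site truth: tight site K_d = 50 nM (quench efficiency 0.45),
  weak site K_d = 40 μM (efficiency 0.5) — per-site efficiencies are
  plausible placeholders, as no experiment quantifies them for the
  Trp pair; sites independent, quenching multiplicative;
* Lehrer truth f_a = 0.44, K_SV = 117,050 L/mol; CD truth 59% helix
  (apo) / 68% (bound); melt midpoints at the tabulated 210/225 nm
  values, ΔH_app = 300 kJ/mol, flat 0/1 baselines;
* noise: multiplicative Gaussian CV (default 1%) for fluorescence and
  melts, additive mdeg (default SD 0.2) for CD — detector-like, but
  *not* photobleaching, temperature drift, baseline wander, or
  instrument response.

Tight-site occupancy uses the exact mass-balance quadratic in its
cancellation-stable conjugate form 2L/(s + √(s² − 4PL)),
s = P + L + K_d, verified against an independent bisection oracle to
10⁻¹⁰ over six decades of parameters. The CD generator emits
*millidegrees* via the inverse MRE conversion, so every recovery run
exercises the unit pipeline end to end.

Recovery experiments in the tests and in `scripts/acceptance.R` use 100
seeded replicates per condition (200 where a tighter median is wanted),
sizes chosen so the whole suite runs in well under a minute while the
medians are stable to the tolerances asserted. Passing them shows the
estimators are consistent and approximately unbiased *under the
generators' assumptions*; it does not validate the basis set against
measured CD references, the two-state shape against irreversible
aggregation kinetics, or the independence of the two binding sites in
any real protein.

## Known limitations

* CSV is canonical; the JCAMP-DX reader is single-block
  `(X++(Y..Y))` AFFN only, read-only.
* No global multi-site equilibrium *fitting* of fluorescence data: the
  two-site model is a generator, and the fitting surface is the
  segmented Stern–Volmer description, mirroring standard practice.
* No bootstrap uncertainties by default; asymptotic standard errors
  only.
* Fractions from `estimate_secondary_structure()` inherit the basis:
  with the shipped synthetic basis they are internally consistent, not
  instrument-calibrated.
* Isothermal titration calorimetry, docking and dynamics are entirely
  outside the package's scope.
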