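# bindspec

Spectroscopic analysis of protein–ligand binding for the bench scientist
running steady-state fluorescence and circular dichroism (CD)
experiments: quenching titrations of intrinsic tryptophan fluorescence,
far-UV CD spectra, and thermal denaturation ramps. The package grew out
of the analysis of coffee diterpenes binding to a nuclear-receptor
ligand-binding domain, but every routine is generic.

## What it computes

**Stern–Volmer analysis.** For a titration of a quencher/ligand Q
against a fluorescent protein, the classical relation

    F0 / F = 1 + K_SV [Q]

is fitted by ordinary least squares (`stern_volmer_fit()`). Under a
static (complex-forming) mechanism K_SV equals the association
constant, so the dissociation constant is `K_d = 1 / K_SV`
(`dissociation_constant()`), and the apparent bimolecular rate
`K_q = K_SV / τ` (τ = fluorophore lifetime, default 5 ns) discriminates
static from diffusion-limited collisional quenching against the
~10¹⁰ L mol⁻¹ s⁻¹ ceiling (`mechanism_call()`).

**Segmented (bimodal) plots.** Titrations where a tight site saturates
at a 1:1 ligand:protein ratio and a weaker site takes over show two
linear regimes. `segmented_sv_fit()` finds the split by exhaustive
search minimising the pooled residual sum of squares, reports both
regimes as full Stern–Volmer fits, guards against over-segmentation
with an F-test plus a slope-difference t-test, and returns the
breakpoint as the intersection of the two fitted lines.

**Lehrer (accessible-fraction) model.** When only a fraction f_a of
fluorophores is reachable by the quencher,

    F0 / (F0 − F) = 1 / ([Q] · K_SV · f_a) + 1 / f_a.

`lehrer_fit()` fits this directly (nonlinear least squares on F vs [Q],
default) or in the classical double-reciprocal linearisation.

**Inner-filter correction.** `inner_filter_correct()` applies
`F_corr = F_obs · 10^((A_ex + A_em)/2)` per titration point.

**CD processing.** `mdeg_to_mre()` converts instrument millidegrees to
mean residue ellipticity `[Θ] = θ·MRW / (10·l·c)` (l in cm, c in g/L);
`estimate_secondary_structure()` decomposes an MRE spectrum into helix,
sheet and coil fractions by exact simplex-constrained least squares
onto a pluggable reference basis (`default_basis()` ships a synthetic
parametric basis, 200–240 nm).

**Thermal unfolding.** `fit_melt_two_state()` fits the two-state model
with linear baselines, `S(T) = [N(T) + U(T)K(T)]/[1 + K(T)]`,
`K(T) = exp[−(ΔH_app/R)(1/T − 1/Tm)]`, yielding an apparent melting
midpoint Tm; `tm_by_derivative()` is the model-free cross-check and
`delta_tm()` the ligand-induced stabilisation shift.

**Synthetic data.** `gen_sv_titration()`, `gen_two_site_titration()`
(exact tight-binding quadratic), `gen_lehrer_titration()`,
`gen_cd_spectrum()`, `gen_melt()` and `gen_emission_spectrum()` are
seeded mechanistic generators, each the documented inverse of an
analysis routine, used for all parameter-recovery validation.

## Worked example

```r
library(bindspec)

# a two-site quenching titration: 1 uM protein, tight site 50 nM,
# weak site 40 uM, 1% multiplicative noise
tit <- gen_two_site_titration(two_site_truth(), seed = 11)
segmented_sv_fit(tit)
#> Segmented Stern-Volmer fit: breakpoint 1.497e-06 mol/L (1.5 uM)
#> Low range:
#> Stern-Volmer fit
#>   Ksv = 554641 +/- 8.3e+03 L/mol (intercept 0.9872, r2 0.99955, n = 4)
#>   Kq  = 1.109e+14 L/mol/s (tau = 5e-09 s)
#>   Kd  = 1.803e-06 mol/L (1.803 uM)
#> High range:
#> Stern-Volmer fit
#>   Ksv = 16146.4 +/- 921 L/mol (intercept 1.793, r2 0.99034, n = 5)
#>   Kq  = 3.229e+12 L/mol/s (tau = 5e-09 s)
#>   Kd  = 6.193e-05 mol/L (61.93 uM)
```

The slope change lands near the 1:1 ligand:protein point (1 μM
protein), the tight-binding signature; both regimes quench far above
the diffusion limit:

```r
mechanism_call(554641)
#> Kq = 1.109e+14 L/mol/s (threshold 1e+10): static
```

Accessible-fraction and structure analysis on generated data:

```r
lehrer_fit(gen_lehrer_titration(lehrer_truth(), seed = 11))
#> Lehrer fit (direct): fa = 0.4538 +/- 0.0174, Ksv = 101927 +/- 1.01e+04 L/mol (n = 8)
# truth: fa = 0.44, Ksv = 117,050 L/mol

cd <- gen_cd_spectrum(cd_truth(), seed = 11)      # 59% helix truth, mdeg
estimate_secondary_structure(mdeg_to_mre(cd))
#> Secondary-structure fractions (simplex-constrained least squares)
#>   helix 0.591  sheet 0.199  coil 0.210  (residual norm 620.2)

holo <- fit_melt_two_state(gen_melt(melt_truth(tm = 53.84, noise_cv = 0.02), seed = 11))
holo
#> Two-state melt fit at 210 nm: Tm = 54.25 +/- 0.15 C, dH_app = 286 kJ/mol
apo <- fit_melt_two_state(gen_melt(melt_truth(tm = 51.18, noise_cv = 0.02), seed = 12))
delta_tm(apo, holo)   # +2.87 C: ligand-stabilised
```

A YAML-driven pipeline (`run_pipeline()`, `validate_config()`, thin CLI
at `inst/cli/bindspec`) ties generation, fitting and JSON reporting
together; `inst/extdata/demo_pipeline.yaml` is a complete example.

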