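---
title: "Track-end radiolysis of the super-Fricke dosimeter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-end radiolysis of the super-Fricke dosimeter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggfricke)
```

## The measurement this package models

When a proton or carbon-ion beam stops inside a centimetre of aqueous
solution, nearly all of its energy is released in the last few millimetres
of the track — the Bragg peak. The radiation chemistry in that region is
characterised by the *track-segment radiolytic yield* G(Fe³⁺): the amount
of ferric ion produced per joule of absorbed energy over a short path
interval where the linear energy transfer (LET) is roughly constant. The
yield drops as LET rises, because densely ionising tracks favour radical
recombination over escape into the bulk.

The instrument emulated here reads that yield profile optically. A
super-Fricke solution (10 mM Fe²⁺, 0.4 M H₂SO₄, 1 mM NaCl, O₂-saturated)
sits in a 10 mm cuvette; the stopping beam oxidises Fe²⁺ to Fe³⁺, which
absorbs at 304 nm. A bundle of twenty 250 µm fibres behind an 8/9
magnification relay images twenty contiguous 281.25 µm intervals along the
propagation axis; a camera records frames every 100 ms. Each fibre's
absorbance grows linearly while the dose response is linear, and the
initial slope per fibre, divided by the local dose rate, gives the local
yield:

    G(x) = (dA/dt)_{t=0} / (rho * eps * l * dD/dt(x))

with ρ = 1.024 kg/dm³ the solution density, ε = 2212 L mol⁻¹ cm⁻¹ the
Fe³⁺ extinction coefficient at 304 nm and 25 °C, and l = 0.8 cm the
optical path through the 8 mm beam cylinder. The dose rate comes from the
beam transport model:

    dD/dt(x) = ELF(x) * [I / (z e)] / (rho * A_beam)

where ELF(x) is the energy loss per ion per unit depth, I/(z·e) the
particle rate (electrical current over ion charge state), and A_beam the
8-mm-disc cross-section. The package implements the forward direction
(beam transport → chemistry → fibre absorbance, with noise) and the
inverse direction (traces → slopes → peak location → ELF alignment →
yields with uncertainty bands), so that the inverse pipeline can be
validated by parameter recovery against a known ground truth.

## Beam transport

Electronic stopping powers use the relativistic Bethe formula with the
exact maximum energy transfer to a free electron and Bragg additivity over
the target composition — no shell, Barkas or density-effect corrections.
These corrections matter below roughly 1 MeV/u; the formula is therefore
evaluated only above a documented cutoff of **0.5 MeV/u**, and when a
transported ion drops below the cutoff its remaining energy is deposited
in the current depth bin. That is a deliberately crude treatment of the
last ~10 µm of track, and it is harmless here: the Gaussian straggling
convolution (below) is far wider than the sub-cutoff residual range, so it
dominates the shape of the modelled Bragg peak. Mean excitation energies
are the standard values I(water) = 75 eV, I(PMMA) = 74 eV,
I(air) = 85.7 eV; the super-Fricke solution is dilute enough to be treated
as water at its measured density 1.024 g/cm³.

CSDA ranges integrate the reciprocal stopping power on a fine energy grid;
degrader transport steps dE/dx = −S·ρ with classical RK4 at 5 µm steps.
With these choices 64 MeV protons exit the 23.57 mm PMMA degrader at
27.2 MeV (the beamline quotes ≈25 MeV; an uncorrected Bethe formula
overestimates residual energy by a few percent at these depths) and
95 MeV/u carbon exits 14 mm of PMMA at ≈597 MeV (quoted ≈550 MeV).

The monoenergetic depth-dose curve inside the sample is computed by the
same RK4 stepping on a uniform **10 µm** grid (energy difference across
each bin, so energy is conserved exactly by construction) and then
convolved with a Gaussian in depth. Its width combines two terms in
quadrature:

* range straggling, σ_mono = 0.012 · R^0.951 (R the water CSDA range of
  the *initial* beam energy, in cm — straggling accumulates over the whole
  slowing-down path, degrader included), scaled by √(m_p/m_ion) for
  heavier ions, which reproduces the familiar ≈3.5× narrower carbon peak;
* the initial energy spread mapped to depth through dR/dE at the initial
  energy (σ_E = 0.3 MeV for the proton line).

For the degraded proton beam this gives σ ≈ 0.48 mm; for the carbon beam
σ ≈ 0.08 mm, well below one fibre interval. The convolution kernel is
truncated at 5σ and renormalised; for a stopping beam the profile is
rescaled so the depth integral equals the sample-entrance energy (the
contract is conservation within 1%, and the rescaling makes it exact).
The printed dose-rate formula divides the current by one elementary
charge; this package always divides by z·e so that a 0.1 nA C⁶⁺ current
means I/(6e) ions per second. A `single_charge` switch in the yield step
reproduces the bare printed constant for comparison.

With this model the Bragg-peak dose rates, read the way the instrument
reads them (ELF maximum anchored at a fibre centre, averaged over
281.25 µm bins), are 66 Gy/s for 0.5 nA protons, 133 Gy/s at 1 nA —
exactly double, since the conversion is linear in current — and 88 Gy/s
for 0.1 nA carbon, against quoted values of 70, 140 and 88 Gy/s.

## Chemistry

The super-Fricke mechanism is five reactions: hydrated electrons are
converted to ·H by the acid (k₁ = 2.3×10¹⁰ M⁻¹s⁻¹), ·H to HO₂· by
dissolved oxygen (k₂ = 2.1×10¹⁰), and Fe²⁺ is oxidised by ·OH
(k₃ = 4.3×10⁸), H₂O₂ (k₄ = 42) and HO₂· (k₅ = 2.1×10⁶). Reaction 5 is
implemented with the stoichiometry as published (Fe²⁺ + HO₂· → Fe³⁺ +
H₂O₂ + OH⁻), although in acid the conventional route is protonation of
HO₂⁻; the kinetic consequences for Fe³⁺ are identical because the chain
bookkeeping is unchanged. Summing the chains gives the observed yield

    G(Fe3+) = G(OH) + 2 G(H2O2) + 3 (G(eaq) + G(H) + G(HO2))

implemented as a pure combinator — the package deliberately ships no
"true" primary-yield set, since the measurement determines the combined
yield only. Units convert by exactly 1.036×10⁻⁷ mol/J per
molecule/100 eV.

Two quantitative checks tie the kinetics to the combinator: iron
(Fe²⁺ + Fe³⁺) is conserved exactly by the scheme, and once the slow
H₂O₂ + Fe²⁺ step reaches steady state (τ₄ = 1/(k₄[Fe²⁺]) ≈ 2.4 s) the
Fe³⁺ growth rate matches G(Fe³⁺)·ρ·(dD/dt) to better than 2%. The
dissolved O₂ concentration defaults to 1.3 mM (O₂-saturated acidic water
at 1 atm, 25 °C) and [H₃O⁺] to 0.4 M (first sulfuric proton fully
dissociated) — both config-overridable, as the source only states
"oxygen-saturated" and the acid concentration.

Saturation of the dose response is modelled phenomenologically:
C(D) = G·ρ·D_sat·(1 − exp(−D/D_sat)), with D_sat fixed by requiring a 5%
departure from linearity at the variant's dose limit (500 Gy classic,
10³ Gy super-Fricke). This reproduces the observed onset of curvature
after several seconds at Bragg-peak dose rates without asserting a
mechanism; the full kinetic ODE is available when mechanistic fidelity
matters.

## The synthetic acquisition

The generator's defaults are the measurement conditions: 20 fibres ×
281.25 µm, 100 ms frames, 60 s sequences, beam on at 2 s, 8 mm beam, and
the beam/stack geometries above. One free geometric parameter is not
printed anywhere: the depth at which the fibre window starts. The default
places the shallowest fibre interval at 3 mm, which centres the degraded
proton track end on the array (peak near fibre 7); carbon runs shift the
window accordingly. Fibre intervals are taken as contiguous; the physical
bundle may have gaps, which is why the offset and pitch are
config-exposed.

The concentration field evolves per frame as
dC/dt = G(x)·ρ·(dD/dt)(x)·exp(−D/D_sat), i.e. the derivative of the
saturating dose response, plus 1-D axial diffusion
(D = 6.07×10⁻¹⁰ m²/s for Fe³⁺ at 25 °C) by explicit finite differences
with reflecting boundaries, automatically sub-stepped to respect the CFL
limit, and a first-order radial-loss term standing in for transport out of
the 8 mm beam cylinder. The loss rate, −ln(0.9)/28 s⁻¹, is calibrated so
the deficit reaches 10% after 28 s, matching the 1-D displacement estimate
√(4Dt/π) ≈ 28 µm/s^½ against the cylinder. Diffusion is treated as a
perturbation, not a 3-D solve — consistent with how the measurement treats
it (a displacement-length estimate and a warning to fit slopes early).

Detector noise is applied in intensity space: I = I₀·10^(−A) is perturbed
multiplicatively with shot-like relative width σ_I/I = 0.5% · √(I₀/I)
(so darker, more absorbing frames are noisier — heteroscedastic in A, as
in real transmission data), plus a 0.1% per-frame source flicker common to
all fibres. A constant *relative* perturbation would be homoscedastic in
A (dA = −log₁₀(1+ε)), which is why the shot scaling is used. All
stochastic output is reproducible from config + seed.

What the generator does **not** emulate: beam current drift, monochromator
stray light, camera fixed-pattern noise, stirring, lateral beam structure,
nuclear fragmentation and chloride-impurity chemistry. Passing recovery
tests therefore validates the inversion arithmetic and its failure modes
under the stated statistical structure, not the instrument's systematics.

## The inverse pipeline and its design choices

**Beam-on detection** sums absorbance across fibres and finds the first
frame whose increment exceeds 5× the baseline noise for 3 consecutive
frames; at least 1 s of pre-beam baseline is required.

**Initial slopes** are unweighted OLS over the first n frames after t₀
(n = 10 for protons, 15 for carbon, as in the published read-out). The
optional compromise scan picks the smallest n whose r² ≥ 0.95. Scanning
from n = 5 proved fragile: five noisy points can correlate by luck,
yielding an accepted but wildly wrong slope on low-signal fibres. The
default scan range therefore starts at the fixed-n default (10), so low
signal-to-noise can only lengthen the window — at the Bragg peak the
response saturates within seconds and small n is preferred; at entrance
fibres the signal is weak and n grows toward 30.

**Peak location** takes the fibre of steepest slope (ties broken toward
the deepest fibre, with a warning) and refines it by parabolic
interpolation through the three neighbouring slopes. The refinement is
biased by ~30 µm by the Bragg curve's asymmetry; that bias cancels in the
next step.

**ELF alignment** translates the computed ELF so its maximum falls at the
located absorption maximum, then averages it over the fibre intervals.
Crucially, the ELF's own peak position is estimated with the *same*
fibre-binned parabolic estimator applied to the slopes, so the estimator's
shape bias subtracts out; on self-consistent synthetic data the residual
shift is below 2 µm, and a deliberate 1 mm axis miscalibration is
corrected to a few µm. Alignment presumes the observed coincidence of the
absorption maximum with the energy-loss maximum. A ground truth whose
yield varies strongly across the peak breaks that coincidence (the slope
profile ∝ G·ELF peaks proximal of the ELF), so recovery runs on synthetic
data use `align = FALSE` — the simulator and the analysis share a
calibrated axis, and anchoring is an instrument-calibration step tested
separately on flat-truth runs.

**Yields** divide each slope by ρ·ε·l·(dD/dt) with the dose rate from the
fibre-binned ELF. Fibres whose ELF is below 1% of the maximum are reported
as undefined rather than inflated: a measurable slope at near-zero ELF is
the signature of ferric diffusion beyond the track end, not of local
production. Recovery is judged against the dose-weighted per-fibre truth
⟨G·ELF⟩/⟨ELF⟩, which is what a fibre averaging concentration over its
interval physically measures when G varies within it.

**Uncertainty** is an envelope, not a parametric interval: the yields are
recomputed with the alignment shifted by ±1 fibre and, when replicate runs
are supplied, averaged over replicates with the envelope covering all
shifts and replicates. The dominant systematic in this measurement is
where the computed ELF sits along the fibre axis, and the published error
treatment uses exactly such alignment variations; no distributional claim
is made.

## Problem sizes and reproducibility

The shipped analysis and the test suite run at the measurement's native
scale: 10 µm depth grids over 10 mm (1000 bins), 20 fibres, 100 ms frames
over 10–20 s, two replicates for noisy recovery. The full test suite
completes in well under a minute. End-to-end checks recover a flat truth
within 1% (noiseless), a depth-varying truth within 5% noiseless and 15%
with default noise at 2 nA on all fibres with ELF ≥ 10% of its maximum,
and reproduce the qualitative contrast that motivates the physics: with
proton-like straggling the reconstructed yield rises monotonically over
~1 mm beyond the peak, while with carbon-like straggling at the same fibre
pitch the distal falloff is confined to a single fibre and no progressive
recovery is observable.

## Known limitations

* The Bethe implementation carries no low-energy corrections; absolute
  residual energies after thick degraders are a few percent high, and
  Bragg-peak *positions* inherit that shift. Shapes and dose-rate maxima
  are insensitive because straggling dominates.
* The saturation model is phenomenological; beyond the dose limit only the
  kinetic ODE should be trusted.
* Radial transport is a single loss rate, not a geometry-resolved solve.
* Alignment by absorption maximum fails by construction when the true
  yield varies strongly enough across the peak to displace the absorption
  maximum; the package then requires an externally calibrated depth axis.
* The carbon chain uses the proton straggling law scaled by √(m_p/m_ion);
  fragmentation tails are not modelled.
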