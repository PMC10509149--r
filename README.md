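# braggfricke

Forward and inverse modelling of super-Fricke radiolysis along the track
end of stopping ion beams.

## The problem

In proton and carbon-ion therapy, most of the beam's energy is released in
the final millimetres of the track — the Bragg peak — where the linear
energy transfer (LET) is highest and the radiation chemistry differs
sharply from the low-LET regime. The quantity that captures this is the
track-segment radiolytic yield G(Fe³⁺) of the Fricke dosimeter: moles of
ferric ion produced per joule of absorbed energy over a sub-millimetre
path interval. Measuring it along the track requires imaging the growth of
Fe³⁺ absorbance (304 nm) with sub-millimetre resolution while the beam
stops inside the sample, then inverting the optical signal through a beam
transport model.

This package is for radiation chemists and medical-physics researchers who
want to model or analyse such measurements. It implements:

* **Beam transport** — Bethe stopping powers with Bragg additivity, CSDA
  ranges, degrader transport, and straggled Bragg energy-loss curves
  ELF(x) on a 10 µm depth grid; dose rates via
  dD/dt(x) = ELF(x) · I/(z·e) / (ρ·A_beam).
* **Super-Fricke chemistry** — the five-reaction oxidation mechanism as a
  stiff ODE, the yield combination
  G(Fe³⁺) = G(·OH) + 2·G(H₂O₂) + 3·(G(e⁻aq) + G(·H) + G(HO₂·)),
  dose-response with saturation, and exact unit bridging
  (1 molecule/100 eV = 1.036×10⁻⁷ mol/J).
* **A forward simulator** of the 20-fibre absorbance imager (281.25 µm
  intervals, 100 ms frames, ferric diffusion, shot-like detector noise),
  from a known ground-truth yield profile.
* **The inverse pipeline** — beam-on detection, per-fibre initial slopes
  via G(x) = (dA/dt)₀ / (ρ·ε·l·dD/dt(x)), Bragg-peak localisation, ELF
  alignment and per-fibre yields with alignment-shift uncertainty bands.

## Worked example

Transport the degraded 64 MeV proton beam into the cuvette, simulate an
acquisition with a LET-dependent yield truth, and recover the yield
profile:

```r
library(braggfricke)

stack <- material_stack(list(
  list(material = bf_material("pmma"),         thickness = 23.57),
  list(material = bf_material("super_fricke"), thickness = 10)
), sample = 2)
beam <- beam_spec(projectile("proton"), 64, 0.3, current = 2e-9)

dp <- bragg_elf_curve(beam, stack)
dp
#> <depth profile: 1000 bins x 0.01 mm, peak 6.87 MeV/mm at 6.78 mm, integral 27.18 MeV>

max(dose_rate_profile(dp, beam))
#> [1] 266.8905

fa <- fibre_array()
G_truth <- convert_yield(15 - 10 * dp$elf / max(dp$elf), "molec_100eV", "mol_J")
gt  <- ground_truth(dp, beam, G_truth)
rec <- simulate_acquisition(gt, fa, acquisition_spec(duration = 10), seed = 1)

res <- recover_yields(rec, dp, beam, fa, scan = TRUE, align = FALSE)
res$bp$fibre                 # fibre with the steepest absorbance growth
#> [1] 10
subset(res$yields, fibre %in% 6:8,
       select = c(fibre, depth_mm, elf, G_molec_100eV))
#>    fibre depth_mm      elf G_molec_100eV
#> 13     8 6.515625 6.501033      5.495008
#> 14     7 6.796875 6.819288      5.050592
#> 15     6 7.078125 6.136096      6.068827
```

The depth profile peaks at 6.78 mm with ≈6.9 MeV/mm per ion; at 2 nA that
is ≈270 Gy/s on the fine grid (≈265 Gy/s averaged over a fibre interval),
so the classic 500 Gy Fricke limit is passed within two seconds and only
the first ~1 s of each trace is fitted. The recovered `G_molec_100eV`
falls to ≈5 molecules/100 eV at the energy-loss maximum and rises again
over the next ~1 mm — the straggling-driven post-peak yield recovery.

A scripted version of the whole analysis lives under `analysis/`:

```sh
Rscript analysis/01_stopping_power.R    # ELF curves + Bragg-peak dose rates
Rscript analysis/02_simulate_beamline.R # replicate synthetic acquisitions
Rscript analysis/03_recover_yields.R    # inverse pipeline + truth comparison
```

Each step prints what it found and writes its tables under `results/`.

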