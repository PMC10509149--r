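# Shared fixtures, built once per test run and cached. The beamline
# geometry mirrors the measurement: 64 MeV protons (0.3 MeV spread, 8 mm)
# through a 23.57 mm PMMA degrader into a 10 mm super-Fricke cuvette;
# carbon ions at 95 MeV/u through 14 mm PMMA into the same cuvette.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

fx_proton_stack <- function() fx("p_stack", function() {
  material_stack(list(
    list(material = bf_material("pmma"), thickness = 23.57),
    list(material = bf_material("super_fricke"), thickness = 10)
  ), sample = 2)
})

fx_carbon_stack <- function() fx("c_stack", function() {
  material_stack(list(
    list(material = bf_material("pmma"), thickness = 14),
    list(material = bf_material("super_fricke"), thickness = 10)
  ), sample = 2)
})

fx_proton_beam <- function(current = 0.5e-9) {
  beam_spec(projectile("proton"), 64, 0.3, current)
}

fx_carbon_beam <- function(current = 0.1e-9) {
  beam_spec(projectile("carbon"), 12 * 95, 0.3, current)
}

# straggled ELF for the degraded proton beam (current only affects dose
# rate, not the ELF, so one profile serves all currents)
fx_proton_dp <- function() fx("p_dp", function() {
  bragg_elf_curve(fx_proton_beam(), fx_proton_stack())
})

fx_carbon_dp <- function() fx("c_dp", function() {
  bragg_elf_curve(fx_carbon_beam(), fx_carbon_stack())
})

# Bragg-peak dose rate read the way the instrument reads it: the ELF
# maximum anchored at a fibre centre (the alignment step), binned over the
# 281.25 um intervals, converted with the particle rate I/(z e) over the
# 8 mm beam disc
fx_bp_dose_rate <- function(dp, beam, density = 1.024) {
  w <- 250 / (8 / 9) / 1000
  pk <- dp$depth[which.max(dp$elf)]
  fa <- fibre_array(offset_mm = max(0, pk - 10.5 * w))
  binned <- fibre_average(dp$depth, dp$elf, fa)
  n_ions <- beam$current / (beam$projectile$z * 1.602176634e-19)
  max(binned$value, na.rm = TRUE) * 1.602176634e-13 * 1e3 * n_ions /
    (density * 1000 * pi * (beam$diameter / 2e3)^2)
}

# dose-weighted per-fibre truth: what a fibre averaging the concentration
# over its interval actually measures when G varies within the interval
fx_weighted_truth <- function(dp, G_molec, fa) {
  wt <- fibre_average(dp$depth, G_molec * dp$elf, fa)
  et <- fibre_average(dp$depth, dp$elf, fa)
  data.frame(fibre = wt$fibre, G = wt$value / et$value)
}

# noiseless flat-truth acquisition + recovery at 0.5 nA, reused by several
# pipeline tests
fx_flat_run <- function() fx("flat_run", function() {
  beam <- fx_proton_beam()
  dp <- fx_proton_dp()
  fa <- fibre_array()
  gt <- ground_truth(dp, beam, convert_yield(15, "molec_100eV", "mol_J"),
                     diffusion_D = 0, radial_loss = 0)
  acq <- acquisition_spec(noise_rel = 0, flicker_rel = 0, duration = 10)
  rec <- simulate_acquisition(gt, fa, acq, seed = 1)
  list(beam = beam, dp = dp, fa = fa, gt = gt, acq = acq, rec = rec,
       res = recover_yields(rec, dp, beam, fa))
})
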