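# Stopping-power engine: Bethe formula, CSDA ranges, degrader transport,
# straggled Bragg ELF curves and dose-rate profiles.

test_that("Bethe stopping power has the right magnitude and scaling", {
  w <- bf_material("water")
  p <- projectile("proton")
  c6 <- projectile("carbon")

  # 64 MeV protons in water: reference magnitude from the range tables
  expect_equal(mass_stopping_power(64, w, p), 9.60, tolerance = 0.10)

  # 1/beta^2 regime: stopping power decreases with energy over 1-100 MeV
  Eg <- c(1, 2, 5, 10, 25, 64, 100)
  S <- mass_stopping_power(Eg, w, p)
  expect_true(all(diff(S) < 0))
  expect_true(all(S > 0))

  # z^2 scaling at equal velocity: carbon at the same beta carries z^2 = 36
  # times the proton stopping power (identical Bethe bracket up to the tiny
  # Tmax mass dependence)
  E_p <- 25
  E_c <- E_p * c6$mass / p$mass
  ratio <- mass_stopping_power(E_c, w, c6) / mass_stopping_power(E_p, w, p)
  expect_equal(ratio, 36, tolerance = 0.01)

  # below the 0.5 MeV/u validity cutoff the formula refuses to evaluate
  expect_error(mass_stopping_power(0.4, w, p), "cutoff")
  expect_error(mass_stopping_power(2.9, w, c6), "cutoff")
})

test_that("unknown elements and bad compositions are rejected", {
  expect_error(material("x", 1, data.frame(element = "Xx", fraction = 1), 75),
               "unknown element")
  expect_error(material("x", 1, data.frame(element = "O", fraction = 0.5), 75),
               "sum to 1")
})

test_that("CSDA range matches the brute-force integral and is monotone", {
  w <- bf_material("water")
  p <- projectile("proton")

  # 25 MeV protons in water: ~6.2 mm; brute-force trapezoid at 1 keV steps
  # as the independent oracle
  Eg <- seq(0.5 + 1e-9, 25, by = 1e-3)
  oracle <- 10 * sum(diff(Eg) *
    (1 / (mass_stopping_power(Eg[-1], w, p)) +
     1 / (mass_stopping_power(Eg[-length(Eg)], w, p))) / 2)
  expect_equal(csda_range(25, w, p), oracle, tolerance = 1e-4)
  expect_equal(csda_range(25, w, p), 6.2, tolerance = 0.10)

  # vanishing just above the cutoff; strictly increasing in E0
  expect_lt(csda_range(0.51, w, p), 0.01)
  expect_gt(csda_range(64, w, p), csda_range(25, w, p))
})

test_that("degrader transport reproduces the beamline energies", {
  pm <- bf_material("pmma")
  p <- projectile("proton")
  c6 <- projectile("carbon")

  # zero thickness is the identity
  expect_identical(degrade_energy(64, pm, 0, p), 64)

  # 64 MeV protons through the 23.57 mm PMMA degrader exit near 25 MeV
  expect_equal(degrade_energy(64, pm, 23.57, p), 25, tolerance = 0.10)

  # 95 MeV/u carbon through 14 mm PMMA slows to ~550 MeV
  expect_equal(degrade_energy(12 * 95, pm, 14, c6), 550, tolerance = 0.10)

  # residual energy strictly decreasing in thickness
  th <- c(5, 10, 15, 20)
  Eout <- vapply(th, function(t) degrade_energy(64, pm, t, p), numeric(1))
  expect_true(all(diff(Eout) < 0))

  # beam stopping inside the layer: zero + warning + flag, not an error
  expect_warning(E <- degrade_energy(25, pm, 30, p), "stops inside")
  expect_identical(as.numeric(E), 0)
  expect_true(attr(E, "stopped"))
})

test_that("straggled ELF conserves energy and peaks at the CSDA range", {
  dp <- fx_proton_dp()
  sf <- bf_material("super_fricke")
  p <- projectile("proton")

  # depth-integrated ELF equals the sample-entrance energy within 1 %
  expect_equal(sum(dp$elf) * dp$grid_step, dp$energy_at_sample,
               tolerance = 0.01)
  expect_true(all(dp$elf >= 0))

  # the Bragg peak sits at the CSDA range of the sample-entrance energy,
  # within the straggling width
  r <- csda_range(dp$energy_at_sample, sf, p)
  expect_lt(abs(dp$depth[which.max(dp$elf)] - r), dp$sigma)

  # single global maximum with a distal falloff to ~zero
  expect_lt(dp$elf[length(dp$elf)] / max(dp$elf), 1e-6)

  # conservation holds for any straggling sigma (convolution preserves the
  # integral)
  for (s in c(0.1, 0.8)) {
    dps <- bragg_elf_curve(dp$beam, dp$stack, sigma = s)
    expect_equal(sum(dps$elf) * dps$grid_step, dps$energy_at_sample,
                 tolerance = 0.01)
  }

  # the fibre pitch must be resolved
  expect_error(bragg_elf_curve(dp$beam, dp$stack, grid_step = 0.1),
               "grid_step")
})

test_that("zero-straggling ELF matches naive 1 um Euler stepping", {
  beam <- fx_proton_beam()
  stack <- fx_proton_stack()
  sf <- bf_material("super_fricke")
  p <- projectile("proton")
  dp0 <- bragg_elf_curve(beam, stack, sigma = 0)

  # oracle: explicit Euler at 1 um through the sample, deposits binned on
  # the same 10 um grid
  E <- energy_at_sample(beam, stack)
  h <- 0.001
  steps_per_bin <- 10L  # grid_step / h exactly
  nbin <- length(dp0$depth)
  dep <- numeric(nbin)
  i <- 0L
  while (E > 0.5 && i < 10 / h) {
    dE <- mass_stopping_power(E, sf, p) * sf$density / 10 * h
    dE <- min(dE, E)
    bin <- min(i %/% steps_per_bin + 1L, nbin)  # integer binning, no aliasing
    dep[bin] <- dep[bin] + dE
    E <- E - dE
    i <- i + 1L
  }
  if (E > 0) {  # sub-cutoff residue deposited locally, as the engine does
    bin <- min(i %/% steps_per_bin + 1L, nbin)
    dep[bin] <- dep[bin] + E
  }
  oracle <- dep / dp0$grid_step

  peak_bin <- which.max(oracle)
  sel <- seq_len(peak_bin - 3)  # away from the singular peak bins
  rel <- abs(dp0$elf[sel] - oracle[sel]) / oracle[sel]
  expect_lt(max(rel), 0.02)
})

test_that("beam that cannot reach the sample yields a zero profile", {
  stack <- material_stack(list(
    list(material = bf_material("pmma"), thickness = 40),
    list(material = bf_material("super_fricke"), thickness = 10)
  ), sample = 2)
  expect_warning(dp <- bragg_elf_curve(fx_proton_beam(), stack),
                 "does not reach")
  expect_true(all(dp$elf == 0))
})

test_that("dose rate is exactly linear in current and matches geometry", {
  dp <- fx_proton_dp()
  b1 <- fx_proton_beam(0.5e-9)
  b2 <- fx_proton_beam(1.0e-9)
  d1 <- dose_rate_profile(dp, b1)
  d2 <- dose_rate_profile(dp, b2)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  # hand-computed conversion at one depth: ELF [MeV/mm] * J/MeV * 1e3 *
  # (I / e) / (rho * A)
  i <- which.max(dp$elf)
  expected <- dp$elf[i] * 1.602176634e-13 * 1e3 *
    (0.5e-9 / 1.602176634e-19) / (1024 * pi * 0.004^2)
  expect_equal(d1[i], expected, tolerance = 1e-10)
})

test_that("ELF tables round-trip through the two-column text format", {
  dp <- fx_proton_dp()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_elf(dp, path)
  dp2 <- read_elf(path)
  expect_equal(dp2$depth, dp$depth)
  expect_equal(dp2$elf, dp$elf, tolerance = 1e-12)
  expect_error(read_elf(withr::local_tempfile(lines = "x\t1")), "header")
})
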