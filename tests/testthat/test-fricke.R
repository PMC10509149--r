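# Super-Fricke chemistry: unit conversion, yield combination, dose
# response, scavenging timescales and the kinetic mechanism.

test_that("yield unit conversion is exact and round-trips", {
  expect_equal(convert_yield(1, "molec_100eV", "mol_J"), 1.036e-7)
  # 16.4 molecules/100 eV -> 17.0e-7 mol/J to 3 s.f.
  expect_equal(signif(convert_yield(16.4, "molec_100eV", "mol_J"), 3),
               17.0e-7)
  x <- c(0, 0.3, 5, 16.4)
  expect_equal(
    convert_yield(convert_yield(x, "molec_100eV", "mol_J"),
                  "mol_J", "molec_100eV"), x, tolerance = 1e-15)
  expect_error(convert_yield(1, "eV"), "arg")
})

test_that("ferric yield combination is linear with coefficients 1,2,3,3,3", {
  expect_identical(combined_ferric_yield(c(0, 0, 0, 0, 0)), 0)
  # hand oracle: 1 + 2*1 + 3*(1 + 1 + 0) = 9
  expect_identical(combined_ferric_yield(c(1, 1, 1, 1, 0)), 9)
  # hand oracle: 2.7 + 2*0.7 + 3*(2.6 + 0.6 + 0.02) = 13.76
  expect_equal(combined_ferric_yield(c(2.7, 0.7, 2.6, 0.6, 0.02)), 13.76)

  # linearity in each argument, coefficient by coefficient
  set.seed(7)
  coefs <- c(1, 2, 3, 3, 3)
  for (rep in 1:5) {
    y <- runif(5, 0, 4)
    expect_equal(combined_ferric_yield(y), sum(coefs * y))
    i <- sample(5, 1)
    d <- runif(1)
    y2 <- y; y2[i] <- y2[i] + d
    expect_equal(combined_ferric_yield(y2) - combined_ferric_yield(y),
                 coefs[i] * d)
  }
  expect_error(combined_ferric_yield(c(-1, 0, 0, 0, 0)), "non-negative")

  # primary_yields objects feed through with the exact unit factor
  py <- primary_yields(2.7, 0.7, 2.6, 0.6, 0.02)
  expect_equal(combined_ferric_yield(unclass(py)), 13.76 * 1.036e-7)
})

test_that("ferric concentration: linear regime, saturation, mass balance", {
  sys <- fricke_system()
  G15 <- 15 * 1.036e-7

  expect_identical(ferric_concentration(0, G15, sys), 0)
  # hand oracle: 15*1.036e-7 * 1.024 * 100 = 1.591e-4 mol/L
  expect_equal(ferric_concentration(100, G15, sys, variant = "linear"),
               1.591e-4, tolerance = 1e-3)
  # saturating model departs from linearity by 5 % at the variant limit
  dep_super <- 1 - ferric_concentration(1e3, G15, sys, "super") /
    ferric_concentration(1e3, G15, sys, "linear")
  dep_fricke <- 1 - ferric_concentration(500, G15, sys, "fricke") /
    ferric_concentration(500, G15, sys, "linear")
  expect_equal(dep_super, 0.05, tolerance = 1e-6)
  expect_equal(dep_fricke, 0.05, tolerance = 1e-6)
  # never exceeds the Fe2+ inventory
  expect_lte(ferric_concentration(1e9, G15, sys, "linear"), sys$conc_Fe2)
  expect_lte(ferric_concentration(1e9, G15, sys, "super"), sys$conc_Fe2)
})

test_that("scavenging lifetimes are pseudo-first-order and fast", {
  sys <- fricke_system()
  tau <- scavenging_timescale(sys)
  # radical conversion (reactions 1-2) completes well within a microsecond
  expect_equal(tau[["r1"]], 1 / (2.3e10 * 0.4))
  expect_lt(tau[["r1"]], 1e-6)
  expect_lt(tau[["r2"]], 1e-6)
  # the slow H2O2 + Fe2+ step takes seconds
  expect_equal(tau[["r4"]], 1 / (42 * 0.01), tolerance = 1e-12)
  # doubling a partner concentration halves the lifetime
  tau2 <- scavenging_timescale(fricke_system(conc_Fe2 = 20e-3))
  expect_equal(tau2[["r3"]], tau[["r3"]] / 2)
  # zero partner: infinite lifetime, not an error
  expect_identical(scavenging_timescale(fricke_system(conc_O2 = 0))[["r2"]],
                   Inf)
})

test_that("kinetic mechanism conserves iron and reproduces the combined yield", {
  py <- primary_yields(2.7, 0.7, 2.6, 0.6, 0.02)
  sys <- fricke_system()

  # zero dose rate: nothing moves
  tr0 <- simulate_mechanism(py, 0, 1, times = seq(0, 1, 0.1))
  expect_true(all(abs(tr0$Fe3) < 1e-15))
  expect_true(all(abs(tr0$Fe2 - sys$conc_Fe2) < 1e-12))

  # iron mass balance to 0.1 % throughout
  tr <- simulate_mechanism(py, 1, 40, times = seq(0, 40, 0.5))
  expect_lt(max(abs(tr$Fe2 + tr$Fe3 - sys$conc_Fe2)) / sys$conc_Fe2, 1e-3)
  expect_true(all(tr$Fe3 >= 0))

  # once the slow H2O2 chain reaches steady state (tau4 ~ 2.4 s), the Fe3+
  # slope equals G(Fe3+) rho dD/dt from the yield combination, within 2 %
  G <- combined_ferric_yield(unclass(py))
  pred <- G * sys$density * 1  # mol/L/s at 1 Gy/s
  slope <- (tr$Fe3[tr$time == 40] - tr$Fe3[tr$time == 35]) / 5
  expect_equal(slope, pred, tolerance = 0.02)
})

test_that("linearity limits follow the dosimeter variant", {
  # 560 Gy at 140 Gy/s: beyond classic Fricke, within super-Fricke
  expect_true(linearity_check(560, 140, variant = "super"))
  expect_false(linearity_check(560, 140, variant = "fricke"))
  expect_true(linearity_check(0, 0, variant = "super"))
  expect_true(linearity_check(0, 0, variant = "fricke"))
  expect_false(linearity_check(900, 1e8, variant = "super"))
})
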