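# Forward simulator: diffusion estimate, concentration field, absorbance
# rendering and the raw-image round trip.

test_that("diffusive displacement follows the sqrt(4Dt/pi) law", {
  D <- 6.07e-10
  # 1 s of Fe3+ diffusion at 25 degC: ~28 um
  expect_equal(signif(diffusion_displacement(D, 1) * 1e6, 2), 28)
  expect_identical(diffusion_displacement(D, 0), 0)
  expect_equal(diffusion_displacement(D, 4), 2 * diffusion_displacement(D, 1))
})

test_that("noiseless undiffused field is exactly separable", {
  beam <- fx_proton_beam()
  dp <- fx_proton_dp()
  gt <- ground_truth(dp, beam, convert_yield(15, "molec_100eV", "mol_J"),
                     diffusion_D = 0, radial_loss = 0)
  times <- seq(0, 2, 0.1)
  f <- simulate_concentration_field(gt, times, beam_on = c(0, 2),
                                    saturation = FALSE)
  ddt <- dose_rate_profile(dp, beam)
  # closed form: C(x,t) = G(x) rho dD/dt(x) t
  for (j in c(5, 21)) {
    expected <- gt$yield_profile * gt$sys$density * ddt * times[j]
    expect_equal(f$C[, j], expected, tolerance = 1e-9)
  }
})

test_that("axial diffusion conserves ferric mass and feeds deep fibres", {
  beam <- fx_proton_beam()
  dp <- fx_proton_dp()
  times <- seq(0, 8, 0.1)

  g0 <- ground_truth(dp, beam, diffusion_D = 0, radial_loss = 0)
  gD <- ground_truth(dp, beam, radial_loss = 0)  # D = 6.07e-10 m^2/s
  f0 <- simulate_concentration_field(g0, times)
  fD <- simulate_concentration_field(gD, times)

  # the diffusion operator redistributes but conserves total Fe3+ (0.1 %)
  expect_equal(sum(fD$C[, length(times)]), sum(f0$C[, length(times)]),
               tolerance = 1e-3)

  # a fibre interval beyond the range: zero without diffusion, slowly
  # growing with it
  deep <- dp$depth > dp$depth[which.max(dp$elf)] + 1.5
  expect_true(all(f0$C[deep, length(times)][sum(deep) - (0:9)] == 0))
  expect_gt(max(fD$C[deep, length(times)]), 0)

  # diffusion is symmetric: reflecting the source profile reflects the field
  gR <- g0
  gR$dp$elf <- rev(gR$dp$elf)
  gR$yield_profile <- rev(gR$yield_profile)
  gR$diffusion_D <- gD$diffusion_D
  fR <- simulate_concentration_field(gR, times)
  expect_equal(fR$C[rev(seq_len(nrow(fR$C))), length(times)],
               fD$C[, length(times)], tolerance = 1e-10)
})

test_that("absorbance rendering applies Beer-Lambert over fibre intervals", {
  fa <- fibre_array()
  acq <- acquisition_spec(noise_rel = 0, flicker_rel = 0)
  times <- seq(0, 1, 0.1)
  depth <- seq(0.005, 9.995, 0.01)

  # zero concentration -> zero absorbance everywhere
  f0 <- list(depth = depth, times = times,
             C = matrix(0, length(depth), length(times)))
  A0 <- render_absorbance(f0, fa, acq)
  expect_true(all(A0$absorbance == 0))

  # uniform 1e-4 M: A = 2212 * 0.8 * 1e-4 = 0.177 on every fibre
  fu <- list(depth = depth, times = times,
             C = matrix(1e-4, length(depth), length(times)))
  Au <- render_absorbance(fu, fa, acq)
  expect_equal(unique(round(Au$absorbance, 6)), 0.17696)

  # noise sigma -> 0 reproduces the noiseless rendering bit for bit
  set.seed(5)
  Au2 <- render_absorbance(fu, fa, acquisition_spec(noise_rel = 0,
                                                    flicker_rel = 0))
  expect_identical(Au$absorbance, Au2$absorbance)

  # noisy rendering is heteroscedastic in A: equal intensity noise makes
  # larger absorbance scatter at higher A
  set.seed(11)
  CC <- matrix(rep(c(1e-5, 1.5e-3), each = length(depth)),
               length(depth), 2)
  fh <- list(depth = depth, times = c(0, 0.1), C = CC)
  reps <- replicate(200, {
    a <- render_absorbance(fh, fa, acquisition_spec(noise_rel = 0.005,
                                                    flicker_rel = 0))
    c(stats::sd(a$absorbance[a$time_s == 0]),
      stats::sd(a$absorbance[a$time_s == 0.1]))
  })
  expect_gt(mean(reps[2, ]), mean(reps[1, ]))
})

test_that("identical config and seed give identical traces", {
  run <- fx_flat_run()
  acq <- acquisition_spec(duration = 5)  # default noise on
  r1 <- simulate_acquisition(run$gt, run$fa, acq, seed = 99)
  r2 <- simulate_acquisition(run$gt, run$fa, acq, seed = 99)
  expect_identical(r1$absorbance, r2$absorbance)
  r3 <- simulate_acquisition(run$gt, run$fa, acq, seed = 100)
  expect_false(identical(r3$absorbance, r1$absorbance))
})

test_that("image stacks encode absorbance and round-trip to records", {
  run <- fx_flat_run()
  rec <- run$rec
  short <- rec[rec$time_s <= 5, ]
  attr(short, "frame_period") <- attr(rec, "frame_period")
  attr(short, "beam_on_time") <- attr(rec, "beam_on_time")

  x <- render_image_stack(short, acquisition_spec(duration = 5))
  # pre-beam frames (A = 0) carry the reference intensity I0
  j0 <- which(x$sidecar$times == 0)
  expect_equal(mean(x$stack[j0, , ]), x$sidecar$I0, tolerance = 1e-6)

  # round trip through pixels reproduces the records (16-bit quantisation)
  back <- extract_absorbance(x$stack, x$sidecar)
  m <- merge(short, back, by = c("fibre", "time_s"))
  expect_lt(max(abs(m$absorbance.x - m$absorbance.y)), 2e-4)

  # binning 2 halves the spatial dimensions
  x2 <- render_image_stack(short, acquisition_spec(duration = 5, binning = 2))
  expect_equal(dim(x2$stack)[2:3], dim(x$stack)[2:3] / 2)

  # a stack with no pre-beam frames demands an explicit I0
  sc <- x$sidecar
  sc$beam_on_time <- 0
  expect_error(extract_absorbance(x$stack, sc), "I0")
  ok <- extract_absorbance(x$stack, sc, I0 = x$sidecar$I0)
  expect_equal(nrow(ok), nrow(back))

  # intensity overflow is clipped with a warning
  expect_warning(render_image_stack(short, acquisition_spec(duration = 5),
                                    I0 = 70000), "overflow")
})
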