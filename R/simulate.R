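## Forward simulator of the beamline measurement: a known ground-truth
## yield profile G(Fe3+)(x) plus the ELF-derived dose-rate profile generate
## a ferric concentration field C(x, t) (linear growth, saturation,
## 1-D axial diffusion with a first-order radial-loss term), which is read
## out by the fibre array as Beer-Lambert absorbance with heteroscedastic
## transmission noise.

#' Ground truth for a synthetic run
#'
#' @param dp A `bf_depth_profile` (the ELF along the sample).
#' @param beam A `bf_beam` (defaults to the profile's).
#' @param yield_profile Ferric yield G(Fe3+) in mol/J on `dp$depth`;
#'   either a single number (flat truth) or a vector.
#' @param sys A `fricke_system`.
#' @param diffusion_D Fe3+ diffusion coefficient in m^2/s (default
#'   6.07e-10 at 25 degC).
#' @param radial_loss Per-second first-order loss rate of Fe3+ out of the
#'   8 mm beam cylinder. The default is calibrated from the 1-D
#'   displacement estimate sqrt(4 D t / pi) against the cylinder: the
#'   concentration deficit reaches ~10 percent after 28 s.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(dp, beam = dp$beam,
                         yield_profile = convert_yield(15, "molec_100eV", "mol_J"),
                         sys = fricke_system(),
                         diffusion_D = 6.07e-10,
                         radial_loss = -log(0.9) / 28) {
  stopifnot(inherits(dp, "bf_depth_profile"), diffusion_D >= 0,
            radial_loss >= 0)
  if (length(yield_profile) == 1)
    yield_profile <- rep(yield_profile, length(dp$depth))
  stopifnot(length(yield_profile) == length(dp$depth),
            all(yield_profile >= 0))
  structure(list(dp = dp, beam = beam, yield_profile = yield_profile,
                 sys = sys, diffusion_D = diffusion_D,
                 radial_loss = radial_loss),
            class = "ground_truth")
}

#' Mean one-dimensional diffusive displacement
#'
#' sqrt(4 D t / pi), the mean absolute displacement of a Brownian particle
#' in one dimension after time t.
#'
#' @param D Diffusion coefficient in m^2/s.
#' @param t Time in s (vectorised).
#' @return Displacement in m.
#' @examples
#' diffusion_displacement(6.07e-10, 1) * 1e6  # ~27.8 um
#' @export
diffusion_displacement <- function(D, t) {
  stopifnot(D >= 0, all(t >= 0))
  sqrt(4 * D * t / pi)
}

#' Simulate the ferric concentration field
#'
#' Generates C(x, t) on the depth grid of the ground truth's ELF profile.
#' Per frame, the source term G(x) rho dD/dt(x) exp(-D(x,t)/D_sat) is
#' accumulated (the exponential factor is the derivative of the saturating
#' dose response, so the no-diffusion field integrates exactly to the
#' saturation model), then 1-D diffusion along the beam axis is applied by
#' explicit finite differences with reflecting boundaries (automatically
#' sub-stepped to respect the CFL limit) together with the first-order
#' radial-loss term.
#'
#' @param gt A `ground_truth`.
#' @param times Output times in s (uniform grid, e.g. frame times).
#' @param beam_on Length-2 beam-on window in s.
#' @param saturation Logical; apply the saturating dose response
#'   (default TRUE).
#' @return A list with `depth` (mm), `times` (s) and `C` (matrix
#'   depth x time, mol/L).
#' @export
simulate_concentration_field <- function(gt, times, beam_on = c(0, max(times)),
                                         saturation = TRUE) {
  stopifnot(inherits(gt, "ground_truth"), length(times) >= 2)
  dt_out <- diff(times)
  stopifnot(all(abs(dt_out - dt_out[1]) < 1e-9))
  dt <- dt_out[1]
  depth <- gt$dp$depth
  nx <- length(depth)
  dx_m <- gt$dp$grid_step * 1e-3
  ddt <- dose_rate_profile(gt$dp, gt$beam, gt$sys$density)  # Gy/s
  rho <- gt$sys$density
  d_sat <- .bf_dsat(gt$sys$dose_limit_super)

  # diffusion sub-stepping: explicit scheme stable for D dt/dx^2 <= 0.5
  n_sub <- if (gt$diffusion_D > 0)
    max(1L, ceiling(gt$diffusion_D * dt / (0.4 * dx_m^2))) else 1L
  h <- dt / n_sub
  alpha <- gt$diffusion_D * h / dx_m^2
  loss <- gt$radial_loss

  C <- matrix(0, nx, length(times))
  conc <- numeric(nx)
  dose <- numeric(nx)
  for (j in seq_along(times)[-1]) {
    t0 <- times[j - 1]
    for (s in seq_len(n_sub)) {
      tm <- t0 + (s - 0.5) * h
      if (tm >= beam_on[1] && tm < beam_on[2]) {
        fac <- if (saturation) exp(-dose / d_sat) else 1
        conc <- conc + gt$yield_profile * rho * ddt * fac * h
        dose <- dose + ddt * h
      }
      if (alpha > 0) {
        lap <- c(conc[2] - conc[1],
                 conc[-c(1, 2)] - 2 * conc[-c(1, nx)] + conc[-c(nx - 1, nx)],
                 conc[nx - 1] - conc[nx])
        conc <- conc + alpha * lap
      }
      if (loss > 0) conc <- conc * (1 - loss * h)
    }
    C[, j] <- conc
  }
  list(depth = depth, times = times, C = C)
}

#' Render per-fibre absorbance records from a concentration field
#'
#' Per fibre, the absorbance at 304 nm is A(t) = eps l <C> with <C> the
#' mean concentration over the fibre's 281.25 um interval and l the 0.8 cm
#' optical path through the beam cylinder. Noise, when enabled, is applied
#' in intensity space: I = I0 10^-A is perturbed multiplicatively with a
#' shot-like relative sigma `acq$noise_rel * sqrt(I0/I)` (Poisson scaling,
#' so darker i.e. more absorbing frames are noisier), plus a per-frame
#' source flicker common to all fibres, and A is recomputed - so the noise
#' is heteroscedastic in A as in real transmission data.
#'
#' @param field Output of [simulate_concentration_field()].
#' @param fa A `fibre_array`.
#' @param acq An `acquisition_spec`.
#' @param sys A `fricke_system` (for epsilon).
#' @param path_length Optical path in cm (default 0.8, the beam diameter).
#' @return Data frame (fibre, time_s, absorbance) of class
#'   `absorbance_records`, with attributes `frame_period`, `beam_on_time`,
#'   `path_length`.
#' @export
render_absorbance <- function(field, fa, acq, sys = fricke_system(),
                              path_length = 0.8) {
  stopifnot(inherits(fa, "fibre_array"), inherits(acq, "acquisition_spec"))
  nt <- length(field$times)
  A <- matrix(0, fa$n_fibres, nt)
  for (i in seq_len(fa$n_fibres)) {
    lo <- fa$map$x_lo[i]; hi <- fa$map$x_hi[i]
    sel <- field$depth >= lo & field$depth < hi
    if (!any(sel))
      stop("concentration field does not cover fibre ", fa$map$fibre[i])
    A[i, ] <- sys$epsilon_304 * path_length * colMeans(field$C[sel, , drop = FALSE])
  }
  if (acq$noise_rel > 0 || acq$flicker_rel > 0) {
    I <- 10^(-A)
    flick <- 1 + acq$flicker_rel * stats::rnorm(nt)
    noise <- matrix(1 + acq$noise_rel * 10^(A / 2) * stats::rnorm(length(I)),
                    nrow(I), ncol(I))
    I <- I * noise * rep(flick, each = nrow(I))
    I[I <= 0] <- .Machine$double.eps
    A <- -log10(I)
  }
  out <- data.frame(
    fibre = rep(fa$map$fibre, nt),
    time_s = rep(field$times, each = fa$n_fibres),
    absorbance = as.vector(A)
  )
  structure(out, class = c("absorbance_records", "data.frame"),
            frame_period = acq$frame_period,
            beam_on_time = acq$beam_on_time,
            path_length = path_length)
}

#' Simulate a complete synthetic acquisition
#'
#' Convenience wrapper: concentration field on the acquisition's frame
#' grid (beam on from `acq$beam_on_time` to the end), rendered to fibre
#' absorbance records.
#'
#' @inheritParams render_absorbance
#' @param gt A `ground_truth`.
#' @param seed Optional RNG seed recorded in the output's `seed`
#'   attribute; all stochastic output is reproducible from it.
#' @return An `absorbance_records` data frame.
#' @export
simulate_acquisition <- function(gt, fa = fibre_array(),
                                 acq = acquisition_spec(),
                                 path_length = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, acq$duration, by = acq$frame_period)
  field <- simulate_concentration_field(
    gt, times, beam_on = c(acq$beam_on_time, acq$duration))
  rec <- render_absorbance(field, fa, acq, gt$sys, path_length)
  attr(rec, "seed") <- seed
  rec
}

#' Write absorbance records as a tidy delimited table
#' @param records An `absorbance_records` data frame.
#' @param path Output path (tab-separated: fibre, time_s, absorbance).
#' @export
write_traces <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param frame_period,beam_on_time Acquisition metadata to attach when
#'   reading (frame period inferred from the time grid if omitted).
#' @export
read_traces <- function(path, frame_period = NULL, beam_on_time = NA) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("fibre", "time_s", "absorbance") %in% names(tab)))
  if (is.null(frame_period)) {
    tt <- sort(unique(tab$time_s))
    frame_period <- stats::median(diff(tt))
  }
  structure(tab, class = c("absorbance_records", "data.frame"),
            frame_period = frame_period, beam_on_time = beam_on_time)
}
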