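## Geometry of the 20-fibre readout. Each 250 um fibre images, through the
## 8/9-magnification relay, a 281.25 um wide interval of the track; fibre
## 20 sits at the beam entrance side and fibre 1 is the deepest, so depth
## increases as the fibre index decreases.

#' Fibre-array geometry
#'
#' @param n_fibres Number of fibres (default 20).
#' @param fibre_diameter Fibre core diameter in um (default 250).
#' @param magnification Relay magnification (default 8/9); the interval
#'   width in the sample is `fibre_diameter / magnification`.
#' @param offset_mm Depth (mm, from the sample entrance) of the start of
#'   the shallowest fibre's interval. The bundle spans 5.625 mm of a 10 mm
#'   cuvette; the default 3 mm centres the track end of the degraded
#'   proton beam on the array.
#' @return A `fibre_array` with the per-fibre half-open depth intervals
#'   `[x_lo, x_hi)` in mm, ordered fibre `n_fibres` (shallowest) to 1
#'   (deepest).
#' @examples
#' fa <- fibre_array()
#' fa$width_mm  # 0.28125
#' @export
fibre_array <- function(n_fibres = 20, fibre_diameter = 250,
                        magnification = 8 / 9, offset_mm = 3) {
  stopifnot(n_fibres >= 1, fibre_diameter > 0, magnification > 0,
            offset_mm >= 0)
  w <- fibre_diameter / magnification / 1000  # mm
  fibre <- seq(n_fibres, 1)
  x_lo <- offset_mm + (n_fibres - fibre) * w
  structure(list(
    n_fibres = n_fibres,
    width_mm = w,
    offset_mm = offset_mm,
    map = data.frame(fibre = fibre, x_lo = x_lo, x_hi = x_lo + w)
  ), class = "fibre_array")
}

#' Depth of a fibre's interval centre
#' @param fa A `fibre_array`.
#' @param fibre Fibre index (vectorised).
#' @return Depth in mm.
#' @export
fibre_centre <- function(fa, fibre) {
  i <- match(fibre, fa$map$fibre)
  (fa$map$x_lo[i] + fa$map$x_hi[i]) / 2
}

#' Average a depth profile over the fibre intervals
#'
#' Bins a quantity sampled on a (fine) depth grid into the per-fibre
#' half-open intervals by arithmetic mean over the grid points falling in
#' each interval.
#'
#' @param depth Depth grid (mm), bin centres.
#' @param values Values on `depth`.
#' @param fa A `fibre_array`.
#' @return Data frame (fibre, depth_mm, value), ordered shallowest first.
#' @export
fibre_average <- function(depth, values, fa) {
  stopifnot(length(depth) == length(values))
  out <- fa$map
  out$value <- vapply(seq_len(nrow(out)), function(i) {
    sel <- depth >= out$x_lo[i] & depth < out$x_hi[i]
    if (!any(sel)) return(NA_real_)
    mean(values[sel])
  }, numeric(1))
  data.frame(fibre = out$fibre, depth_mm = (out$x_lo + out$x_hi) / 2,
             value = out$value)
}

#' Acquisition parameters of the camera
#'
#' @param frame_period Frame integration time in s (default 0.1).
#' @param duration Sequence duration in s (default 60).
#' @param beam_on_time Time at which the irradiation starts, s.
#' @param noise_rel Relative intensity noise sigma_I/I per fibre and frame
#'   (default 0.5 percent); 0 disables noise.
#' @param flicker_rel Relative per-frame source flicker common to all
#'   fibres (default 0.1 percent).
#' @param binning Camera binning, 1 or 2.
#' @return An `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_period = 0.1, duration = 60,
                             beam_on_time = 2, noise_rel = 0.005,
                             flicker_rel = 0.001, binning = 1) {
  stopifnot(frame_period > 0, duration > 0,
            beam_on_time >= 0, beam_on_time < duration,
            noise_rel >= 0, flicker_rel >= 0, binning %in% c(1, 2))
  structure(list(frame_period = frame_period, duration = duration,
                 beam_on_time = beam_on_time, noise_rel = noise_rel,
                 flicker_rel = flicker_rel, binning = as.integer(binning)),
            class = "acquisition_spec")
}
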