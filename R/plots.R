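## Cosmetic plots: absorbance vs time per fibre, and the yield / ELF
## depth profiles. Base graphics, untested numerically.

#' Plot absorbance traces per fibre
#'
#' @param records An `absorbance_records` data frame.
#' @param fibres Fibre indices to draw (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_traces <- function(records, fibres = NULL, ...) {
  rm_ <- .records_matrix(records)
  keep <- if (is.null(fibres)) seq_along(rm_$fibres) else
    match(fibres, rm_$fibres)
  graphics::matplot(rm_$times, t(rm_$A[keep, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (s)",
                    ylab = "absorbance at 304 nm", ...)
  graphics::legend("topleft", legend = paste("fibre", rm_$fibres[keep]),
                   col = seq_along(keep), lty = 1, cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Plot a yield profile with its ELF
#'
#' Recovered G(Fe3+) per fibre (left axis, molecules/100 eV) over the
#' aligned ELF (right axis, arbitrary normalisation), against depth.
#'
#' @param yp A `yield_profile` (with or without bands).
#' @param truth Optional true yield values (molecules/100 eV) on the same
#'   fibres, drawn as a dashed line.
#' @export
plot_yield_profile <- function(yp, truth = NULL) {
  ok <- !is.na(yp$G_molec_100eV)
  ylim <- range(c(yp$G_molec_100eV[ok],
                  if (!is.null(yp$band_hi)) convert_yield(
                    yp$band_hi[ok], "mol_J", "molec_100eV"), truth),
                na.rm = TRUE)
  graphics::plot(yp$depth_mm[ok], yp$G_molec_100eV[ok], pch = 19,
                 ylim = ylim, xlab = "depth in sample (mm)",
                 ylab = "G(Fe3+) (molecules / 100 eV)")
  if (!is.null(yp$band_lo)) {
    graphics::arrows(yp$depth_mm[ok],
                     convert_yield(yp$band_lo[ok], "mol_J", "molec_100eV"),
                     yp$depth_mm[ok],
                     convert_yield(yp$band_hi[ok], "mol_J", "molec_100eV"),
                     angle = 90, code = 3, length = 0.03)
  }
  if (!is.null(truth))
    graphics::lines(yp$depth_mm, truth, lty = 2)
  elf_scaled <- yp$elf / max(yp$elf, na.rm = TRUE) * ylim[2]
  graphics::lines(yp$depth_mm, elf_scaled, col = "grey50")
  graphics::legend("topright",
                   legend = c("recovered G", "ELF (scaled)",
                              if (!is.null(truth)) "truth"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 2),
                   col = c("black", "grey50", "black"), bty = "n")
  invisible(NULL)
}
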