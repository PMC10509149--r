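## Physical constants used across the package. CODATA values, MeV/cm/g units
## on the physics side; SI conversions are confined to dose_rate_profile()
## and the chemistry layer.

#' Physical constants
#'
#' A named list of the physical constants the package relies on:
#' \describe{
#'   \item{K}{Bethe stopping-power coefficient
#'     \eqn{4\pi N_A r_e^2 m_e c^2} = 0.307075 MeV cm^2/mol.}
#'   \item{me_c2}{Electron rest energy, 0.510999 MeV.}
#'   \item{mp_c2}{Proton rest energy, 938.272 MeV.}
#'   \item{amu_c2}{Atomic mass unit rest energy, 931.494 MeV.}
#'   \item{e_charge}{Elementary charge, 1.602176634e-19 C.}
#'   \item{MeV_J}{Joules per MeV, 1.602176634e-13.}
#'   \item{G_unit}{mol/J per molecule/100 eV, exactly 1.036e-7.}
#' }
#'
#' @format Named list of numeric scalars.
#' @export
bf_constants <- list(
  K         = 0.307075,        # MeV cm^2 / mol
  me_c2     = 0.51099895,      # MeV
  mp_c2     = 938.27208816,    # MeV
  amu_c2    = 931.49410242,    # MeV
  e_charge  = 1.602176634e-19, # C
  MeV_J     = 1.602176634e-13, # J per MeV
  G_unit    = 1.036e-7         # mol/J per molecule/100 eV
)

#' Convert a radiolytic yield between units
#'
#' G-values are quoted either in molecules per 100 eV of absorbed energy or
#' in SI units of mol/J. One molecule/100 eV corresponds to exactly
#' 1.036e-7 mol/J; the conversion is a pure scale factor, so round trips are
#' exact to machine precision.
#'
#' @param value Numeric vector of yields.
#' @param from,to Unit strings, one of `"molec_100eV"` or `"mol_J"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_yield(16.4, "molec_100eV", "mol_J")  # 1.699e-06
#' @export
convert_yield <- function(value, from = c("molec_100eV", "mol_J"),
                          to = c("mol_J", "molec_100eV")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value))
  if (from == to) return(value)
  if (from == "molec_100eV") value * bf_constants$G_unit
  else value / bf_constants$G_unit
}
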