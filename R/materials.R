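## Target materials and projectiles for the stopping-power engine.
## Compositions are ICRU mass fractions; mean excitation energies are the
## standard ICRU-37/49 values. The super-Fricke solution is dilute enough
## (10 mM Mohr's salt, 0.4 M H2SO4) that it is treated as water at its
## measured density of 1.024 g/cm^3.

# Z and A for the elements the built-in materials use.
.bf_elements <- data.frame(
  element = c("H", "C", "N", "O", "Ar", "S", "Fe"),
  Z = c(1, 6, 7, 8, 18, 16, 26),
  A = c(1.008, 12.011, 14.007, 15.999, 39.948, 32.06, 55.845),
  stringsAsFactors = FALSE
)

#' Define a target material
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3.
#' @param composition Data frame with columns `element` and `fraction`
#'   (mass fractions, must sum to 1).
#' @param I Mean excitation energy in eV.
#' @return A `bf_material` object.
#' @export
material <- function(name, density, composition, I) {
  stopifnot(is.character(name), density > 0, I > 0)
  stopifnot(all(c("element", "fraction") %in% names(composition)))
  if (abs(sum(composition$fraction) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", sum(composition$fraction), ")")
  unknown <- setdiff(composition$element, .bf_elements$element)
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  idx <- match(composition$element, .bf_elements$element)
  comp <- data.frame(
    element = composition$element,
    Z = .bf_elements$Z[idx],
    A = .bf_elements$A[idx],
    fraction = composition$fraction,
    stringsAsFactors = FALSE
  )
  structure(list(name = name, density = density, composition = comp, I = I),
            class = "bf_material")
}

#' Built-in materials
#'
#' Standard targets for the beamline geometry: liquid water, the
#' super-Fricke solution (water composition at 1.024 g/cm^3), PMMA
#' (degrader plastic) and dry air.
#'
#' @param name One of `"water"`, `"super_fricke"`, `"pmma"`, `"air"`.
#' @return A `bf_material`.
#' @examples
#' bf_material("super_fricke")$density  # 1.024
#' @export
bf_material <- function(name = c("water", "super_fricke", "pmma", "air")) {
  name <- match.arg(name)
  water_comp <- data.frame(element = c("H", "O"),
                           fraction = c(0.111894, 0.888106))
  switch(name,
    water = material("water", 1.000, water_comp, I = 75),
    super_fricke = material("super_fricke", 1.024, water_comp, I = 75),
    pmma = material("pmma", 1.19,
      data.frame(element = c("H", "C", "O"),
                 fraction = c(0.080538, 0.599848, 0.319614)),
      I = 74),
    air = material("air", 1.20479e-3,
      data.frame(element = c("C", "N", "O", "Ar"),
                 fraction = c(0.000124, 0.755267, 0.231781, 0.012827)),
      I = 85.7)
  )
}

#' Define a projectile ion
#'
#' @param name One of `"proton"`, `"carbon"`, or a custom name when `z` and
#'   `mass` are given explicitly.
#' @param z Charge number (1 for protons, 6 for fully stripped carbon).
#' @param mass Rest energy in MeV.
#' @return A `bf_projectile` object.
#' @export
projectile <- function(name = c("proton", "carbon"), z = NULL, mass = NULL) {
  if (is.null(z) || is.null(mass)) {
    name <- match.arg(name)
    if (name == "proton") {
      z <- 1L; mass <- bf_constants$mp_c2
    } else {
      z <- 6L; mass <- 12 * bf_constants$amu_c2
    }
  }
  stopifnot(z >= 1, mass > 0)
  structure(list(name = name, z = as.integer(z), mass = mass,
                 n_nucleons = round(mass / bf_constants$amu_c2)),
            class = "bf_projectile")
}

#' Beam specification
#'
#' Bundles the projectile with the accelerator parameters: mean kinetic
#' energy at the stack entrance, Gaussian energy spread, electrical beam
#' current and collimated beam diameter.
#'
#' @param projectile A `bf_projectile`.
#' @param energy Mean kinetic energy in MeV (total, not per nucleon).
#' @param energy_spread Gaussian sigma of the energy distribution in MeV.
#' @param current Beam current in A.
#' @param diameter Collimated beam diameter in mm.
#' @return A `bf_beam` object.
#' @examples
#' beam_spec(projectile("proton"), 64, 0.3, 0.5e-9)
#' @export
beam_spec <- function(projectile, energy, energy_spread = 0.3,
                      current = 0.5e-9, diameter = 8) {
  stopifnot(inherits(projectile, "bf_projectile"),
            energy > 0, energy_spread >= 0, current >= 0, diameter > 0)
  structure(list(projectile = projectile, energy = energy,
                 energy_spread = energy_spread, current = current,
                 diameter = diameter),
            class = "bf_beam")
}

#' Material stack traversed by the beam
#'
#' Ordered layers from the accelerator exit to the far wall of the sample
#' cuvette. Exactly one layer is flagged as the observed sample.
#'
#' @param layers List of `list(material = <bf_material>, thickness = <mm>)`.
#' @param sample Index of the sample layer.
#' @return A `bf_stack` object.
#' @export
material_stack <- function(layers, sample = length(layers)) {
  stopifnot(length(layers) >= 1, sample >= 1, sample <= length(layers))
  for (ly in layers) {
    stopifnot(inherits(ly$material, "bf_material"), ly$thickness > 0)
  }
  structure(list(layers = layers, sample = as.integer(sample)),
            class = "bf_stack")
}

#' @export
print.bf_material <- function(x, ...) {
  cat(sprintf("<material %s: rho = %g g/cm^3, I = %g eV>\n",
              x$name, x$density, x$I))
  invisible(x)
}

#' @export
print.bf_beam <- function(x, ...) {
  cat(sprintf("<beam: %s, %.1f MeV (sigma %.2f), %.3g nA, %g mm>\n",
              x$projectile$name, x$energy, x$energy_spread,
              x$current * 1e9, x$diameter))
  invisible(x)
}
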