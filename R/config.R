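## YAML run configuration and run manifests. A config file groups the
## physical defaults under `beam:`, `stack:`, `fricke:`, `optics:`,
## `acquisition:` and `truth:` blocks; every analysis run can emit a JSON
## manifest recording the config snapshot, seed and input/output digests
## so that identical config + seed reproduces identical tables.

#' Read a run configuration
#'
#' Parses a YAML configuration into the package's domain objects. All
#' blocks are optional; missing values fall back to the built-in defaults
#' (64 MeV proton beam, 0.3 MeV spread, 8 mm diameter; PMMA degrader +
#' 10 mm super-Fricke cuvette; standard solution; 20-fibre array).
#'
#' @param path Path to a YAML file.
#' @return List with elements `beam`, `stack`, `sys` (fricke system),
#'   `fibres`, `acq`, `truth` (raw list or NULL), `raw` (parsed YAML).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- cfg$beam %||% list()
  proj <- projectile(b$projectile %||% "proton")
  beam <- beam_spec(proj,
                    energy = b$energy_MeV %||% 64,
                    energy_spread = b$energy_spread_MeV %||% 0.3,
                    current = b$current_nA %||% 0.5 * 1e-9,
                    diameter = b$diameter_mm %||% 8)
  s <- cfg$stack %||% list()
  layers <- if (!is.null(s$layers)) {
    lapply(s$layers, function(ly)
      list(material = bf_material(ly$material), thickness = ly$thickness_mm))
  } else {
    list(list(material = bf_material("pmma"),
              thickness = s$degrader_mm %||% 23.57),
         list(material = bf_material("super_fricke"),
              thickness = s$sample_mm %||% 10))
  }
  stack <- material_stack(layers, sample = s$sample_index %||% length(layers))
  f <- cfg$fricke %||% list()
  sys <- fricke_system(
    conc_Fe2 = f$conc_Fe2 %||% 10e-3,
    conc_H2SO4 = f$conc_H2SO4 %||% 0.4,
    conc_NaCl = f$conc_NaCl %||% 1e-3,
    conc_O2 = f$conc_O2 %||% 1.3e-3,
    epsilon_304 = f$epsilon_304 %||% 2212,
    density = f$density %||% 1.024)
  o <- cfg$optics %||% list()
  fibres <- fibre_array(
    n_fibres = o$n_fibres %||% 20,
    fibre_diameter = o$fibre_diameter_um %||% 250,
    magnification = o$magnification %||% (8 / 9),
    offset_mm = o$offset_mm %||% 3)
  a <- cfg$acquisition %||% list()
  acq <- acquisition_spec(
    frame_period = a$frame_period_s %||% 0.1,
    duration = a$duration_s %||% 60,
    beam_on_time = a$beam_on_time_s %||% 2,
    noise_rel = a$noise_rel %||% 0.005,
    flicker_rel = a$flicker_rel %||% 0.001,
    binning = a$binning %||% 1)
  list(beam = beam, stack = stack, sys = sys, fibres = fibres, acq = acq,
       truth = cfg$truth, raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records, as JSON, everything needed to reproduce a run: the raw config
#' snapshot, the RNG seed, a timestamp, the package version, and md5
#' digests of the listed input/output files.
#'
#' @param path Output JSON path.
#' @param config Raw config list (e.g. `read_config(...)$raw`).
#' @param seed RNG seed used.
#' @param files Character vector of file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL,
                           files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "braggfricke",
    version = as.character(utils::packageVersion("braggfricke")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    digests = as.list(vapply(files, function(f)
      unname(tools::md5sum(f)), character(1)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
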