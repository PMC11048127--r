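#' Run configuration
#'
#' A single JSON-backed configuration object binding the pipeline
#' together: resonator geometry, dielectric defaults, sample
#' parameters, simulation settings, the RNG seed and output paths.
#' All defaults equal the documented assay constants (GaAs substrate
#' permittivity 12.85, loss tangent 0.00028, 200 um height; 15 um
#' cells; 1 uL droplets; the doubling ladder; the reference
#' calibration line; 3.8% relative replicate noise). The membrane and
#' cytoplasm permittivities are placeholders — no measured values
#' exist for this cell line — and are labelled as such.
#'
#' @return A named list of class `run_config`.
#' @examples
#' cfg <- default_run_config()
#' cfg$sample$cell_diameter
#' @export
default_run_config <- function() {
  structure(
    list(
      geometry = list(
        n = 3, d_out = 300e-6, d_in = 100e-6,
        finger_length = 1e-3, a = 10e-6, b = 20e-6,
        nitride_thickness = 0.2e-6,
        substrate_eps = 12.85, substrate_tand = 0.00028,
        substrate_height = 200e-6,
        c_sinx = 0, c_ab = 0, c_sub = 0
      ),
      dielectrics = list(
        # placeholder shell permittivities (not measured for this line)
        eps_mem_real = 6, eps_mem_imag = 0,
        eps_cyto_real = 60, eps_cyto_imag = 0,
        mixing_rule = "maxwell-garnett"
      ),
      sample = list(
        concentrations = concentration_ladder(),
        volume = 1, cell_diameter = 15e-6, membrane_thickness = 10e-9,
        chip_width = 1e-3, chip_height = 1e-3
      ),
      simulation = list(
        true_slope = -0.02506e-6, true_intercept = -1.65475,
        replicates = 3, noise_sd = 0.038,
        dry_time = 600, sample_interval = 10, post_dry_time = 120,
        eps_wet = 76, eps_solute = 100, residue_eps_scale = 12,
        kappa = 0.02
      ),
      seed = 1L,
      output = list(dir = ".")
    ),
    class = "run_config"
  )
}

#' @rdname default_run_config
#' @param path Path to a JSON configuration file; keys present in the
#'   file override the defaults, section by section.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- unclass(default_run_config())
  for (sec in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      cfg[[sec]] <- modifyList(cfg[[sec]], as.list(user[[sec]]))
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config section(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname default_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_run_config
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- cfg$geometry
  # constructors run the full invariant checks
  resonator_geometry(
    n = g$n, d_out = g$d_out, d_in = g$d_in,
    finger_length = g$finger_length, a = g$a, b = g$b,
    nitride_thickness = g$nitride_thickness,
    substrate_eps = g$substrate_eps, substrate_tand = g$substrate_tand,
    substrate_height = g$substrate_height
  )
  s <- cfg$sample
  chip_surface(s$chip_width, s$chip_height)
  if (any(s$concentrations < 0)) abort("concentrations must be >= 0.")
  check_scalar(s$volume, "sample$volume", positive = TRUE)
  sim <- cfg$simulation
  check_scalar(sim$noise_sd, "simulation$noise_sd", nonneg = TRUE)
  if (sim$eps_solute <= sim$eps_wet) {
    abort("simulation: eps_solute must exceed eps_wet.")
  }
  if (!cfg$dielectrics$mixing_rule %in% c("maxwell-garnett", "linear")) {
    abort("dielectrics$mixing_rule must be 'maxwell-garnett' or 'linear'.")
  }
  if (!is.null(cfg$seed)) check_scalar(as.numeric(cfg$seed), "seed")
  cfg
}
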