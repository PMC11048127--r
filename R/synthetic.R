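#' Configuration for synthetic endpoint calibration datasets
#'
#' Defaults reproduce the study conditions of the assay this package
#' models: the reference line (slope -0.02506e-6 GHz per cells/mL,
#' intercept -1.65475 GHz), the six-step doubling ladder 0.25e6 to 8e6
#' cells/mL, three replicates per concentration, and multiplicative
#' Gaussian replicate noise with relative SD 0.038 (the quoted
#' replicate-scatter bound, SD < 3.8%).
#'
#' @param true_slope GHz per cells/mL.
#' @param true_intercept GHz.
#' @param concentrations Cells/mL.
#' @param replicates Replicates per concentration, >= 1.
#' @param noise_sd Relative noise SD, >= 0.
#' @param seed Optional integer seed for reproducible draws.
#' @return A named list of class `endpoint_sim_config`.
#' @examples
#' endpoint_sim_config(noise_sd = 0)
#' @export
endpoint_sim_config <- function(true_slope = -0.02506e-6,
                                true_intercept = -1.65475,
                                concentrations = concentration_ladder(),
                                replicates = 3,
                                noise_sd = 0.038,
                                seed = NULL) {
  check_scalar(true_slope, "true_slope")
  check_scalar(true_intercept, "true_intercept")
  if (length(concentrations) < 1L || any(concentrations < 0)) {
    abort("`concentrations` must be non-negative.")
  }
  check_scalar(replicates, "replicates", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(
    list(
      true_slope = true_slope, true_intercept = true_intercept,
      concentrations = concentrations,
      replicates = as.integer(replicates),
      noise_sd = noise_sd, seed = seed
    ),
    class = "endpoint_sim_config"
  )
}

#' Simulate an endpoint calibration dataset
#'
#' Draws a measurement table from the configured affine law with
#' multiplicative Gaussian replicate noise:
#' `f_res = (slope * x + intercept) * (1 + N(0, noise_sd))`.
#' Bit-reproducible for a fixed seed; returns exactly
#' `length(concentrations) * replicates` rows.
#'
#' @param cfg An [endpoint_sim_config()].
#' @return A tibble with columns `concentration_cells_per_ml`,
#'   `f_res_ghz`, `replicate`.
#' @examples
#' simulate_endpoint_dataset(endpoint_sim_config(seed = 1))
#' @export
simulate_endpoint_dataset <- function(cfg = endpoint_sim_config()) {
  stopifnot(inherits(cfg, "endpoint_sim_config"))
  draw <- function() {
    tidyr::expand_grid(
      concentration_cells_per_ml = cfg$concentrations,
      replicate = seq_len(cfg$replicates)
    ) |>
      dplyr::mutate(
        truth = cfg$true_slope * .data$concentration_cells_per_ml +
          cfg$true_intercept,
        f_res_ghz = .data$truth *
          (1 + rnorm(dplyr::n(), 0, cfg$noise_sd))
      ) |>
      dplyr::select("concentration_cells_per_ml", "f_res_ghz", "replicate")
  }
  if (is.null(cfg$seed)) draw() else withr::with_seed(cfg$seed, draw())
}
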