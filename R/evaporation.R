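#' Configuration for synthetic evaporation time courses
#'
#' Describes a droplet drying on the chip: 1 uL initial volume,
#' complete natural evaporation after about ten minutes (600 s), and
#' the dielectric endpoints of the surface model. During the wet
#' segment the solute volume fraction rises as solvent leaves, and the
#' surface permittivity follows [effective_medium_mixture()] of a
#' solute phase (`eps_solute`) in the wet medium (`eps_wet`); both are
#' placeholders standing in for quantities never measured for dried
#' white-blood-cell deposits, constrained only to reproduce the
#' qualitative trajectory (monotone wet downshift, upward jump, dry
#' plateau ordered by concentration). The dry-residue permittivity is
#' `1 + (residue_eps_scale - 1) * coverage` with coverage the deposited
#' count over the monolayer capacity; a pure-PBS run uses
#' `pbs_residue_permittivity`, which must lie strictly between the
#' residue permittivities of the 1e6 and 2e6 cells/mL cases (the
#' observed ordering of the dried-PBS response).
#'
#' @param concentration Cells/mL (0 means pure PBS).
#' @param initial_volume Droplet volume (uL).
#' @param dry_time Time to complete evaporation (s).
#' @param sample_interval Sampling cadence (s); must divide the trace
#'   into `dry_time > sample_interval`.
#' @param post_dry_time Extra time recorded after drying (s).
#' @param eps_wet Wet-medium (PBS) relative permittivity.
#' @param eps_solute Solute-phase permittivity driving the wet-segment
#'   rise; must exceed `eps_wet`.
#' @param residue_eps_scale Full-coverage dry-residue permittivity.
#' @param pbs_residue_permittivity Dry-residue permittivity of pure
#'   PBS; default midway between the 1e6 and 2e6 cells/mL residues.
#' @param kappa Capacitance-loading coefficient: the surface
#'   permittivity perturbs the tank as `C -> C * (1 + kappa * (eps - 1))`.
#' @param noise_sd Trace noise SD (relative for `"multiplicative"`,
#'   GHz for `"additive"`).
#' @param noise_model `"multiplicative"` or `"additive"`.
#' @param volume_decay `"exponential"` (reaches 1% of the initial
#'   volume at `dry_time`) or `"linear"`.
#' @param cell_diameter Cell diameter (m), for volume fraction and
#'   coverage.
#' @param seed Optional integer seed.
#' @return A named list of class `evaporation_sim_config`.
#' @examples
#' evaporation_sim_config(concentration = 1e6)
#' @export
evaporation_sim_config <- function(concentration,
                                   initial_volume = 1,
                                   dry_time = 600,
                                   sample_interval = 10,
                                   post_dry_time = 120,
                                   eps_wet = 76,
                                   eps_solute = 100,
                                   residue_eps_scale = 12,
                                   pbs_residue_permittivity = NULL,
                                   kappa = 0.02,
                                   noise_sd = 0,
                                   noise_model = c("multiplicative", "additive"),
                                   volume_decay = c("exponential", "linear"),
                                   cell_diameter = 15e-6,
                                   seed = NULL) {
  noise_model <- match.arg(noise_model)
  volume_decay <- match.arg(volume_decay)
  check_scalar(concentration, "concentration", nonneg = TRUE)
  check_scalar(initial_volume, "initial_volume", positive = TRUE)
  check_scalar(dry_time, "dry_time", positive = TRUE)
  check_scalar(sample_interval, "sample_interval", positive = TRUE)
  if (dry_time <= sample_interval) {
    abort("`dry_time` must exceed `sample_interval`.")
  }
  check_scalar(post_dry_time, "post_dry_time", positive = TRUE)
  check_scalar(eps_wet, "eps_wet", positive = TRUE)
  check_scalar(eps_solute, "eps_solute", positive = TRUE)
  if (eps_solute <= eps_wet) {
    abort(paste(
      "inconsistent permittivity endpoints: the wet-segment model",
      "requires eps_solute > eps_wet."
    ))
  }
  if (residue_eps_scale <= 1) abort("`residue_eps_scale` must exceed 1.")
  check_scalar(kappa, "kappa", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(cell_diameter, "cell_diameter", positive = TRUE)
  res_lo <- residue_permittivity(1e6, initial_volume, residue_eps_scale,
                                 cell_diameter)
  res_hi <- residue_permittivity(2e6, initial_volume, residue_eps_scale,
                                 cell_diameter)
  if (is.null(pbs_residue_permittivity)) {
    pbs_residue_permittivity <- (res_lo + res_hi) / 2
  }
  if (pbs_residue_permittivity <= res_lo || pbs_residue_permittivity >= res_hi) {
    abort(paste(
      "`pbs_residue_permittivity` must lie strictly between the",
      "dry-residue permittivities of the 1e6 and 2e6 cells/mL cases."
    ))
  }
  structure(
    list(
      concentration = concentration, initial_volume = initial_volume,
      dry_time = dry_time, sample_interval = sample_interval,
      post_dry_time = post_dry_time, eps_wet = eps_wet,
      eps_solute = eps_solute, residue_eps_scale = residue_eps_scale,
      pbs_residue_permittivity = pbs_residue_permittivity,
      kappa = kappa, noise_sd = noise_sd, noise_model = noise_model,
      volume_decay = volume_decay, cell_diameter = cell_diameter,
      seed = seed
    ),
    class = "evaporation_sim_config"
  )
}

# Dry-residue surface permittivity for a deposited concentration.
# Coverage is deliberately uncapped: stacked layers beyond a full
# monolayer keep adding material inside the sensing volume, so the
# plateau stays strictly monotone in concentration.
residue_permittivity <- function(concentration, volume, residue_eps_scale,
                                 cell_diameter) {
  count <- droplet_cell_count(concentration, volume)
  cap <- monolayer_capacity(chip_surface(), cell_diameter)$capacity_raw
  coverage <- count / cap
  1 + (residue_eps_scale - 1) * coverage
}

#' Default equivalent circuit of the bare sensing chip
#'
#' A representative LC tank resonating at the chip's bare operating
#' point of 1.28 GHz (5 nH with the matching capacitance). The
#' fabricated layout behind that operating point is not public, so the
#' split between L and C is conventional; only their product (the
#' resonant frequency) matters to the evaporation simulator.
#'
#' @return A [circuit_params()].
#' @examples
#' default_chip_circuit()
#' @export
default_chip_circuit <- function() {
  L <- 5e-9
  C <- 1 / ((2 * pi * 1.28e9)^2 * L)
  circuit_params(L_total = L, C_total = C)
}

#' Simulate an evaporation time course of the resonator
#'
#' Generates the resonant-frequency trajectory of a droplet drying on
#' the chip. While wet (`t < dry_time`) the solvent volume decays, the
#' solute volume fraction rises, the surface permittivity climbs
#' through the effective-medium mixture, and the resonance shifts
#' monotonically downward through the capacitance loading
#' `f0 = f_bare / sqrt(1 + kappa * (eps_surf - 1))`. At `dry_time` the
#' solvent is gone: the surface permittivity collapses to the dry
#' residue value and the resonance jumps upward (between samples) to a
#' stable plateau that sits lower for higher concentrations.
#'
#' @param cfg An [evaporation_sim_config()].
#' @param circuit A [circuit_params()] giving the bare-chip tank;
#'   default [default_chip_circuit()].
#' @param sweeps Also synthesise a full S11 sweep per time point on
#'   [vna_grid()] and extract its resonance (slower; adds list column
#'   `sweep` and column `f0_extracted_ghz`).
#' @param q_loaded,coupling Resonator line-shape parameters used when
#'   `sweeps = TRUE`.
#' @return A tibble with columns `time_s`, `phase` (`"wet"`/`"dry"`),
#'   `eps_surface`, `f0_ghz`, `concentration_cells_per_ml`, plus sweep
#'   columns when requested.
#' @examples
#' tr <- simulate_evaporation_trace(evaporation_sim_config(1e6))
#' range(tr$f0_ghz)
#' @export
simulate_evaporation_trace <- function(cfg,
                                       circuit = default_chip_circuit(),
                                       sweeps = FALSE,
                                       q_loaded = 80, coupling = 0.9) {
  stopifnot(inherits(cfg, "evaporation_sim_config"),
            inherits(circuit, "circuit_params"))
  f_bare <- circuit$f0
  t <- seq(0, cfg$dry_time + cfg$post_dry_time, by = cfg$sample_interval)
  wet <- t < cfg$dry_time
  # solvent volume fraction remaining
  v_frac <- switch(cfg$volume_decay,
    exponential = exp(-log(100) / cfg$dry_time * t),
    linear = pmax(1 - t / cfg$dry_time, 1e-2)
  )
  # solute volume fraction: cells conserved while solvent leaves
  cell_vol_ml <- 4 / 3 * pi * (cfg$cell_diameter / 2)^3 * 1e6
  phi0 <- min(1, cfg$concentration * cell_vol_ml)
  phi <- pmin(1, phi0 / v_frac)
  eps_wet_t <- Re(effective_medium_mixture(
    complex_permittivity(cfg$eps_solute),
    complex_permittivity(cfg$eps_wet), phi
  ))
  eps_dry <- if (cfg$concentration == 0) {
    cfg$pbs_residue_permittivity
  } else {
    residue_permittivity(cfg$concentration, cfg$initial_volume,
                         cfg$residue_eps_scale, cfg$cell_diameter)
  }
  eps_surf <- ifelse(wet, eps_wet_t, eps_dry)
  f0 <- hz_to_ghz(f_bare) / sqrt(1 + cfg$kappa * (eps_surf - 1))
  add_noise <- function(f) {
    if (cfg$noise_sd == 0) return(f)
    if (cfg$noise_model == "multiplicative") {
      f * (1 + rnorm(length(f), 0, cfg$noise_sd))
    } else {
      f + rnorm(length(f), 0, cfg$noise_sd)
    }
  }
  f0_noisy <- if (is.null(cfg$seed)) add_noise(f0) else {
    withr::with_seed(cfg$seed, add_noise(f0))
  }
  out <- tibble(
    time_s = t,
    phase = ifelse(wet, "wet", "dry"),
    eps_surface = eps_surf,
    f0_ghz = f0_noisy,
    concentration_cells_per_ml = cfg$concentration
  )
  if (sweeps) {
    grid <- vna_grid()
    out <- out |>
      dplyr::mutate(
        sweep = purrr::map(.data$f0_ghz, function(fg) {
          synth_s11(grid, ghz_to_hz(fg), q_loaded, coupling)
        }),
        f0_extracted_ghz = purrr::map_dbl(.data$sweep, function(sw) {
          hz_to_ghz(extract_resonance(sw)$f0_hz)
        })
      )
  }
  out
}

#' Extract endpoint measurements from evaporation traces
#'
#' Locates the post-dry jump in each trace (the largest frequency
#' increment, which must be positive and stand clear of the wet-segment
#' fluctuations) and averages the samples after it into the endpoint
#' resonant frequency — the quantity the evaporation-endpoint protocol
#' records once the trajectory stabilises. At least 3 plateau samples
#' are required.
#'
#' @param traces A single trace tibble from
#'   [simulate_evaporation_trace()], or a list of them.
#' @param replicate Replicate ids, one per trace (default sequential).
#' @return A measurement table (`concentration_cells_per_ml`,
#'   `f_res_ghz`, `replicate`) ready for [fit_calibration()].
#' @examples
#' tr <- simulate_evaporation_trace(evaporation_sim_config(1e6))
#' endpoint_from_traces(tr)
#' @export
endpoint_from_traces <- function(traces, replicate = NULL) {
  if (is.data.frame(traces)) traces <- list(traces)
  replicate <- replicate %||% seq_along(traces)
  purrr::map2_dfr(traces, replicate, function(tr, rep_id) {
    f <- tr$f0_ghz
    if (length(f) < 4L) abort("trace too short to contain a plateau.")
    d <- diff(f)
    j <- which.max(d)
    others <- abs(d[-j])
    clear <- d[j] > 0 &&
      d[j] > 3 * (stats::quantile(others, 0.9, names = FALSE) + 1e-12)
    n_plateau <- length(f) - j
    if (!clear || n_plateau < 3L) {
      abort(paste(
        "no plateau detected: trace lacks a clear post-dry jump with",
        ">= 3 samples after it (was the trace truncated before drying?)"
      ))
    }
    tibble(
      concentration_cells_per_ml = tr$concentration_cells_per_ml[1L],
      f_res_ghz = mean(f[(j + 1L):length(f)]),
      replicate = rep_id
    )
  })
}

#' Plot an evaporation trace
#'
#' @param object A trace tibble from [simulate_evaporation_trace()].
#' @param ... Unused.
#' @return A ggplot of resonant frequency against time, coloured by
#'   wet/dry phase.
#' @export
plot_evaporation_trace <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_s, .data$f0_ghz,
                               colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "Time (s)", y = "Resonant frequency (GHz)",
                  colour = "Phase")
}
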