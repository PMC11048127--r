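#' Droplet sample specification
#'
#' Concentration and volume of a pipetted droplet plus the cell size
#' parameters used by the coverage arithmetic. Defaults describe the
#' K562 white-blood-cell assay: 15 um average cell diameter, 10 nm
#' membrane thickness (back-derived from the two-membrane stacking
#' floor; override if better morphology data exist), 1 uL droplets.
#'
#' @param concentration Cell concentration (cells/mL), >= 0.
#' @param volume Droplet volume (uL), > 0.
#' @param cell_diameter Mean cell diameter (m).
#' @param membrane_thickness Membrane thickness (m).
#' @return A named list of class `sample_spec`.
#' @examples
#' sample_spec(1e6)
#' @export
sample_spec <- function(concentration, volume = 1,
                        cell_diameter = 15e-6,
                        membrane_thickness = 10e-9) {
  check_scalar(concentration, "concentration", nonneg = TRUE)
  check_scalar(volume, "volume", positive = TRUE)
  check_scalar(cell_diameter, "cell_diameter", positive = TRUE)
  check_scalar(membrane_thickness, "membrane_thickness", positive = TRUE)
  structure(
    list(
      concentration = concentration, volume = volume,
      cell_diameter = cell_diameter,
      membrane_thickness = membrane_thickness
    ),
    class = "sample_spec"
  )
}

#' Chip sensing surface
#'
#' @param width,height Chip surface dimensions (m); default 1 mm x 1 mm.
#' @return A named list of class `chip_surface` with an `area` field.
#' @examples
#' chip_surface()$area # 1e-6 m^2
#' @export
chip_surface <- function(width = 1e-3, height = 1e-3) {
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  structure(
    list(width = width, height = height, area = width * height),
    class = "chip_surface"
  )
}

#' The six-step doubling concentration ladder
#'
#' The standard assay ladder: six doubling concentrations from
#' 0.25e6 to 8e6 cells/mL.
#'
#' @return Numeric vector of length 6 (cells/mL).
#' @examples
#' concentration_ladder()
#' @export
concentration_ladder <- function() {
  0.25e6 * 2^(0:5)
}

#' Expected cell count deposited by a droplet
#'
#' `count = concentration * volume`, with the uL-to-mL conversion.
#' At 1 uL the doubling ladder gives exactly 250, 500, 1000, 2000,
#' 4000, 8000 cells.
#'
#' @param concentration Cells/mL, >= 0 (vectorised), or a
#'   [sample_spec()].
#' @param volume Droplet volume (uL); ignored when a `sample_spec` is
#'   given.
#' @return Expected deposited count (cells, real >= 0).
#' @examples
#' droplet_cell_count(concentration_ladder()) # 250 ... 8000
#' @export
droplet_cell_count <- function(concentration, volume = 1) {
  if (inherits(concentration, "sample_spec")) {
    volume <- concentration$volume
    concentration <- concentration$concentration
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("`concentration` must be finite and >= 0.")
  }
  check_scalar(volume, "volume", positive = TRUE)
  concentration * volume * 1e-3 # uL -> mL
}

#' Maximum cross-sectional area of a spherical cell
#'
#' `area = pi * (diameter / 2)^2`. For the 15 um K562 cell this is
#' 1.767e-10 m^2 (about 1.8e-10 m^2 at two significant figures).
#'
#' @param cell_diameter Cell diameter (m), > 0, vectorised.
#' @return Area (m^2).
#' @examples
#' max_cross_section(15e-6)
#' @export
max_cross_section <- function(cell_diameter) {
  if (any(!is.finite(cell_diameter)) || any(cell_diameter <= 0)) {
    abort("`cell_diameter` must be > 0.")
  }
  pi * (cell_diameter / 2)^2
}

#' Monolayer capacity of the chip surface
#'
#' Number of cells needed to tile the chip surface one layer deep,
#' `raw = chip_area / max_cross_section(diameter)`. This is a lower
#' bound on the true packed count, since deformable cells squeeze
#' together. Two companion figures are reported: the raw value rounded
#' to three significant figures (the conventional quote, 5660 for the
#' 1 mm x 1 mm chip and 15 um cells), and the capacity implied by the
#' two-significant-figure cross-section 1.8e-10 m^2 (about 5556), which
#' differs from the unrounded arithmetic — the package always computes
#' with the unrounded area.
#'
#' @param chip A [chip_surface()].
#' @param cell_diameter Cell diameter (m).
#' @return A one-row tibble: `capacity_raw`, `capacity_3sf`,
#'   `capacity_rounded_area`, `cross_section_m2`, `chip_area_m2`.
#' @examples
#' monolayer_capacity()
#' @export
monolayer_capacity <- function(chip = chip_surface(), cell_diameter = 15e-6) {
  stopifnot(inherits(chip, "chip_surface"))
  check_scalar(cell_diameter, "cell_diameter", positive = TRUE)
  xs <- max_cross_section(cell_diameter)
  raw <- chip$area / xs
  tibble(
    capacity_raw = raw,
    capacity_3sf = signif(raw, 3),
    capacity_rounded_area = chip$area / signif(xs, 2),
    cross_section_m2 = xs,
    chip_area_m2 = chip$area
  )
}

#' Height range of a stacked cell deposit
#'
#' Bounds the vertical extent of the dried deposit. The deposit is
#' `layers = ceiling(count / capacity)` cell layers deep. The lower
#' bound takes each contributing interface as flattened down to a
#' membrane thickness, floored at two membranes for any multi-layer
#' stack (`h_min = min(layers, 2) * membrane_thickness`); the upper
#' bound stacks undeformed spheres (`h_max = layers * cell_diameter`).
#' Two cells stacked on a single footprint (`count = 2`,
#' `capacity = 1`) give the canonical range 0.02-30 um at the default
#' cell dimensions.
#'
#' @param count Deposited cell count, >= 0.
#' @param capacity Cells per full layer, > 0 (e.g.
#'   `monolayer_capacity()$capacity_raw`).
#' @param cell_diameter Cell diameter (m).
#' @param membrane_thickness Membrane thickness (m).
#' @return A one-row tibble: `layers`, `h_min_m`, `h_max_m`.
#' @examples
#' stack_height_range(2, 1) # 0.02 um to 30 um
#' @export
stack_height_range <- function(count, capacity,
                               cell_diameter = 15e-6,
                               membrane_thickness = 10e-9) {
  check_scalar(count, "count", nonneg = TRUE)
  check_scalar(capacity, "capacity", positive = TRUE)
  check_scalar(cell_diameter, "cell_diameter", positive = TRUE)
  check_scalar(membrane_thickness, "membrane_thickness", positive = TRUE)
  layers <- ceiling(count / capacity)
  tibble(
    layers = layers,
    h_min_m = min(layers, 2) * membrane_thickness,
    h_max_m = layers * cell_diameter
  )
}

#' Summarise the droplet-deposit geometry for an assay ladder
#'
#' Convenience wrapper combining [droplet_cell_count()],
#' [monolayer_capacity()] and [stack_height_range()] across a set of
#' concentrations.
#'
#' @param concentrations Cells/mL; default the doubling ladder.
#' @param volume Droplet volume (uL).
#' @param chip A [chip_surface()].
#' @param cell_diameter,membrane_thickness Cell dimensions (m).
#' @return A tibble with one row per concentration: deposited count,
#'   surface coverage fraction, layer count and height bounds.
#' @examples
#' deposit_geometry()
#' @export
deposit_geometry <- function(concentrations = concentration_ladder(),
                             volume = 1, chip = chip_surface(),
                             cell_diameter = 15e-6,
                             membrane_thickness = 10e-9) {
  cap <- monolayer_capacity(chip, cell_diameter)
  tibble(concentration = concentrations) |>
    dplyr::mutate(
      count = droplet_cell_count(.data$concentration, volume),
      coverage = .data$count / cap$capacity_raw
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      stack_height_range(.data$count, cap$capacity_raw,
                         cell_diameter, membrane_thickness)
    ) |>
    dplyr::ungroup()
}
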