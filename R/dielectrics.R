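#' Complex relative permittivity
#'
#' Builds a complex permittivity in the physics sign convention
#' `eps = eps' - i eps''`, with `eps' ` the storage part and
#' `eps'' >= 0` the loss part. All dielectric routines in the package
#' accept these plain complex values, so mixing and shell formulas run
#' in ordinary complex arithmetic.
#'
#' @param eps_real Real (storage) part, dimensionless relative value.
#' @param eps_imag Loss part, `>= 0`.
#' @return A complex vector `eps_real - 1i * eps_imag`.
#' @examples
#' complex_permittivity(50, 20)
#' @export
complex_permittivity <- function(eps_real, eps_imag = 0) {
  if (any(!is.finite(eps_real)) || any(!is.finite(eps_imag))) {
    abort("permittivity components must be finite.")
  }
  if (any(eps_imag < 0)) abort("loss part `eps_imag` must be >= 0.")
  complex(real = eps_real, imaginary = -eps_imag)
}

#' @rdname complex_permittivity
#' @param eps A complex permittivity.
#' @export
loss_tangent <- function(eps) {
  er <- Re(eps)
  if (any(er <= 0)) abort("loss tangent undefined for eps' <= 0.")
  -Im(eps) / er
}

#' Electromagnetic penetration depth in a lossy dielectric
#'
#' Depth over which the field power decays in a medium of complex
#' permittivity `eps' - i eps''` at frequency `f`:
#'
#' `Dp = lambda0 / (2 pi sqrt(2 eps')) * (sqrt(1 + (eps''/eps')^2) - 1)^(-1/2)`
#'
#' with `lambda0 = c / f`. A lossless medium (`eps'' = 0`) returns the
#' explicit sentinel `Inf`. In the low-loss limit (`tan d << 1`) this
#' reduces to `lambda0 sqrt(eps') / (2 pi eps'')`.
#'
#' @param eps Complex permittivity from [complex_permittivity()] (or any
#'   complex value with `Re > 0`, `Im <= 0`).
#' @param f Frequency (Hz), > 0.
#' @return Depth in metres (`Inf` when lossless), vectorised.
#' @examples
#' penetration_depth(complex_permittivity(50, 20), 1.28e9) # ~13.4 mm
#' @export
penetration_depth <- function(eps, f) {
  ep <- Re(eps)
  es <- -Im(eps)
  if (any(ep <= 0)) abort("require eps' > 0.")
  if (any(es < 0)) abort("require eps'' >= 0.")
  if (any(!is.finite(f)) || any(f <= 0)) abort("require f > 0.")
  lam0 <- physical_constants()$c_light / f
  tand2 <- (es / ep)^2
  # eps'' = 0 gives 0^(-1/2) = Inf: the lossless sentinel falls out
  lam0 / (2 * pi * sqrt(2 * ep)) * (sqrt(1 + tand2) - 1)^(-0.5)
}

#' Single-shell spherical cell
#'
#' A biological cell modelled as a cytoplasm sphere of radius `R`
#' wrapped in a thin membrane shell of thickness `d` (`0 <= d < R`),
#' each phase with its own complex permittivity.
#'
#' @param radius Cell radius R (m).
#' @param membrane_thickness Membrane thickness d (m), `0 <= d < R`.
#' @param eps_mem,eps_cyto Complex permittivities of membrane and
#'   cytoplasm ([complex_permittivity()]).
#' @return An object of class `shelled_cell`.
#' @examples
#' shelled_cell(7.5e-6, 10e-9, complex_permittivity(6),
#'              complex_permittivity(60))
#' @export
shelled_cell <- function(radius, membrane_thickness, eps_mem, eps_cyto) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(membrane_thickness, "membrane_thickness", nonneg = TRUE)
  if (membrane_thickness >= radius) {
    abort("membrane thickness must satisfy d < R.")
  }
  structure(
    list(
      radius = radius, membrane_thickness = membrane_thickness,
      eps_mem = as.complex(eps_mem), eps_cyto = as.complex(eps_cyto),
      gamma = radius / (radius - membrane_thickness)
    ),
    class = "shelled_cell"
  )
}

#' Equivalent homogeneous permittivity of a single-shell cell
#'
#' Maxwell-Wagner (interfacial) single-shell result: with
#' `g = R / (R - d)` and `A = (eps_i - eps_mem) / (eps_i + 2 eps_mem)`,
#'
#' `eps_P = eps_mem * (g^3 + 2 A) / (g^3 - A)`
#'
#' computed in complex arithmetic. Limits: `d = 0` or
#' `eps_mem = eps_i` both collapse to `eps_P = eps_i`.
#'
#' @param cell A [shelled_cell()].
#' @param tol Singularity guard on the denominator magnitude.
#' @return Complex permittivity `eps_P`.
#' @examples
#' cl <- shelled_cell(7.5e-6, 10e-9, complex_permittivity(6),
#'                    complex_permittivity(60))
#' Re(single_shell_permittivity(cl)) # ~59.15
#' @export
single_shell_permittivity <- function(cell, tol = 1e-12) {
  stopifnot(inherits(cell, "shelled_cell"))
  em <- cell$eps_mem
  ei <- cell$eps_cyto
  g3 <- cell$gamma^3
  A <- (ei - em) / (ei + 2 * em)
  den <- g3 - A
  if (Mod(den) < tol) abort("single-shell denominator is singular.")
  em * (g3 + 2 * A) / den
}

#' Effective permittivity of a dilute suspension (effective medium)
#'
#' Maps inclusion and host permittivities plus a volume fraction to a
#' bulk effective permittivity. The default rule is Maxwell-Garnett for
#' spherical inclusions,
#'
#' `eps_eff = eps_h * (eps_i + 2 eps_h + 2 phi (eps_i - eps_h)) /
#'            (eps_i + 2 eps_h - phi (eps_i - eps_h))`
#'
#' which is exact at `phi = 0` (host) and `phi = 1` (inclusion) and
#' monotone in `phi` for real permittivities. A linear volume-weighted
#' rule is available for sensitivity analysis.
#'
#' @param eps_incl,eps_host Complex permittivities of inclusion and host.
#' @param phi Inclusion volume fraction in `[0, 1]`, vectorised.
#' @param rule `"maxwell-garnett"` (default) or `"linear"`.
#' @return Complex effective permittivity.
#' @examples
#' effective_medium_mixture(complex_permittivity(59.15),
#'                          complex_permittivity(1), 0.3)
#' @export
effective_medium_mixture <- function(eps_incl, eps_host, phi,
                                     rule = c("maxwell-garnett", "linear")) {
  rule <- match.arg(rule)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    abort("`phi` must lie in [0, 1].")
  }
  ei <- as.complex(eps_incl)
  eh <- as.complex(eps_host)
  if (rule == "linear") {
    return(phi * ei + (1 - phi) * eh)
  }
  eh * (ei + 2 * eh + 2 * phi * (ei - eh)) / (ei + 2 * eh - phi * (ei - eh))
}

#' Frequency-regime classification of the cell equivalent circuit
#'
#' Assigns each frequency to the band of the suspended-cell equivalent
#' circuit that dominates the response there:
#'
#' * `EDL_DOMINATED` below 1 kHz — the electrode double layer absorbs
#'   most of the voltage; no cell information.
#' * `MEMBRANE_POLARIZATION` 1 kHz to 1 MHz — the membrane capacitance
#'   insulates; current flows around the cell.
#' * `MEMBRANE_CHARGING` 1 MHz to 100 MHz — membrane reactance falls,
#'   current begins to enter the cell.
#' * `CYTOPLASM_SENSITIVE` above 100 MHz — the membrane is effectively
#'   short-circuited and the field probes the cytoplasm.
#'
#' Bands are half-open `[low, high)`: a frequency exactly at a threshold
#' belongs to the higher band.
#'
#' @param f Frequencies (Hz), > 0, vectorised.
#' @return A tibble with columns `frequency_hz`, `regime` (factor),
#'   `f_low_hz`, `f_high_hz`.
#' @examples
#' dispersion_regime(c(500, 50e6, 1.28e9))
#' @export
dispersion_regime <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0)) abort("require f > 0.")
  edges <- c(0, 1e3, 1e6, 1e8, Inf)
  labels <- c("EDL_DOMINATED", "MEMBRANE_POLARIZATION",
              "MEMBRANE_CHARGING", "CYTOPLASM_SENSITIVE")
  idx <- findInterval(f, edges, left.open = FALSE, rightmost.closed = FALSE)
  tibble(
    frequency_hz = f,
    regime = factor(labels[idx], levels = labels),
    f_low_hz = edges[idx],
    f_high_hz = edges[idx + 1L]
  )
}

#' Lumped elements of the suspended-cell equivalent circuit
#'
#' Light container for the circuit roles of a cell in suspension: the
#' membrane and double-layer capacitances, the cytoplasm resistance and
#' the suspending-medium RC pair. All values must be positive when
#' instantiated; the package carries them as configuration, since no
#' closed forms tie them to geometry here.
#'
#' @param c_mem,c_dl Membrane and electric-double-layer capacitance (F).
#' @param r_cyto Cytoplasm resistance (ohm).
#' @param r_medium,c_medium Suspending-medium resistance (ohm) and
#'   capacitance (F).
#' @return A named list of class `cell_circuit_elements`.
#' @export
cell_circuit_elements <- function(c_mem, c_dl, r_cyto, r_medium, c_medium) {
  vals <- list(c_mem = c_mem, c_dl = c_dl, r_cyto = r_cyto,
               r_medium = r_medium, c_medium = c_medium)
  for (nm in names(vals)) check_scalar(vals[[nm]], nm, positive = TRUE)
  structure(vals, class = "cell_circuit_elements")
}
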