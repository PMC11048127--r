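#' Physical constants used by the circuit and dielectric models
#'
#' Vacuum permeability and the speed of light are CODATA 2018 values.
#' The vacuum permittivity is the conventional engineering value
#' 8.854e-12 F/m used throughout the design equations, so capacitances
#' computed here match hand calculations done at that precision.
#'
#' @return A named list with elements `mu0` (H/m), `eps0` (F/m) and
#'   `c_light` (m/s).
#' @examples
#' physical_constants()$c_light
#' @export
physical_constants <- function() {
  list(
    mu0 = 1.25663706212e-6,
    eps0 = 8.854e-12,
    c_light = 299792458
  )
}

# Unit helpers; frequencies are Hz internally, GHz at user surfaces.
ghz_to_hz <- function(f_ghz) f_ghz * 1e9
hz_to_ghz <- function(f_hz) f_hz / 1e9

# Validate a scalar numeric argument; used by the model entry points.
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0 (got %g).", name, x))
  }
  invisible(x)
}
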