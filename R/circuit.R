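#' Resonator geometry description
#'
#' Bundles the layout and substrate parameters of a printed LC resonator:
#' an outer spiral (circular) inductor and an inner circular fork-finger
#' (interdigital) capacitor on a GaAs substrate capped with a thin SiNx
#' layer. Substrate defaults are the GaAs values used throughout the
#' design equations: relative permittivity 12.85, loss tangent 0.00028,
#' height 200 um.
#'
#' @param n Integer turn count of the spiral inductor (>= 1).
#' @param d_out,d_in Outer and inner diameter of the spiral (m);
#'   `d_out > d_in >= 0`.
#' @param finger_length Total circular finger length L_C of the
#'   interdigital capacitor (m).
#' @param a,b Inner and outer conductor radius parameters of the finger
#'   cross-section (m); `0 < a < b`.
#' @param nitride_thickness SiNx layer thickness t (m).
#' @param substrate_eps Relative permittivity of the substrate
#'   (dimensionless).
#' @param substrate_tand Substrate loss tangent (dimensionless).
#' @param substrate_height Substrate height (m).
#' @param d_avg Average spiral diameter (m); defaults to
#'   `(d_out + d_in) / 2`.
#'
#' @return An object of class `resonator_geometry` (a named list).
#' @examples
#' geom <- resonator_geometry(
#'   n = 3, d_out = 300e-6, d_in = 100e-6,
#'   finger_length = 1e-3, a = 10e-6, b = 20e-6
#' )
#' geom$d_avg
#' @export
resonator_geometry <- function(n, d_out, d_in, finger_length, a, b,
                               nitride_thickness = 0.2e-6,
                               substrate_eps = 12.85,
                               substrate_tand = 0.00028,
                               substrate_height = 200e-6,
                               d_avg = (d_out + d_in) / 2) {
  check_scalar(n, "n", positive = TRUE)
  if (n != round(n)) abort("`n` must be an integer turn count.")
  check_scalar(d_out, "d_out", positive = TRUE)
  check_scalar(d_in, "d_in", nonneg = TRUE)
  if (d_out <= d_in) abort("`d_out` must exceed `d_in`: non-physical layout.")
  check_scalar(finger_length, "finger_length", positive = TRUE)
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b", positive = TRUE)
  if (a >= b) abort("require 0 < a < b for the finger cross-section.")
  check_scalar(nitride_thickness, "nitride_thickness", positive = TRUE)
  if (substrate_eps < 1) abort("`substrate_eps` must be >= 1.")
  check_scalar(substrate_tand, "substrate_tand", nonneg = TRUE)
  check_scalar(substrate_height, "substrate_height", positive = TRUE)
  check_scalar(d_avg, "d_avg", positive = TRUE)
  structure(
    list(
      n = as.integer(n), d_out = d_out, d_in = d_in, d_avg = d_avg,
      finger_length = finger_length, a = a, b = b,
      nitride_thickness = nitride_thickness,
      substrate_eps = substrate_eps, substrate_tand = substrate_tand,
      substrate_height = substrate_height
    ),
    class = "resonator_geometry"
  )
}

#' Layout coefficients for the spiral-inductance current-sheet formula
#'
#' The closed-form spiral inductance uses four dimensionless layout
#' coefficients. The circular preset is (1.00, 2.16, 0.00, 0.20).
#'
#' @param shape Preset name; only `"circular"` is defined.
#' @return Named list with elements `c1`..`c4`.
#' @examples
#' layout_coefficients()
#' @export
layout_coefficients <- function(shape = "circular") {
  switch(shape,
    circular = list(c1 = 1.00, c2 = 2.16, c3 = 0.00, c4 = 0.20),
    abort(sprintf("unknown layout preset '%s'", shape))
  )
}

#' Spiral fill ratio
#'
#' The fill ratio of a spiral inductor,
#' `rho = (d_out - d_in) / (d_out + d_in)`: 0 for a degenerate annulus
#' (`d_out == d_in`), 1 for a filled disc (`d_in == 0`). Invariant under
#' common scaling of both diameters.
#'
#' @param d_out,d_in Outer and inner diameter (same length unit);
#'   `d_out > d_in >= 0` except the degenerate `d_out == d_in > 0` case,
#'   which returns 0.
#' @return Dimensionless ratio in `[0, 1]`, vectorised over inputs.
#' @examples
#' fill_ratio(300e-6, 100e-6) # 0.5
#' @export
fill_ratio <- function(d_out, d_in) {
  if (any(!is.finite(d_out)) || any(!is.finite(d_in))) {
    abort("diameters must be finite.")
  }
  if (any(d_in < 0) || any(d_out < d_in) || any(d_out <= 0)) {
    abort("require d_out >= d_in >= 0 with d_out > 0: non-physical layout.")
  }
  (d_out - d_in) / (d_out + d_in)
}

#' Spiral (circular) inductance from the current-sheet closed form
#'
#' `L = mu0 * n^2 * d_avg * (c1 / 2) * (log(c2 / rho) + c3 * rho + c4 * rho^2)`
#' with the layout coefficients of [layout_coefficients()]. Inductance
#' grows as the square of the turn count and diverges logarithmically as
#' the fill ratio approaches zero, so `rho = 0` is a domain error.
#'
#' @param n Turn count (>= 1).
#' @param d_avg Average diameter (m).
#' @param rho Fill ratio in `(0, 1]`, from [fill_ratio()].
#' @param coeffs Layout coefficients; default circular preset.
#' @return Inductance in henries.
#' @examples
#' spiral_inductance(1, 200e-6, 0.5) # ~0.19 nH
#' @export
spiral_inductance <- function(n, d_avg, rho, coeffs = layout_coefficients()) {
  check_scalar(n, "n", positive = TRUE)
  if (n < 1) abort("`n` must be >= 1.")
  check_scalar(d_avg, "d_avg", positive = TRUE)
  check_scalar(rho, "rho")
  if (rho <= 0 || rho > 1) {
    abort("`rho` must lie in (0, 1]; rho = 0 diverges logarithmically.")
  }
  mu0 <- physical_constants()$mu0
  mu0 * n^2 * d_avg * (coeffs$c1 / 2) *
    (log(coeffs$c2 / rho) + coeffs$c3 * rho + coeffs$c4 * rho^2)
}

#' Circinate (interdigital) capacitance via complete elliptic integrals
#'
#' Conformal-mapping capacitance of the inner circular fork-finger
#' capacitor. With modulus `k = a/b` and complementary modulus
#' `k' = sqrt(1 - k^2)`, the implemented form is
#'
#' `C = ( eps0 * (1 + eps_sub) / 2 * K(k') / K(k) + eps0 * t / a ) * L_C`
#'
#' where `K` is the complete elliptic integral of the first kind,
#' `eps_sub` the substrate relative permittivity, `t` the SiNx layer
#' thickness and `L_C` the total finger length. The first term is the
#' standard coplanar half-space result (air above, substrate below); the
#' second is a thin-film SiNx/air correction proportional to the layer
#' thickness over the inner radius. C is strictly linear in `L_C`.
#'
#' @param geom A [resonator_geometry()].
#' @return Capacitance in farads.
#' @examples
#' g <- resonator_geometry(1, 300e-6, 100e-6, 1e-3, 10e-6, 20e-6)
#' circinate_capacitance(g)
#' @export
circinate_capacitance <- function(geom) {
  stopifnot(inherits(geom, "resonator_geometry"))
  k <- geom$a / geom$b
  if (k <= 0 || k >= 1) abort("modulus k = a/b must satisfy 0 < k < 1.")
  kp2 <- 1 - k^2
  # pracma::ellipke takes the parameter m = k^2
  K_k <- pracma::ellipke(k^2)$k
  K_kp <- pracma::ellipke(kp2)$k
  eps0 <- physical_constants()$eps0
  per_len <- eps0 * (1 + geom$substrate_eps) / 2 * K_kp / K_k +
    eps0 * geom$nitride_thickness / geom$a
  per_len * geom$finger_length
}

#' Resonant frequency of an LC tank
#'
#' `f0 = 1 / (2 * pi * sqrt(L * C))`.
#'
#' @param L Inductance (H), > 0.
#' @param C Capacitance (F), > 0.
#' @return Frequency in Hz, vectorised.
#' @examples
#' resonant_frequency(1e-9, 1e-12) # ~5.03 GHz
#' @export
resonant_frequency <- function(L, C) {
  if (any(!is.finite(L)) || any(!is.finite(C)) || any(L <= 0) || any(C <= 0)) {
    abort("`L` and `C` must be finite and > 0.")
  }
  1 / (2 * pi * sqrt(L * C))
}

#' Equivalent-circuit parameters of the resonator
#'
#' Derives total inductance and capacitance from a geometry and folds in
#' the named parasitics of the equivalent circuit: the SiNx layer
#' capacitance, the inter-turn fringing capacitance `C_ab`, and the
#' trace-to-substrate shunt capacitance and resistance. No closed forms
#' exist for the parasitics in this layout family, so they are
#' user-supplied values added to the geometric capacitance (default 0,
#' i.e. the ideal LC tank).
#'
#' @param geom A [resonator_geometry()], or `NULL` when `L_total` and
#'   `C_total` are given directly.
#' @param c_sinx,c_ab,c_sub Parasitic capacitances (F), folded into
#'   `C_total`.
#' @param r_sub Substrate shunt resistance (ohm), carried for loss
#'   bookkeeping.
#' @param L_total,C_total Direct overrides (H, F) bypassing the geometry.
#' @return An object of class `circuit_params`: a named list with
#'   `L_total`, `C_total`, `C_SiNx`, `C_ab`, `C_sub`, `R_sub` and the
#'   derived `f0` (Hz).
#' @examples
#' circuit_params(L_total = 5e-9, C_total = 3.09e-12)
#' @export
circuit_params <- function(geom = NULL, c_sinx = 0, c_ab = 0, c_sub = 0,
                           r_sub = Inf, L_total = NULL, C_total = NULL) {
  for (nm in c("c_sinx", "c_ab", "c_sub")) {
    check_scalar(get(nm), nm, nonneg = TRUE)
  }
  if (is.null(L_total)) {
    stopifnot(inherits(geom, "resonator_geometry"))
    rho <- fill_ratio(geom$d_out, geom$d_in)
    L_total <- spiral_inductance(geom$n, geom$d_avg, rho)
  }
  if (is.null(C_total)) {
    stopifnot(inherits(geom, "resonator_geometry"))
    C_total <- circinate_capacitance(geom) + c_sinx + c_ab + c_sub
  } else {
    C_total <- C_total + c_sinx + c_ab + c_sub
  }
  if (L_total <= 0 || C_total <= 0) {
    abort("a valid resonator needs L_total > 0 and C_total > 0.")
  }
  structure(
    list(
      L_total = L_total, C_total = C_total,
      C_SiNx = c_sinx, C_ab = c_ab, C_sub = c_sub, R_sub = r_sub,
      f0 = resonant_frequency(L_total, C_total)
    ),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  L_total: %.6g nH\n", x$L_total * 1e9))
  cat(sprintf("  C_total: %.6g pF\n", x$C_total * 1e12))
  cat(sprintf("  f0:      %.6g GHz\n", hz_to_ghz(x$f0)))
  invisible(x)
}

#' @export
print.resonator_geometry <- function(x, ...) {
  cat("<resonator_geometry>\n")
  cat(sprintf(
    "  spiral: n = %d, d_out = %g um, d_in = %g um (d_avg = %g um)\n",
    x$n, x$d_out * 1e6, x$d_in * 1e6, x$d_avg * 1e6
  ))
  cat(sprintf(
    "  fingers: L_C = %g mm, a = %g um, b = %g um\n",
    x$finger_length * 1e3, x$a * 1e6, x$b * 1e6
  ))
  cat(sprintf(
    "  substrate: eps = %g, tan d = %g, h = %g um\n",
    x$substrate_eps, x$substrate_tand, x$substrate_height * 1e6
  ))
  invisible(x)
}
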